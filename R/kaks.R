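# Nei-Gojobori (1986) synonymous/nonsynonymous divergence with
# Jukes-Cantor correction. Site counts treat changes to stop codons as
# nonsynonymous; difference counts average over all minimal mutational
# paths between two codons, excluding paths that pass through a stop codon
# (falling back to all paths when every path does).

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# synonymous/nonsynonymous site totals of one in-frame CDS
ng86_sites <- function(cds) {
  cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  S <- sum(vapply(cod, codon_syn_sites, numeric(1)))
  list(S = S, N = 3 * length(cod) - S)
}

codon_syn_sites_env <- new.env(parent = emptyenv())

codon_syn_sites <- function(codon) {
  if (!is.null(codon_syn_sites_env[[codon]])) {
    return(codon_syn_sites_env[[codon]])
  }
  aa0 <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    vars <- single_nt_variants_at(codon, p)
    s <- s + sum(translate_codon(vars) == aa0) / 3
  }
  codon_syn_sites_env[[codon]] <- s
  s
}

single_nt_variants_at <- function(codon, p) {
  nt <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
  vapply(nt, function(x) { v <- codon; substr(v, p, p) <- x; v },
         character(1))
}

# all permutations of a small integer vector
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# average synonymous/nonsynonymous step counts over minimal mutational paths
codon_path_counts <- function(a, b) {
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diff_pos) == 0) return(c(sd = 0, nd = 0))
  paths <- perms(diff_pos)
  res <- lapply(paths, function(ord) {
    cur <- a; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (translate_codon(nxt) == "*" && nxt != b) valid <- FALSE
      if (translate_codon(cur) == translate_codon(nxt) &&
          translate_codon(nxt) != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, valid)
  })
  m <- do.call(rbind, res)
  use <- m[, 3] == 1
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

#' NG86 Ka/Ks between two aligned in-frame coding sequences
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the
#' two sequences; observed differences are resolved codon-by-codon by
#' averaging over all minimal mutational paths. Proportions are corrected
#' with the Jukes-Cantor formula.
#'
#' @param cds_a,cds_b character or [Biostrings::DNAString]; equal length,
#'   divisible by 3, no stop codons, no ambiguity codes.
#' @return list with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`
#'   (`Ka/Ks`, `NA` when `Ks` is 0 or a proportion saturates).
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("length not divisible by 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    stop("ambiguity codes not supported")
  }
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  if (any(translate_codon(ca) == "*") || any(translate_codon(cb) == "*")) {
    stop("internal stop codon")
  }
  S <- (sum(vapply(ca, codon_syn_sites, numeric(1))) +
          sum(vapply(cb, codon_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  counts <- mapply(codon_path_counts, ca, cb)
  Sd <- sum(counts["sd", ]); Nd <- sum(counts["nd", ])
  pS <- Sd / S; pN <- Nd / N
  Ks <- if (is.finite(pS) && pS < 0.75) jc_correct(pS) else NA_real_
  Ka <- if (is.finite(pN) && pN < 0.75) jc_correct(pN) else NA_real_
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, omega = omega)
}

#' NG86 Ka/Ks over a set of paired coding sequences
#'
#' @param pairs `list(a =, b =)` of matched [Biostrings::DNAStringSet]s,
#'   as produced by [generate_gene_pairs()] or read from paired FASTA.
#' @return data.frame with one row per pair and the [ng86_ka_ks()] fields.
#' @export
kaks_table <- function(pairs) {
  stopifnot(length(pairs$a) == length(pairs$b))
  rows <- lapply(seq_along(pairs$a), function(i) {
    r <- ng86_ka_ks(pairs$a[[i]], pairs$b[[i]])
    data.frame(gene = names(pairs$a)[i], S = r$S, N = r$N, Sd = r$Sd,
               Nd = r$Nd, Ks = r$Ks, Ka = r$Ka, omega = r$omega,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
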