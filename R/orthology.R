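# Junction-based identification of orthologous insertions between two
# genomes: each insertion is represented by two 100-bp junctions (50 bp
# flank + 50 bp element terminus); an insertion is orthologous when both
# junctions have exactly one qualifying match in the other genome, at
# consistent loci.

#' Extract the two 100-bp junction sequences of an element
#'
#' Left junction: 50 bp upstream flank + first 50 bp of the element.
#' Right junction: last 50 bp of the element + 50 bp downstream flank.
#'
#' @param element one-row element data.frame (TSD-defined boundaries).
#' @param genome genome A.
#' @return list `left`, `right` (100-bp strings), or `NULL` when a flank
#'   is shorter than 50 bp.
#' @export
extract_junctions <- function(element, genome) {
  s <- as.character(genome[[element$seq_id]])
  st <- element$start; en <- element$end
  if (st - 50 < 1 || en + 50 > nchar(s)) return(NULL)
  list(left = substr(s, st - 50, st + 49),
       right = substr(s, en - 49, en + 50))
}

# exact occurrence count of a pattern in a genome (both strands)
count_occurrences <- function(pattern, genome) {
  p <- Biostrings::DNAString(pattern)
  sum(Biostrings::vcountPattern(p, genome)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), genome))
}

# seed-and-verify search of a short pattern against an indexed genome;
# returns data.frame of qualifying loci
build_search_index <- function(genome, k) {
  lapply(seq_along(genome), function(j) {
    codes <- dna_codes(as.character(genome[[j]]))
    km <- kmer_ends(codes, k)
    idx <- data.table::data.table(code = km, end = seq_along(km))
    idx <- idx[!is.na(idx$code)]
    data.table::setkeyv(idx, "code")
    list(seq_id = names(genome)[j], seq = as.character(genome[[j]]),
         idx = idx)
  })
}

search_pattern <- function(index, pattern, k, min_identity, min_len) {
  mat <- sub_matrix(1, -1)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else revcomp(pattern)
    pk <- kmer_ends(dna_codes(pat), k)
    pdt <- data.table::data.table(code = pk, lend = seq_along(pk))
    pdt <- pdt[!is.na(pdt$code)]
    if (nrow(pdt) == 0) next
    for (ch in index) {
      mm <- merge(ch$idx, pdt, by = "code", allow.cartesian = TRUE)
      if (nrow(mm) == 0) next
      mm$diag <- mm$end - mm$lend
      tab <- mm[, list(nseed = .N), by = "diag"]
      tab <- tab[tab$nseed >= 2]
      if (nrow(tab) == 0) next
      tab <- tab[order(tab$diag)]
      grp <- cumsum(c(TRUE, diff(tab$diag) > 20))
      for (g in unique(grp)) {
        dg <- tab$diag[grp == g]
        st <- max(1, min(dg) + 1 - 10)
        en <- min(nchar(ch$seq), max(dg) + nchar(pat) + 10)
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(pat),
          Biostrings::DNAString(substr(ch$seq, st, en)),
          type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 1)
        alen <- nchar(as.character(Biostrings::alignedPattern(al)))
        if (alen == 0) next
        ident <- Biostrings::nmatch(al) / alen
        if (ident < min_identity || alen < min_len) next
        sj <- Biostrings::subject(al)
        hits <- c(hits, list(data.frame(
          seq_id = ch$seq_id,
          start = st + Biostrings::start(sj) - 1L,
          end = st + Biostrings::end(sj) - 1L,
          strand = strand, identity = ident, stringsAsFactors = FALSE)))
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric()))
  }
  # collapse duplicate loci found on overlapping diagonal groups
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (out$seq_id[i] == out$seq_id[i - 1] &&
          out$start[i] <= out$end[i - 1]) keep[i] <- FALSE
    }
  }
  out[keep, , drop = FALSE]
}

#' Call orthologous insertions between two genomes via junction uniqueness
#'
#' For each TSD-anchored element of genome A with unique junctions, both
#' 100-bp junctions are searched against genome B (both strands,
#' >= `min_identity` over >= `min_len` bp). Status is `orthologous` when
#' each junction has exactly one qualifying locus and the two loci are
#' consistent (same sequence and strand, spacing below twice the element
#' length); `absent` when the empty-site flanks are present but the
#' element-side junction halves are not; `ambiguous` otherwise. For
#' orthologous intact elements the intra- and inter-genome LTR divergences
#' are computed.
#'
#' @param elements element table of genome A (TSD-bearing rows are used).
#' @param genome_a,genome_b the two genomes.
#' @param min_identity junction match identity threshold (default 0.9).
#' @param min_len minimum matched length of the 100-bp junction.
#' @param k seed word length.
#' @return data.frame, one row per usable element: `status` plus B-locus
#'   coordinates and `K_intra_A`, `K_intra_B`, `K_inter_5`, `K_inter_3`,
#'   `K_inter`.
#' @export
ortholog_calls <- function(elements, genome_a, genome_b,
                           min_identity = 0.90, min_len = 90, k = 15) {
  idx_b <- build_search_index(genome_b, k)
  seqs_a <- as.character(genome_a)
  seqs_b <- as.character(genome_b)
  use <- which(!is.na(elements$tsd))
  rows <- list()
  for (i in use) {
    el <- elements[i, , drop = FALSE]
    jn <- extract_junctions(el, genome_a)
    res <- data.frame(element_id = el$element_id, status = "skipped_flank",
                      b_seq = NA_character_, b_start = NA_integer_,
                      b_end = NA_integer_, b_strand = NA_character_,
                      K_intra_A = NA_real_, K_intra_B = NA_real_,
                      K_inter_5 = NA_real_, K_inter_3 = NA_real_,
                      K_inter = NA_real_, stringsAsFactors = FALSE)
    if (is.null(jn)) { rows <- c(rows, list(res)); next }
    if (count_occurrences(jn$left, genome_a) != 1 ||
        count_occurrences(jn$right, genome_a) != 1) {
      res$status <- "skipped_nonunique"
      rows <- c(rows, list(res)); next
    }
    hl <- search_pattern(idx_b, jn$left, k, min_identity, min_len)
    hr <- search_pattern(idx_b, jn$right, k, min_identity, min_len)
    if (nrow(hl) == 1 && nrow(hr) == 1 &&
        hl$seq_id == hr$seq_id && hl$strand == hr$strand &&
        abs(hr$start - hl$start) <= 2 * (el$end - el$start + 1) + 200) {
      res$status <- "orthologous"
      res$b_seq <- hl$seq_id
      res$b_strand <- hl$strand
      if (hl$strand == "+") {
        res$b_start <- hl$start + 50L
        res$b_end <- hr$end - 50L
      } else {
        res$b_start <- hr$start + 50L
        res$b_end <- hl$end - 50L
      }
      if (!is.na(el$ltr3_start)) {
        kv <- ortholog_ltr_divergences(el, res, seqs_a, seqs_b)
        res[names(kv)] <- kv
      }
    } else if (nrow(hl) == 0 && nrow(hr) == 0 &&
               empty_site_present(jn, idx_b, k, min_identity)) {
      res$status <- "absent"
    } else {
      res$status <- "ambiguous"
    }
    rows <- c(rows, list(res))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(element_id = character(), status = character())
  }
  rownames(out) <- NULL
  out
}

# do the flank-only halves of both junctions match somewhere in B?
empty_site_present <- function(jn, idx_b, k, min_identity) {
  lf <- substr(jn$left, 1, 50)
  rf <- substr(jn$right, 51, 100)
  hl <- search_pattern(idx_b, lf, k, min_identity, 45)
  hr <- search_pattern(idx_b, rf, k, min_identity, 45)
  nrow(hl) >= 1 && nrow(hr) >= 1
}

# intra/inter LTR divergences for one orthologous intact element, mapping
# the A-side LTR offsets onto the matched B locus
ortholog_ltr_divergences <- function(el, res, seqs_a, seqs_b) {
  sa <- seqs_a[[el$seq_id]]
  sb <- seqs_b[[res$b_seq]]
  a5 <- substr(sa, el$ltr5_start, el$ltr5_end)
  a3 <- substr(sa, el$ltr3_start, el$ltr3_end)
  off5 <- c(el$ltr5_start - el$start, el$ltr5_end - el$start)
  off3 <- c(el$end - el$ltr3_end, el$end - el$ltr3_start)
  if (res$b_strand == "+") {
    b5 <- substr(sb, res$b_start + off5[1], res$b_start + off5[2])
    b3 <- substr(sb, res$b_end - off3[2], res$b_end - off3[1])
  } else {
    b5 <- revcomp(substr(sb, res$b_end - off5[2], res$b_end - off5[1]))
    b3 <- revcomp(substr(sb, res$b_start + off3[1], res$b_start + off3[2]))
  }
  d <- function(x, y) {
    tryCatch(ltr_divergence(x, y)$K, error = function(e) NA_real_)
  }
  k5 <- d(a5, b5); k3 <- d(a3, b3)
  list(K_intra_A = d(a5, a3), K_intra_B = d(b5, b3),
       K_inter_5 = k5, K_inter_3 = k3,
       K_inter = mean(c(k5, k3), na.rm = TRUE))
}

#' Intra- versus inter-specific LTR divergence contrast
#'
#' For orthologous intact elements, compares the within-element LTR-LTR
#' divergence in each genome against the cross-genome divergence of the
#' matched LTRs with paired two-sided t-tests. Insertions that predate the
#' species split show intra > inter.
#'
#' @param calls output of [ortholog_calls()].
#' @return list of per-metric means/sds and the three paired tests
#'   (`intraA_vs_inter`, `intraB_vs_inter`, `intraA_vs_intraB`).
#' @export
intra_inter_contrast <- function(calls) {
  ok <- calls$status == "orthologous" & !is.na(calls$K_intra_A) &
    !is.na(calls$K_intra_B) & !is.na(calls$K_inter)
  x <- calls[ok, , drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 orthologous intact elements")
  tt <- function(a, b) {
    r <- t.test(a, b, paired = TRUE)
    list(p_value = r$p.value, t = unname(r$statistic),
         mean_diff = unname(r$estimate))
  }
  list(n = nrow(x),
       mean_K_intra_A = mean(x$K_intra_A), sd_K_intra_A = sd(x$K_intra_A),
       mean_K_intra_B = mean(x$K_intra_B), sd_K_intra_B = sd(x$K_intra_B),
       mean_K_inter = mean(x$K_inter), sd_K_inter = sd(x$K_inter),
       intraA_vs_inter = tt(x$K_intra_A, x$K_inter),
       intraB_vs_inter = tt(x$K_intra_B, x$K_inter),
       intraA_vs_intraB = tt(x$K_intra_A, x$K_intra_B))
}

#' Divergence-time estimate from the modal bin of a divergence histogram
#'
#' Values (orthologous LTR divergences K, or gene Ks) are binned at fixed
#' width from zero; the modal bin's edges are converted to a time range by
#' `T = K / (2 r)`. Ties go to the lower bin.
#'
#' @param values numeric divergence values (>= 10).
#' @param rate substitution rate per site per year (1.3e-8 for LTRs,
#'   6.03e-9 for genes).
#' @param bin_width histogram bin width (default 0.01).
#' @return list `histogram`, `modal_bin` (lo, hi), `modal_fraction`,
#'   `time_range_my` (2 decimals).
#' @export
divergence_time <- function(values, rate, bin_width = 0.01) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need >= 10 divergence values")
  br <- seq(0, max(values) + bin_width, by = bin_width)
  cnt <- table(cut(values, br, right = FALSE))
  m <- which.max(cnt)  # first max: ties resolve to the lower bin
  lo <- br[m]; hi <- br[m + 1]
  list(histogram = data.frame(lo = head(br, -1), hi = tail(br, -1),
                              count = as.integer(cnt)),
       modal_bin = c(lo = lo, hi = hi),
       modal_fraction = as.integer(cnt[m]) / length(values),
       time_range_my = round(c(lo, hi) / (2 * rate) / 1e6, 2))
}
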