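# Independent oracles and small sequence utilities used across test files.

GEN_CODE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GEN_CODE)[GEN_CODE != "*"]

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly n distinct positions of a sequence
mutate_exact <- function(seq, n, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), n)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# --- NG86 enumeration oracle ------------------------------------------------
# Walks every ordering of the differing codon positions with an explicit
# stack (deliberately structured differently from the implementation's
# recursive permutation helper). Paths through stop codons are excluded
# unless all paths hit one.
oracle_codon_counts <- function(a, b) {
  pa <- strsplit(a, "")[[1]]; pb <- strsplit(b, "")[[1]]
  dpos <- which(pa != pb)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  all_orders <- function(v) {
    if (length(v) == 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) {
      for (r in all_orders(v[-i])) res[[length(res) + 1]] <- c(v[i], r)
    }
    res
  }
  recs <- list()
  for (ord in all_orders(dpos)) {
    cur <- pa; sd <- 0; nd <- 0; hits_stop <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- pb[p]
      aa_cur <- GEN_CODE[paste(cur, collapse = "")]
      aa_nxt <- GEN_CODE[paste(nxt, collapse = "")]
      if (aa_nxt == "*" && !identical(nxt, pb)) hits_stop <- TRUE
      if (aa_cur == aa_nxt && aa_nxt != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    recs[[length(recs) + 1]] <- c(sd, nd, hits_stop)
  }
  m <- do.call(rbind, recs)
  use <- m[, 3] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

# per-codon synonymous site count, counting stop-codon targets as
# nonsynonymous (direct enumeration over the nine single-nt neighbours)
oracle_codon_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa0 <- GEN_CODE[codon]
  syn <- 0
  for (p in 1:3) {
    for (x in setdiff(c("A", "C", "G", "T"), ch[p])) {
      v <- ch; v[p] <- x
      if (GEN_CODE[paste(v, collapse = "")] == aa0) syn <- syn + 1
    }
  }
  syn / 3
}

# random sense codon pair with at most max_diff differences, both sense
random_codon_pair <- function(max_diff = 3) {
  repeat {
    a <- sample(SENSE_CODONS, 1)
    nd <- sample(0:max_diff, 1)
    b <- a
    if (nd > 0) {
      ch <- strsplit(a, "")[[1]]
      for (p in sample(1:3, nd)) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      b <- paste(ch, collapse = "")
    }
    if (GEN_CODE[b] != "*") return(c(a, b))
  }
}

# random additive tree + its patristic distance matrix
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
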