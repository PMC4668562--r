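#' @import data.table
#' @importFrom stats rbinom runif rpois setNames filter lm coef cor cor.test
#'   t.test quantile sd as.dist
#' @importFrom utils head tail
NULL

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes its own seed derived
#' deterministically from one master seed, so individual stages can be rerun
#' in isolation and still reproduce a full-pipeline run.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"plant"`, `"randomization"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 69069 + h * 2654435761) %% 2147483563 + 1)
}

# residue string -> integer codes A=0 C=1 G=2 T=3, N/other = NA
dna_codes <- function(x) {
  v <- utf8ToInt(as.character(x))
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

codes_dna <- function(codes) {
  ch <- c("A", "C", "G", "T")[codes + 1L]
  ch[is.na(ch)] <- "N"
  paste(ch, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Jukes-Cantor correction of a raw mismatch proportion
#'
#' @param p raw per-site mismatch proportion, `0 <= p < 0.75`.
#' @return Corrected per-site divergence `K = -(3/4) log(1 - 4p/3)`.
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop("JC correction undefined for p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

# inverse JC: per-site substitution probability realizing divergence K
jc_invert <- function(K) 0.75 * (1 - exp(-4 * K / 3))

# mutate a DNA character string: each site substituted independently with
# probability p (to one of the three other bases); N sites untouched
mutate_sites <- function(seq, p) {
  if (p <= 0) return(seq)
  codes <- dna_codes(seq)
  ok <- which(!is.na(codes))
  hit <- ok[runif(length(ok)) < p]
  if (length(hit)) {
    codes[hit] <- (codes[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  }
  codes_dna(codes)
}

.mat_cache <- new.env(parent = emptyenv())

# cached nucleotide substitution matrix (construction dominates short
# pairwise alignments otherwise)
sub_matrix <- function(match = 1, mismatch = -1) {
  key <- paste(match, mismatch)
  if (is.null(.mat_cache[[key]])) {
    .mat_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
  }
  .mat_cache[[key]]
}

random_dna <- function(n, gc = 0.5) {
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = pr),
        collapse = "")
}
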