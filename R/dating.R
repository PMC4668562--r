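# Insertion-age dating from LTR-LTR divergence. The two LTRs of an element
# are identical at insertion; their divergence K, under a substitution rate
# r per site per year, dates the insertion at T = K / (2 r).

#' Divergence between the two LTRs of an element
#'
#' Global (Needleman-Wunsch, affine-gap) alignment of the two LTR sequences;
#' columns containing a gap or an N are excluded from the site count, so
#' `p` is a pure substitution proportion. `K` is the model-corrected
#' divergence (Jukes-Cantor by default, Kimura two-parameter optional).
#'
#' @param ltr5,ltr3 character or `DNAString`, each >= 50 bp.
#' @param model `"JC"` (default) or `"K2P"`.
#' @param match,mismatch,gap_open,gap_extend alignment scoring parameters.
#' @return list with `p`, `K`, `aligned_sites`.
#' @export
ltr_divergence <- function(ltr5, ltr3, model = c("JC", "K2P"),
                           match = 1, mismatch = -1,
                           gap_open = 5, gap_extend = 1) {
  model <- match.arg(model)
  a <- toupper(as.character(ltr5)); b <- toupper(as.character(ltr3))
  if (nchar(a) < 50 || nchar(b) < 50) stop("LTR sequences must be >= 50 bp")
  if (a == b) {
    return(list(p = 0, K = 0, aligned_sites = nchar(a)))
  }
  # equal-length pairs at low divergence align without gaps: score the
  # ungapped comparison directly and skip the S4 alignment machinery
  if (nchar(a) == nchar(b)) {
    ca <- dna_codes(a); cb <- dna_codes(b)
    keep <- !is.na(ca) & !is.na(cb)
    if (sum(keep) >= 50) {
      p0 <- mean(ca[keep] != cb[keep])
      if (p0 < 0.30) {
        K0 <- if (model == "JC") {
          jc_correct(p0)
        } else {
          pur <- ca %in% c(0L, 2L)
          ts <- mean((pur[keep] == (cb[keep] %in% c(0L, 2L))) &
                       ca[keep] != cb[keep])
          tv <- p0 - ts
          -0.5 * log(1 - 2 * ts - tv) - 0.25 * log(1 - 2 * tv)
        }
        return(list(p = p0, K = K0, aligned_sites = sum(keep)))
      }
    }
  }
  mat <- sub_matrix(match, mismatch)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- pa %in% c("A", "C", "G", "T") & sa %in% c("A", "C", "G", "T")
  n_sites <- sum(keep)
  if (n_sites < 50) stop("fewer than 50 aligned sites")
  mism <- pa[keep] != sa[keep]
  p <- mean(mism)
  K <- if (model == "JC") {
    jc_correct(p)
  } else {
    ts <- mean((pa[keep] %in% c("A", "G") & sa[keep] %in% c("A", "G") |
                  pa[keep] %in% c("C", "T") & sa[keep] %in% c("C", "T")) &
                 mism)
    tv <- p - ts
    -0.5 * log(1 - 2 * ts - tv) - 0.25 * log(1 - 2 * tv)
  }
  list(p = p, K = K, aligned_sites = n_sites)
}

#' Insertion (or divergence) time from divergence K
#'
#' `T = K / (2 r)` with `r` the substitution rate per site per year
#' (default 1.3e-8, the rate commonly applied to plant LTR
#' retrotransposons).
#'
#' @param K per-site divergence (>= 0).
#' @param r substitution rate per site per year.
#' @return Time in years.
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  if (any(K < 0)) stop("negative K")
  stopifnot(r > 0)
  K / (2 * r)
}

#' Date every intact element in an element table
#'
#' @param elements element data.frame (from annotation) with LTR spans.
#' @param genome the genome the coordinates refer to.
#' @param r substitution rate per site per year.
#' @param model distance model passed to [ltr_divergence()].
#' @return `elements` with `p`, `K`, `age_years`, `age_my` filled for rows
#'   with two LTRs (others NA).
#' @export
date_elements <- function(elements, genome, r = 1.3e-8, model = "JC") {
  seqs <- as.character(genome)
  elements$p <- NA_real_; elements$K <- NA_real_
  elements$age_years <- NA_real_
  for (i in which(elements$n_ltrs >= 2)) {
    a <- substr(seqs[[elements$seq_id[i]]],
                elements$ltr5_start[i], elements$ltr5_end[i])
    b <- substr(seqs[[elements$seq_id[i]]],
                elements$ltr3_start[i], elements$ltr3_end[i])
    d <- tryCatch(ltr_divergence(a, b, model = model),
                  error = function(e) NULL)
    if (is.null(d)) next
    elements$p[i] <- d$p
    elements$K[i] <- d$K
    elements$age_years[i] <- insertion_time(d$K, r)
  }
  elements$age_my <- elements$age_years / 1e6
  elements
}

#' Age histogram with linear and exponential diagnostics
#'
#' Bins ages at fixed width and reports the Pearson correlation between bin
#' midpoint and count (linear diagnostic) and between midpoint and
#' log(count) over positive bins (exponential diagnostic), each with its
#' two-sided p-value.
#'
#' @param ages_my numeric insertion ages in millions of years.
#' @param bin bin width in My (default 0.5).
#' @return list with `histogram` (data.frame `mid`, `count`) and `fits`
#'   (list `linear`, `exponential`, each `r` + `p_value`, or `NA` flagged
#'   when undefined).
#' @export
age_distribution <- function(ages_my, bin = 0.5) {
  if (length(ages_my) == 0) stop("no ages supplied")
  br <- seq(0, max(ages_my) + bin, by = bin)
  cnt <- table(cut(ages_my, br, right = FALSE))
  h <- data.frame(mid = head(br, -1) + bin / 2, count = as.integer(cnt))
  fits <- list(linear = list(r = NA_real_, p_value = NA_real_),
               exponential = list(r = NA_real_, p_value = NA_real_))
  if (sum(h$count > 0) >= 2 && nrow(h) >= 3) {
    ct <- cor.test(h$mid, h$count)
    fits$linear <- list(r = unname(ct$estimate), p_value = ct$p.value)
    pos <- h[h$count > 0, ]
    if (nrow(pos) >= 3) {
      ce <- cor.test(pos$mid, log(pos$count))
      fits$exponential <- list(r = unname(ce$estimate), p_value = ce$p.value)
    }
  }
  list(histogram = h, fits = fits)
}
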