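# Window-based density profiles, the randomization test for unbiased
# chromosomal distribution, Marey-map recombination rates, and
# density-rate correlations.

#' Tile a genome into fixed windows and count annotation midpoints
#'
#' Chromosomes are tiled into contiguous windows of `window_size`; the
#' trailing partial window is dropped. An annotation is assigned to the
#' window containing its midpoint. Windows whose N fraction exceeds half
#' the window are marked ineligible.
#'
#' @param annotations data.frame with `seq_id`, `start`, `end` (1-based
#'   inclusive); may be empty.
#' @param genome [Biostrings::DNAStringSet].
#' @param window_size window width in bp (e.g. 1e6, 1e5, 5e4).
#' @return data.frame, one row per window: `seq_id`, `window`, `start`,
#'   `end`, `n_bp_N`, `eligible`, `count`.
#' @export
window_counts <- function(annotations, genome, window_size) {
  out <- lapply(seq_along(genome), function(j) {
    len <- Biostrings::width(genome)[j]
    nwin <- len %/% window_size
    if (nwin == 0) {
      warning("window size exceeds length of ", names(genome)[j])
      return(NULL)
    }
    st <- (seq_len(nwin) - 1L) * window_size + 1L
    en <- st + window_size - 1L
    v <- Biostrings::Views(genome[[j]], start = st, end = en)
    nN <- Biostrings::letterFrequency(v, "N")[, 1]
    data.frame(seq_id = names(genome)[j], window = seq_len(nwin),
               start = st, end = en, n_bp_N = as.integer(nN),
               eligible = nN <= window_size / 2, count = 0L,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, out)
  if (is.null(prof)) {
    return(data.frame(seq_id = character(), window = integer(),
                      start = integer(), end = integer(),
                      n_bp_N = integer(), eligible = logical(),
                      count = integer()))
  }
  if (nrow(annotations) > 0) {
    mid <- floor((annotations$start + annotations$end) / 2)
    w <- (mid - 1L) %/% window_size + 1L
    key <- paste(annotations$seq_id, w)
    tab <- table(key)
    pk <- paste(prof$seq_id, prof$window)
    hit <- match(pk, names(tab))
    prof$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  rownames(prof) <- NULL
  prof
}

#' Randomization test of window occupancy against a uniform null
#'
#' The genome-wide total of midpoints over eligible windows is re-placed
#' uniformly across those windows `n_sim` times. Each window's two-sided
#' empirical p-value is `(1 + #sims as or more extreme) / (n_sim + 1)`,
#' extremeness measured as `|count - expected|`. The summary reports the
#' fraction of eligible windows not distinguishable from the null
#' (`p >= alpha`), the quantity used to describe a genome as "randomly
#' distributed".
#'
#' @param profiles output of [window_counts()].
#' @param n_sim number of simulations (default 10000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return list `profiles` (with `empirical_p` on eligible rows) and
#'   `summary` (`n_eligible`, `n_nonsignificant`, `fraction_nonsignificant`).
#' @export
randomization_test <- function(profiles, n_sim = 10000, alpha = 0.05, seed) {
  el <- which(profiles$eligible)
  if (length(el) == 0) stop("no eligible windows")
  total <- sum(profiles$count[el])
  if (total == 0) stop("no elements in eligible windows")
  set.seed(seed)
  W <- length(el)
  expected <- total / W
  sims <- stats::rmultinom(n_sim, total, rep(1 / W, W))
  obs_dev <- abs(profiles$count[el] - expected)
  dev <- abs(sims - expected)
  pvals <- (1 + rowSums(dev >= obs_dev)) / (n_sim + 1)
  profiles$empirical_p <- NA_real_
  profiles$empirical_p[el] <- pvals
  n_nonsig <- sum(pvals >= alpha)
  list(profiles = profiles,
       summary = list(n_eligible = W, n_nonsignificant = n_nonsig,
                      fraction_nonsignificant = n_nonsig / W,
                      alpha = alpha, n_sim = n_sim))
}

# longest non-decreasing subsequence (indices), O(n^2); marker sets are small
lnds_idx <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] <= x[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (!is.na(i)) { out <- c(i, out); i <- prev[i] }
  out
}

#' Marey-map local recombination rates at window midpoints
#'
#' Markers on each chromosome are filtered to a monotone series (longest
#' non-decreasing subsequence of cM against bp); the local rate at a window
#' midpoint is the least-squares slope over the nearest `k` markers,
#' clamped at zero, in cM/Mb. Chromosomes with fewer than five usable
#' markers get `NA` rates.
#'
#' @param markers marker table from [read_marker_map()].
#' @param windows window table from [window_counts()].
#' @param k number of nearest markers for the local fit (default 7).
#' @return `windows` with a `gr_rate` column (cM/Mb or NA).
#' @export
marey_rates <- function(markers, windows, k = 7) {
  windows$gr_rate <- NA_real_
  for (ch in unique(windows$seq_id)) {
    m <- markers[markers$chrom == ch, ]
    if (nrow(m) == 0) next
    m <- m[order(m$bp), ]
    m <- m[lnds_idx(m$cM), ]
    if (nrow(m) < 5) next
    rows <- which(windows$seq_id == ch)
    mids <- (windows$start[rows] + windows$end[rows]) / 2
    kk <- min(k, nrow(m))
    windows$gr_rate[rows] <- vapply(mids, function(md) {
      nb <- order(abs(m$bp - md))[seq_len(kk)]
      sl <- coef(lm(cM ~ bp, data = m[nb, ]))[2]
      max(0, unname(sl) * 1e6)
    }, numeric(1))
  }
  windows
}

#' Pearson correlation between two per-window quantities, with bootstrap CI
#'
#' @param x,y numeric vectors over the same (eligible) windows.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list `r`, `p_value`, `ci` (percentile 95%), `n`; `r` is NA
#'   (flagged `degenerate`) when either vector has zero variance.
#' @export
density_correlation <- function(x, y, n_boot = 10000, seed) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need >= 10 paired windows")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, ci = c(NA, NA),
                n = length(x), degenerate = TRUE))
  }
  ct <- cor.test(x, y)
  set.seed(seed)
  bs <- replicate(n_boot, {
    i <- sample.int(length(x), replace = TRUE)
    if (sd(x[i]) == 0 || sd(y[i]) == 0) NA_real_ else cor(x[i], y[i])
  })
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci = unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE)),
       n = length(x), degenerate = FALSE)
}
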