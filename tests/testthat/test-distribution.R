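test_that("windows tile chromosomes with the trailing partial dropped", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 3.5e6)))
  w <- window_counts(data.frame(seq_id = character(), start = integer(),
                                end = integer()), g, 1e6)
  expect_equal(nrow(w), 3)
  expect_equal(w$end[3], 3e6)

  # midpoint assignment
  an <- data.frame(seq_id = "c1", start = 1499000L, end = 1501000L)
  w2 <- window_counts(an, g, 1e6)
  expect_equal(w2$count, c(0L, 1L, 0L))

  # window with > half N is ineligible
  gn <- Biostrings::DNAStringSet(c(c1 = paste0(
    strrep("A", 4e5), strrep("N", 6e5), strrep("A", 1e6))))
  wn <- window_counts(an[0, ], gn, 1e6)
  expect_equal(wn$eligible, c(FALSE, TRUE))

  expect_warning(window_counts(an[0, ],
                               Biostrings::DNAStringSet(c(s = "ACGT")),
                               1e6), "window size exceeds")
})

test_that("counts partition all annotations across windows and tail", {
  set.seed(41)
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 1.05e6)))
  mid <- sample.int(1.04e6, 500)
  an <- data.frame(seq_id = "c1", start = mid, end = mid + 10)
  w <- window_counts(an, g, 1e5)
  in_tail <- sum(floor((an$start + an$end) / 2) > 1e6)
  expect_equal(sum(w$count) + in_tail, 500)
})

test_that("an extreme concentration is flagged by the randomization test", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2e6)))
  mid <- rep(55000L, 100)
  an <- data.frame(seq_id = "c1", start = mid, end = mid + 10)
  w <- window_counts(an, g, 1e5)
  rt <- randomization_test(w, n_sim = 2000, seed = 3)
  hot <- rt$profiles$empirical_p[1]
  expect_lt(hot, 0.001)
  expect_error(randomization_test(w[0, ], n_sim = 10, seed = 1),
               "no eligible")
})

test_that("the randomization test is calibrated under the uniform null", {
  set.seed(47)
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2e6)))
  mid <- sample.int(2e6 - 20, 1000)
  an <- data.frame(seq_id = "c1", start = mid, end = mid + 10)
  w <- window_counts(an, g, 1e4)   # 200 windows
  rt <- randomization_test(w, n_sim = 1000, alpha = 0.05, seed = 7)
  frac_sig <- 1 - rt$summary$fraction_nonsignificant
  expect_lt(abs(frac_sig - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
  # seed-reproducible
  rt2 <- randomization_test(w, n_sim = 1000, alpha = 0.05, seed = 7)
  expect_identical(rt$profiles$empirical_p, rt2$profiles$empirical_p)
})

test_that("planted hotspots are detected with high power", {
  set.seed(53)
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2e6)))
  # windows 1-2 of 20 loaded well above the uniform expectation
  mid <- c(sample.int(2e6 - 20, 6000), sample.int(2e5, 4000))
  an <- data.frame(seq_id = "c1", start = mid, end = mid + 10)
  w <- window_counts(an, g, 1e5)
  rt <- randomization_test(w, n_sim = 1000, seed = 11)
  expect_true(all(rt$profiles$empirical_p[1:2] < 0.05))
})

test_that("Marey-map rates recover linear and piecewise maps", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 4e6)))
  w <- window_counts(data.frame(seq_id = character(), start = integer(),
                                end = integer()), g, 2e5)
  mk <- data.frame(chrom = "c1", bp = seq(0, 4e6, 5e4))
  mk$cM <- mk$bp * 1e-6
  r1 <- marey_rates(mk, w)
  expect_equal(r1$gr_rate, rep(1, nrow(w)), tolerance = 1e-8)

  mk2 <- mk
  mk2$cM <- ifelse(mk2$bp <= 2e6, mk2$bp * 1e-6, 2 + (mk2$bp - 2e6) * 2e-6)
  r2 <- marey_rates(mk2, w)
  expect_equal(r2$gr_rate[2], 1, tolerance = 0.05)
  expect_equal(r2$gr_rate[nrow(w) - 1], 2, tolerance = 0.05)

  # too few markers: no rates
  r3 <- marey_rates(mk[1:3, ], w)
  expect_true(all(is.na(r3$gr_rate)))
})

test_that("non-monotone marker noise is filtered before rate fitting", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2e6)))
  w <- window_counts(data.frame(seq_id = character(), start = integer(),
                                end = integer()), g, 2e5)
  mk <- data.frame(chrom = "c1", bp = seq(0, 2e6, 5e4))
  mk$cM <- mk$bp * 1e-6
  mk$cM[10] <- 50  # one wild outlier breaks monotonicity
  r <- marey_rates(mk, w)
  expect_true(all(abs(r$gr_rate - 1) < 0.1))
})

test_that("density correlation reports r, bootstrap CI and degeneracy", {
  set.seed(59)
  x <- runif(200)
  d <- density_correlation(x, 2 * x + rnorm(200, 0, 1e-4), n_boot = 500,
                           seed = 2)
  expect_gt(d$r, 0.999)
  expect_true(d$ci[1] <= d$r && d$r <= d$ci[2])

  d0 <- density_correlation(rep(1, 50), runif(50), n_boot = 10, seed = 1)
  expect_true(d0$degenerate)
  expect_true(is.na(d0$r))
  expect_error(density_correlation(1:5, 1:5, seed = 1), ">= 10")

  # independent vectors: small |r|
  d2 <- density_correlation(runif(500), runif(500), n_boot = 200, seed = 9)
  expect_lt(abs(d2$r), 0.15)
})
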