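# Shared two-genome fixture for the orthology tests.
orth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bg <- generate_background(1.2e6, gc = 0.4, seed = 111)
      sp <- plant_spec(n_intact = 18, n_solo = 4, n_intact_notsd = 0,
                       n_solo_notsd = 0, target_K = 0.02,
                       internal_len_range = c(1500, 3000), seed = 112)
      pl <- plant_elements(bg, sp)
      dv <- diverge_genomes(pl$genome, pl$manifest, ortholog_fraction = 0.5,
                            point_divergence = 0.01, seed = 113)
      el <- annotate_genome(dv$genome_a)
      cache <<- list(dv = dv, elements = el,
                     calls = ortholog_calls(el, dv$genome_a, dv$genome_b))
    }
    cache
  }
})

test_that("junctions are 50 bp flank + 50 bp element on both sides", {
  fx <- orth_fixture()
  el <- fx$elements[fx$elements$category == "IT", ][1, ]
  jn <- extract_junctions(el, fx$dv$genome_a)
  s <- as.character(fx$dv$genome_a[[el$seq_id]])
  expect_equal(nchar(jn$left), 100)
  expect_equal(jn$left, substr(s, el$start - 50, el$start + 49))
  expect_equal(jn$right, substr(s, el$end - 49, el$end + 50))

  near_edge <- el
  near_edge$start <- 30; near_edge$end <- 500
  expect_null(extract_junctions(near_edge, fx$dv$genome_a))
})

test_that("elements inside a duplicated segment are skipped as non-unique", {
  set.seed(117)
  ltr <- rand_dna(300); tsd <- "CGTTA"
  elem <- paste0(ltr, rand_dna(900), mutate_exact(ltr, 6))
  block <- paste0(rand_dna(300), tsd, elem, tsd, rand_dna(300))
  gA <- Biostrings::DNAStringSet(c(c1 = paste0(
    rand_dna(2000), block, rand_dna(2000), block, rand_dna(2000))))
  el <- annotate_genome(gA)
  calls <- ortholog_calls(el, gA, gA)
  expect_true(all(calls$status == "skipped_nonunique"))
})

test_that("orthologous, absent and link metrics agree with the manifest", {
  fx <- orth_fixture()
  lk <- ltrscape:::evaluate_ortholog_links(fx$calls, fx$elements,
                                           fx$dv$manifest_a)
  expect_gte(lk$precision, 0.98)
  expect_gte(lk$recall, 0.90)
  # deleted insertions are recognized as absent, not ambiguous
  expect_gt(sum(fx$calls$status == "absent"), 0)
  expect_equal(sum(fx$calls$status == "ambiguous"), 0)
})

test_that("identical genomes give zero inter-genome divergence", {
  bg <- generate_background(4e5, gc = 0.4, seed = 121)
  sp <- plant_spec(n_intact = 5, n_solo = 0, n_intact_notsd = 0,
                   n_solo_notsd = 0, internal_len_range = c(1500, 2500),
                   seed = 122)
  pl <- plant_elements(bg, sp)
  el <- annotate_genome(pl$genome)
  calls <- ortholog_calls(el, pl$genome, pl$genome)
  orth <- calls[calls$status == "orthologous", ]
  expect_gte(nrow(orth), 4)
  expect_true(all(orth$K_inter == 0))
})

test_that("the intra/inter contrast detects pre-split insertions", {
  fx <- orth_fixture()
  ct <- intra_inter_contrast(fx$calls)
  # planted: K_intra ~ 0.02 + 2*0.01, K_inter ~ 2*0.01
  expect_gt(ct$mean_K_intra_A, ct$mean_K_inter)
  expect_lt(ct$intraA_vs_inter$p_value, 0.01)
  expect_gt(ct$intraA_vs_intraB$p_value, 0.05)
})

test_that("divergence-time estimation reproduces the clock arithmetic", {
  set.seed(127)
  k_vals <- c(runif(40, 0.02, 0.0299), runif(20, 0, 0.02),
              runif(15, 0.03, 0.06))
  dt <- divergence_time(k_vals, rate = 1.3e-8)
  expect_equal(unname(dt$modal_bin), c(0.02, 0.03))
  expect_equal(dt$time_range_my, c(0.77, 1.15))

  ks_vals <- c(runif(40, 0.01, 0.0199), runif(25, 0, 0.01))
  dt2 <- divergence_time(ks_vals, rate = 6.03e-9)
  expect_equal(dt2$time_range_my, c(0.83, 1.66))

  dt0 <- divergence_time(rep(0, 12), rate = 1.3e-8)
  expect_equal(unname(dt0$modal_bin), c(0, 0.01))
  expect_equal(dt0$time_range_my, c(0, 0.38))

  # order invariance
  dt3 <- divergence_time(rev(k_vals), rate = 1.3e-8)
  expect_identical(dt$modal_bin, dt3$modal_bin)
  expect_error(divergence_time(1:5 / 100, rate = 1e-8), ">= 10")
})
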