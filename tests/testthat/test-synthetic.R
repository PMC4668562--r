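test_that("background generation is deterministic and respects GC", {
  a <- generate_background(1000, gc = 0.5, seed = 7)
  b <- generate_background(1000, gc = 0.5, seed = 7)
  expect_identical(as.character(a), as.character(b))
  expect_error(generate_background(0, gc = 0.5, seed = 1))

  g <- generate_background(1e6, gc = 0.5, seed = 21)
  gc_obs <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 1e6
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 1e6))

  gg <- generate_background(5000, gc = 0.5, seed = 2,
                            gaps = data.frame(start = 100, length = 50))
  expect_equal(as.character(Biostrings::subseq(gg[[1]], 100, 149)),
               strrep("N", 50))
})

test_that("planting nothing leaves the genome unchanged", {
  bg <- generate_background(1e4, gc = 0.5, seed = 4)
  sp <- plant_spec(n_intact = 0, n_solo = 0, n_intact_notsd = 0,
                   n_solo_notsd = 0, seed = 1)
  out <- plant_elements(bg, sp)
  expect_identical(as.character(out$genome), as.character(bg))
  expect_equal(nrow(out$manifest), 0)
})

test_that("planting is deterministic and conserves sequence length", {
  bg <- generate_background(4e5, gc = 0.4, seed = 8)
  sp <- plant_spec(n_intact = 6, n_solo = 2, n_intact_notsd = 1,
                   n_solo_notsd = 1, n_complex = 1, seed = 33)
  a <- plant_elements(bg, sp)
  b <- plant_elements(bg, sp)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$manifest, b$manifest)

  m <- a$manifest
  tsd_extra <- sum(nchar(m$tsd[!is.na(m$tsd)]))
  body <- sum(m$end - m$start + 1)
  expect_equal(Biostrings::width(a$genome),
               Biostrings::width(bg) + body + tsd_extra)
  # manifest spans are non-overlapping and carried by the genome
  m <- m[order(m$start), ]
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$end[-nrow(m)] < m$start[-1]))
})

test_that("planted LTR pairs realize the requested divergence", {
  bg <- generate_background(6e5, gc = 0.4, seed = 12)
  sp <- plant_spec(n_intact = 10, n_solo = 0, n_intact_notsd = 0,
                   n_solo_notsd = 0, target_K = 0.026, seed = 9)
  m <- plant_elements(bg, sp)$manifest
  expect_equal(nrow(m), 10)
  expect_lt(abs(mean(m$realized_K) - 0.026), 0.005)
})

test_that("a complex plant carries the requested number of LTR copies", {
  bg <- generate_background(2e5, gc = 0.4, seed = 14)
  sp <- plant_spec(n_intact = 0, n_solo = 0, n_intact_notsd = 0,
                   n_solo_notsd = 0, n_complex = 1, complex_n_ltrs = 3,
                   seed = 5)
  m <- plant_elements(bg, sp)$manifest
  expect_equal(m$n_ltrs, 3)
  expect_equal(m$category, "complex")
})

test_that("infeasible packing fails loudly", {
  bg <- generate_background(1e4, gc = 0.5, seed = 4)
  sp <- plant_spec(n_intact = 50, min_flank = 2000, seed = 2)
  expect_error(plant_elements(bg, sp), "infeasible packing")
})

test_that("genome divergence keeps orthologous loci and deletes the rest", {
  bg <- generate_background(6e5, gc = 0.4, seed = 19)
  sp <- plant_spec(n_intact = 8, n_solo = 2, n_intact_notsd = 0,
                   n_solo_notsd = 0, target_K = 0.02, seed = 27)
  pl <- plant_elements(bg, sp)

  # fraction 1, no point divergence: genome B identical at insertion loci
  d0 <- diverge_genomes(pl$genome, pl$manifest, ortholog_fraction = 1,
                        point_divergence = 0, seed = 3)
  expect_identical(as.character(d0$genome_b), as.character(pl$genome))
  expect_equal(nrow(d0$manifest_b), nrow(pl$manifest))

  # fraction 0: every insertion excised cleanly -> background restored
  dall <- diverge_genomes(pl$genome, pl$manifest, ortholog_fraction = 0,
                          point_divergence = 0, seed = 3)
  expect_identical(as.character(dall$genome_b), as.character(bg))

  # expected inter-genome divergence at ortholog LTRs ~ 2 * point div
  dv <- diverge_genomes(pl$genome, pl$manifest, ortholog_fraction = 1,
                        point_divergence = 0.01, seed = 8)
  ka <- vapply(seq_len(nrow(dv$manifest_a)), function(i) {
    a <- substr(as.character(dv$genome_a[[1]]), dv$manifest_a$ltr5_start[i],
                dv$manifest_a$ltr5_end[i])
    b <- substr(as.character(dv$genome_b[[1]]), dv$manifest_b$ltr5_start[i],
                dv$manifest_b$ltr5_end[i])
    ltr_divergence(a, b)$K
  }, numeric(1))
  expect_lt(abs(mean(ka) - 0.02), 0.006)
})

test_that("ortholog retention follows the requested fraction", {
  bg <- generate_background(3e6, gc = 0.4, seed = 23)
  sp <- plant_spec(n_intact = 60, n_solo = 20, n_intact_notsd = 10,
                   n_solo_notsd = 10, seed = 31)
  pl <- plant_elements(bg, sp)
  dv <- diverge_genomes(pl$genome, pl$manifest, ortholog_fraction = 0.5,
                        point_divergence = 0, seed = 13)
  n_kept <- sum(!is.na(dv$manifest_a$ortholog_id))
  expect_equal(n_kept, nrow(dv$manifest_b))
  expect_lt(abs(n_kept - 50), 3 * sqrt(100 * 0.25) + 1)
})

test_that("gene pairs honour the omega and ks targets in the limits", {
  p0 <- generate_gene_pairs(10, ks_target = 0, omega = 0.5, codons = 100,
                            seed = 3)
  expect_identical(as.character(p0$a), as.character(p0$b))

  ps <- generate_gene_pairs(20, ks_target = 0.03, omega = 0, codons = 200,
                            seed = 4)
  kk <- kaks_table(ps)
  expect_true(all(kk$Ka == 0))
  expect_true(any(kk$Ks > 0))
})
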