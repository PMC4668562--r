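# A mid-sized planted genome shared by the detection tests.
annot_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bg <- generate_background(1.2e6, gc = 0.4, seed = 51)
      sp <- plant_spec(n_intact = 14, n_solo = 5, n_intact_notsd = 3,
                       n_solo_notsd = 3, n_complex = 1, target_K = 0.02,
                       seed = 77)
      pl <- plant_elements(bg, sp)
      cache <<- list(genome = pl$genome, manifest = pl$manifest,
                     elements = annotate_genome(pl$genome))
    }
    cache
  }
})

test_that("TSD detection honours the one-mismatch rule and length order", {
  core <- strrep("G", 30)
  # exact 5-bp duplication; neighbours break any 6-bp extension
  s <- paste0("AAAAAATACGT", core, "TACGTCCCCCC")
  hit <- detect_tsd(s, 12, 41, detection_params())
  expect_equal(hit$tsd, "TACGT")
  expect_equal(hit$mismatch, 0)

  # one mismatch accepted
  s2 <- paste0("AAAAAATACGT", core, "TACCTCCCCCC")
  hit2 <- detect_tsd(s2, 12, 41, detection_params())
  expect_equal(hit2$mismatch, 1)
  expect_equal(nchar(hit2$tsd), 5)

  # two mismatches at every length: rejected
  s3 <- paste0("AAAAAATACGT", core, "TGGCTCCCCCC")
  p_nojit <- detection_params(tsd_jitter = 0)
  expect_null(detect_tsd(s3, 12, 41, p_nojit))

  # contig edge: no flank, no TSD
  expect_null(detect_tsd(core, 1, 30, p_nojit))
})

test_that("structural categories follow LTR count and TSD presence", {
  expect_equal(classify_structure(2, TRUE), "IT")
  expect_equal(classify_structure(2, FALSE), "InT")
  expect_equal(classify_structure(1, TRUE), "ST")
  expect_equal(classify_structure(1, FALSE), "SnT")
  expect_equal(classify_structure(3, TRUE), "complex")
  expect_error(classify_structure(0, TRUE), "malformed")
})

test_that("planted elements are recovered with near-exact boundaries", {
  fx <- annot_fixture()
  ev <- evaluate_against_truth(fx$elements, fx$manifest)
  pc <- ev$per_category
  it <- pc[pc$category == "IT", ]
  # at n = 14 a single boundary accident costs 7%; the 0.95 bar is
  # enforced on the 40-element genome in the acceptance suite
  expect_gte(it$recall, 0.9)
  expect_gte(it$precision, 0.9)
  expect_lte(ev$boundary_mae, 5)
  st <- pc[pc$category == "ST", ]
  expect_gte(st$recall, 0.8)
  # category counts partition all calls
  expect_equal(sum(table(fx$elements$category)), nrow(fx$elements))
})

test_that("detection is deterministic", {
  fx <- annot_fixture()
  again <- annotate_genome(fx$genome)
  expect_identical(again, fx$elements)
})

test_that("a repeat-free genome yields no calls", {
  g <- generate_background(2e5, gc = 0.5, seed = 61)
  expect_equal(nrow(find_intact_candidates(g)), 0)
  expect_equal(nrow(annotate_genome(g)), 0)
})

test_that("reported spans never exceed 10% N", {
  fx <- annot_fixture()
  seqs <- as.character(fx$genome)
  fr <- vapply(seq_len(nrow(fx$elements)), function(i) {
    s <- substr(seqs[[fx$elements$seq_id[i]]], fx$elements$start[i],
                fx$elements$end[i])
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1))
  expect_true(all(fr <= 0.10))
})

test_that("two same-family elements 100 bp apart are not merged", {
  set.seed(91)
  ltr <- rand_dna(300)
  internal <- rand_dna(1200)
  tsd1 <- "TACGTC"; tsd2 <- "GATTAC"
  e1 <- paste0(ltr, internal, mutate_exact(ltr, 6))
  e2 <- paste0(mutate_exact(ltr, 3), mutate_exact(internal, 12),
               mutate_exact(ltr, 9))
  g <- Biostrings::DNAStringSet(c(chrA = paste0(
    rand_dna(3000), tsd1, e1, tsd1, rand_dna(100), tsd2, e2, tsd2,
    rand_dna(3000))))
  calls <- annotate_genome(g)
  calls <- calls[calls$n_ltrs == 2, ]
  expect_equal(nrow(calls), 2)
  expect_equal(sort(calls$tsd), sort(c(tsd1, tsd2)))
  expect_true(all(calls$category == "IT"))
  expect_lte(abs(calls$start[1] - 3007), 3)
})

test_that("solo LTRs are found by homology on both strands", {
  set.seed(95)
  ltr <- rand_dna(400)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ltr)))
  far <- mutate_exact(ltr, 120)  # ~70% identity: below threshold
  g <- Biostrings::DNAStringSet(c(chrA = paste0(
    rand_dna(2000), mutate_exact(ltr, 8), rand_dna(2000), rc,
    rand_dna(2000), far, rand_dna(2000))))
  lib <- c(lib1 = ltr)
  solos <- find_homology_elements(g, lib, called = NULL)
  expect_equal(nrow(solos), 2)
  expect_setequal(solos$strand, c("+", "-"))
  # the 70% copy is not reported
  expect_false(any(abs(solos$start - 6801) < 200))
})

test_that("periodic multi-LTR loci are merged into complex calls", {
  fx <- annot_fixture()
  cx_truth <- fx$manifest[fx$manifest$category == "complex", ]
  cx_call <- fx$elements[fx$elements$category == "complex", ]
  expect_equal(nrow(cx_call), 1)
  expect_equal(cx_call$n_ltrs, cx_truth$n_ltrs)

  # five-copy locus, built directly
  set.seed(97)
  ltr <- rand_dna(250); int <- rand_dna(500); tsd <- "CATTGA"
  unit <- paste0(ltr, int)
  locus <- paste0(strrep(unit, 4), ltr)
  g <- Biostrings::DNAStringSet(c(chrA = paste0(
    rand_dna(3000), tsd, locus, tsd, rand_dna(3000))))
  calls <- annotate_genome(g)
  expect_equal(calls$category, "complex")
  expect_equal(calls$n_ltrs, 5)
})
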