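test_that("pairwise JC distances follow the closed form and the cap", {
  set.seed(73)
  a <- rand_dna(200)
  b <- mutate_exact(a, 10)            # p = 0.05
  sat <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  D <- pairwise_distances(c(x = a, y = b, z = a))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D["x", "z"], 0)
  expect_equal(round(D["x", "y"], 4), 0.0517)
  expect_true(isSymmetric(unname(D)))
})

test_that("the three-taxon NJ tree matches the closed form", {
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.05, 0.15, 0.25))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
  D2 <- D; D2[1, 2] <- 0.9
  expect_error(nj_tree(D2), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(79)
  for (i in 1:25) {
    am <- random_additive_matrix(sample(6:10, 1))
    tr <- nj_tree(am$D)
    expect_equal(ape::dist.topo(ape::unroot(am$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    pd <- ape::cophenetic.phylo(tr)[rownames(am$D), colnames(am$D)]
    expect_lt(max(abs(pd - am$D)), 1e-9)
  }
})

test_that("emitted Newick round-trips topology and branch lengths", {
  set.seed(83)
  am <- random_additive_matrix(8)
  tr <- nj_tree(am$D)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  pd1 <- ape::cophenetic.phylo(tr); pd2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(pd1 - pd2[rownames(pd1), colnames(pd1)])), 1e-9)
})

test_that("lineage assignment finds the seeding reference", {
  refs <- bundled_lineage_refs()
  set.seed(89)
  for (pick in c(which(refs$lineage == "Ale"),
                 which(refs$lineage == "Athila"))) {
    fam_rt <- mutate_exact(refs$seq[pick],
                           round(0.05 * nchar(refs$seq[pick])))
    res <- assign_lineage(fam_rt, refs$superfamily[pick], refs)
    expect_equal(res$lineage, refs$lineage[pick])
    expect_lt(res$distance, 0.15)
  }
  # no RT region (e.g. a TRIM family): unassigned
  expect_equal(assign_lineage(NA_character_, "TRIM")$lineage, "unassigned")
  # reference order does not change the call
  res1 <- assign_lineage(mutate_exact(refs$seq[1], 10), "Copia", refs)
  res2 <- assign_lineage(mutate_exact(refs$seq[1], 10), "Copia",
                         refs[rev(seq_len(nrow(refs))), ])
  expect_equal(res1$lineage, res2$lineage)
})

test_that("RT regions extracted from planted internals carry the lineage", {
  bg <- generate_background(6e5, gc = 0.4, seed = 91)
  sp <- plant_spec(n_intact = 8, n_solo = 0, n_intact_notsd = 0,
                   n_solo_notsd = 0, n_families = 3,
                   superfamily_profile = c(Copia = 0.5, Gypsy = 0.5,
                                           TRIM = 0, LARD = 0),
                   seed = 92)
  pl <- plant_elements(bg, sp)
  el <- annotate_genome(pl$genome)
  cls <- classify_elements(el, pl$genome)
  fams <- assign_lineages(cls$families)
  # every autonomous family resolves to the planted lineage
  ev <- evaluate_against_truth(cls$elements, pl$manifest)
  mt <- ev$matches
  fam_of_truth <- split(pl$manifest$lineage[mt$truth],
                        cls$elements$family_id[mt$call])
  for (fid in names(fam_of_truth)) {
    planted <- unique(stats::na.omit(fam_of_truth[[fid]]))
    if (length(planted) == 1) {
      expect_equal(fams$lineage[fams$family_id == fid], planted)
    }
  }
})
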