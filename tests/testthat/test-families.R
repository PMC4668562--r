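fake_elements <- function(seqs) {
  n <- length(seqs)
  data.frame(element_id = sprintf("E%02d", seq_len(n)), seq_id = "c1",
             start = seq_len(n) * 1e4, end = seq_len(n) * 1e4 + 5000,
             ltr5_seq = seqs, internal_start = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("family linkage follows the 80-80-80 single-linkage rule", {
  set.seed(7)
  a <- rand_dna(300)
  b <- mutate_exact(a, 36)   # ~88% to a
  c <- mutate_exact(b, 36)   # ~88% to b, ~77% to a
  far <- mutate_exact(a, 90) # 70%: unlinked
  el <- cluster_families(fake_elements(c(a, a, far)))
  expect_equal(el$family_id[1], el$family_id[2])
  expect_false(el$family_id[1] == el$family_id[3])

  chain <- cluster_families(fake_elements(c(a, b, c)))
  expect_equal(length(unique(chain$family_id)), 1)
})

test_that("clustering is invariant to element input order", {
  set.seed(13)
  fams <- lapply(1:3, function(i) rand_dna(350))
  seqs <- unlist(lapply(fams, function(f) {
    replicate(3, mutate_exact(f, 10))
  }))
  el1 <- cluster_families(fake_elements(seqs))
  perm <- sample(length(seqs))
  el2 <- cluster_families(fake_elements(seqs[perm]))
  # same partition up to labels
  expect_equal(mclust::adjustedRandIndex(el1$family_id[perm],
                                         el2$family_id), 1)
})

test_that("consensus building is majority-rule with ties to the alphabet", {
  expect_equal(build_consensus("ACGT"), "ACGT")
  m <- c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAGAAAAA")
  expect_equal(build_consensus(m), "AAAAAAAAAA")
  # planted family: consensus recovers the ancestor
  set.seed(17)
  anc <- rand_dna(400)
  members <- replicate(7, mutate_exact(anc, 8))
  cons <- build_consensus(members)
  d <- ltr_divergence(cons, anc)
  expect_lt(d$p, 0.01)
})

test_that("superfamily assignment reads domain order and structure", {
  motifs <- bundled_motifs()
  set.seed(19)
  ct <- ltrscape:::codon_table()
  rt_c <- ltrscape:::reverse_translate(
    motifs$peptide[motifs$superfamily == "Copia" & motifs$domain == "RT"])
  int_c <- ltrscape:::reverse_translate(
    motifs$peptide[motifs$superfamily == "Copia" & motifs$domain == "INT"])
  rt_g <- ltrscape:::reverse_translate(
    motifs$peptide[motifs$superfamily == "Gypsy" & motifs$domain == "RT"])
  int_g <- ltrscape:::reverse_translate(
    motifs$peptide[motifs$superfamily == "Gypsy" & motifs$domain == "INT"])
  copia_int <- paste0(rand_dna(300), int_c, rand_dna(200), rt_c,
                      rand_dna(300))
  gypsy_int <- paste0(rand_dna(300), rt_g, rand_dna(200), int_g,
                      rand_dna(300))
  expect_equal(assign_superfamily(copia_int, 6000), "Copia")
  expect_equal(assign_superfamily(gypsy_int, 6000), "Gypsy")
  expect_equal(assign_superfamily(rand_dna(5000), 6000), "LARD")
  expect_equal(assign_superfamily(rand_dna(600), 1800), "TRIM")
  expect_equal(assign_superfamily(rand_dna(2000), 3000), "unknown")
})

test_that("planted families and superfamilies are recovered end-to-end", {
  bg <- generate_background(8e5, gc = 0.4, seed = 71)
  sp <- plant_spec(n_intact = 12, n_solo = 4, n_intact_notsd = 0,
                   n_solo_notsd = 0, n_families = 4, seed = 55)
  pl <- plant_elements(bg, sp)
  el <- annotate_genome(pl$genome)
  cls <- classify_elements(el, pl$genome)
  ev <- evaluate_against_truth(cls$elements, pl$manifest)
  expect_gte(ev$family_ari, 0.95)
  # called superfamilies match the planted ones on matched intact calls
  mt <- ev$matches
  both <- mt[cls$elements$n_ltrs[mt$call] >= 2, ]
  called_sf <- cls$elements$superfamily[both$call]
  truth_sf <- pl$manifest$superfamily[both$truth]
  expect_gte(mean(called_sf == truth_sf), 0.9)
})

test_that("structural ratios reproduce the published table arithmetic", {
  expect_equal(structural_ratio(1326, 948, 241, 160), "0.71")
  expect_equal(structural_ratio(20, 175, 7, 12), "6.93")
  expect_equal(structural_ratio(0, 5, 0, 0), "/")
})

test_that("the superfamily summary satisfies the partition identity", {
  fx <- data.frame(category = sample(c("IT", "ST", "InT", "SnT"), 200,
                                     replace = TRUE,
                                     prob = c(.45, .4, .08, .07)),
                   superfamily = sample(c("Copia", "Gypsy"), 200, TRUE),
                   family_id = sample(sprintf("F%02d", 1:9), 200, TRUE),
                   age_my = runif(200, 0, 4))
  s <- summarize_superfamilies(fx)
  tot <- s[s$group == "Total", ]
  expect_equal(tot$subtotal, 200)
  expect_equal(sum(s$subtotal[s$group != "Total"]), 200)
  # ratio column recomputes from the counts in the same row
  for (i in seq_len(nrow(s))) {
    expect_equal(s$ratio[i], structural_ratio(s$IT[i], s$ST[i],
                                              s$InT[i], s$SnT[i]))
  }
})
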