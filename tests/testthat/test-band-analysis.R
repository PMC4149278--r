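test_that("band collation follows single-linkage with relative tolerance", {
  # one individual, three well-separated bands: three singleton clusters
  cl <- collate_bands(list(band_pattern("a", "case", c(1000, 2000, 4000))))
  expect_equal(nrow(cl$clusters), 3)
  expect_equal(cl$clusters$n_bands, c(1L, 1L, 1L))

  # 2000 vs 2010 at 2% tolerance: one cluster of two
  cl2 <- collate_bands(list(band_pattern("a", "case", 2000),
                            band_pattern("b", "control", 2010)),
                       rel_tolerance = 0.02)
  expect_equal(nrow(cl2$clusters), 1)
  expect_equal(cl2$clusters$n_bands, 2L)
  expect_equal(cl2$clusters$representative, 2005)
  expect_equal(cl2$clusters$n_individuals, 2L)

  # just outside tolerance: two clusters
  cl3 <- collate_bands(list(band_pattern("a", "case", 2000),
                            band_pattern("b", "control", 2050)),
                       rel_tolerance = 0.02)
  expect_equal(nrow(cl3$clusters), 2)

  expect_error(collate_bands(list(), rel_tolerance = 0.5), "rel_tolerance")
})

test_that("collation is invariant to lane order and empty lanes", {
  set.seed(3)
  pats <- lapply(1:10, function(i)
    band_pattern(sprintf("i%02d", i), "case",
                 sample(c(1000, 1500, 2300, 3600), sample(1:4, 1))))
  base <- collate_bands(pats)
  shuffled <- collate_bands(pats[sample(10)])
  expect_equal(base$clusters, shuffled$clusters)
  with_empty <- collate_bands(c(pats, list(band_pattern("empty", "control",
                                                        numeric(0)))))
  expect_equal(base$clusters, with_empty$clusters)
  # no cluster counts an individual twice
  expect_true(all(base$clusters$n_individuals <=
                    length(unique(base$members$id))))
})

test_that("cluster classification applies size match then PCR concordance", {
  pats <- list(band_pattern("a", "case", c(2076, 5000)),
               band_pattern("b", "control", 2080),
               band_pattern("c", "case", 990))
  cl <- collate_bands(pats)
  preds <- data.frame(locus_id = c("locus_a", "locus_b"), size = c(2076, 1000))

  # without PCR: size match alone assigns known
  ann <- classify_clusters(cl, preds)
  cls <- ann$clusters[order(ann$clusters$representative), ]
  expect_equal(cls$classification, c("known", "known", "novel"))
  expect_equal(cls$locus_id, c("locus_b", "locus_a", NA))

  # concordant PCR vector confirms; discordant demotes to ambiguous
  pcr_good <- data.frame(id = c("a", "b", "c"), locus_id = "locus_a",
                         carrier = c(TRUE, TRUE, FALSE))
  ann2 <- classify_clusters(cl, preds["1", ], pcr_carriers = pcr_good)
  k <- ann2$clusters[ann2$clusters$representative == 2078, ]
  expect_equal(k$classification, "known")

  pcr_bad <- data.frame(id = c("a", "b", "c"), locus_id = "locus_a",
                        carrier = c(TRUE, FALSE, FALSE))
  ann3 <- classify_clusters(cl, preds["1", ], pcr_carriers = pcr_bad)
  k3 <- ann3$clusters[ann3$clusters$representative == 2078, ]
  expect_equal(k3$classification, "ambiguous")

  # two predictions within tolerance of one cluster: ambiguous
  preds2 <- data.frame(locus_id = c("x", "y"), size = c(2076, 2080))
  ann4 <- classify_clusters(cl, preds2)
  k4 <- ann4$clusters[ann4$clusters$representative == 2078, ]
  expect_equal(k4$classification, "ambiguous")
})

test_that("cluster frequencies count individuals once per group", {
  inds <- data.frame(id = c(sprintf("case%02d", 1:25), sprintf("ctrl%02d", 1:25)),
                     group = rep(c("case", "control"), each = 25))
  # planted novel band: 10/25 cases, 11/25 controls (and one fixed band)
  pats <- lapply(seq_len(50), function(i) {
    sizes <- 1500
    if (i <= 10 || (i > 25 & i <= 36)) sizes <- c(sizes, 3700)
    band_pattern(inds$id[i], inds$group[i], sizes)
  })
  freq <- cluster_frequencies(collate_bands(pats), inds)
  novel <- freq[freq$representative == 3700, ]
  expect_equal(c(novel$case_pos, novel$ctrl_pos), c(10, 11))
  expect_equal(c(novel$case_freq, novel$ctrl_freq), c(0.40, 0.44))
  fixed <- freq[freq$representative == 1500, ]
  expect_equal(c(fixed$case_pos, fixed$ctrl_pos), c(25, 25))

  # the novel-band table reproduces the chi-square of its carrier split
  assoc <- association_scan(freq)
  expect_equal(round(assoc$chi2[assoc$representative == 3700], 2), 0.08)
  expect_lt(abs(assoc$p[assoc$representative == 3700] - 0.78), 0.01)

  # permuting individuals leaves the counts unchanged
  freq2 <- cluster_frequencies(collate_bands(pats[sample(50)]), inds)
  expect_equal(freq, freq2)
})

test_that("snp-free simulated cohorts cluster at the predicted fragment sizes", {
  panel <- make_reference_panel(n_elements = 6, n_loci = 4, n_recent = 3,
                                repertoires = c("pro,solo,pre", "pro,pre"),
                                seed = 23)
  enz <- default_enzymes()$BsrI
  probe <- substr(panel$element_seqs[[1]], panel$probe_region[1],
                  panel$probe_region[2])
  cohort <- simulate_cohort(panel, 12, 12, freq = 0.5, seed = 6)
  patterns <- lapply(cohort$individuals$id, function(id)
    digest_pattern(realize_genome(id, cohort, panel), enz, probe, id = id,
                   group = cohort$individuals$group[
                     cohort$individuals$id == id]))
  cl <- collate_bands(patterns)
  preds <- predict_all_fragments(panel, enz)
  carried <- vapply(panel$loci$locus_id, function(l) {
    g <- cohort$genotypes[cohort$genotypes$locus_id == l, ]
    any(g$hap1 %in% c("pro", "tandem") | g$hap2 %in% c("pro", "tandem"))
  }, logical(1))
  expected_sizes <- unique(preds$size[carried])
  expect_equal(nrow(cl$clusters), length(expected_sizes))
  expect_true(all(vapply(cl$clusters$representative, function(r)
    any(abs(r - expected_sizes) < 0.02 * r), logical(1))))

  # presence counts match the simulation's carrier ledger per locus
  ann <- classify_clusters(cl, preds)
  freq <- cluster_frequencies(ann, cohort$individuals)
  for (i in which(!is.na(freq$locus_id))) {
    tr <- cohort$carrier_truth[cohort$carrier_truth$locus_id == freq$locus_id[i], ]
    expect_equal(freq$case_pos[i], tr$carriers[tr$group == "case"])
    expect_equal(freq$ctrl_pos[i], tr$carriers[tr$group == "control"])
  }
})
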