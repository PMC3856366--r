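test_that("simulation configs are validated", {
  cfg <- defaultStudyShapedConfig()
  expect_s3_class(cfg, "SimulationConfig")
  expect_equal(cfg$n_replicates, 2L)
  expect_equal(cfg$timepoints_zt, c(0, 12))
  expect_equal(cfg$mirna_timepoints, 6L)
  expect_equal(cfg$n_transcripts, 5000L)

  expect_error(simulationConfig(unstable_fraction = 0),
               class = "patrseq_spec_error")
  expect_error(simulationConfig(noise_sigma = -1),
               class = "patrseq_spec_error")
  expect_error(simulationConfig(planted_set_odds = 0.5),
               class = "patrseq_spec_error")
  expect_error(simulationConfig(polyA_beta_stable = c(0, 1)),
               class = "patrseq_spec_error")
})

test_that("the generator is a pure function of its config", {
  cfg <- simulationConfig(n_transcripts = 300, seed = 42, n_gene_sets = 5,
                          n_mirna_families = 8)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(s1$expression),
                   SummarizedExperiment::assay(s2$expression))
  expect_identical(s1$truth, s2$truth)
  expect_identical(geneSets(s1$geneSets), geneSets(s2$geneSets))
  expect_identical(mirnaTargets(s1$mirnaTargets), mirnaTargets(s2$mirnaTargets))
  expect_identical(s1$mirnaExpression, s2$mirnaExpression)
})

test_that("noise-free data reproduce the generative identities exactly", {
  sim <- simulateDataset(simulationConfig(n_transcripts = 400, seed = 5,
                                          noise_sigma = 0))
  st <- computePatr(sim$expression)
  f <- sim$truth$f_polyA[match(transcriptIds(st), sim$truth$transcript_id)]
  expect_equal(unname(patr(st)), f, tolerance = 1e-12)

  st <- computeIeRatio(sim$signals, st)
  ok <- !is.na(ieRatio(st))
  kdeg <- sim$truth$k_deg[match(transcriptIds(st), sim$truth$transcript_id)]
  expect_equal(cor(ieRatio(st)[ok], kdeg[ok], method = "spearman"), 1)
  expect_equal(cor(patr(st), f, method = "spearman"), 1)
})

test_that("recovery degrades monotonically with measurement noise", {
  rec <- vapply(c(0, 0.5, 1.5), function(s) {
    sim <- simulateDataset(simulationConfig(n_transcripts = 1500, seed = 7,
                                            noise_sigma = s))
    st <- computePatr(sim$expression)
    f <- sim$truth$f_polyA[match(transcriptIds(st), sim$truth$transcript_id)]
    cor(patr(st), f, method = "spearman")
  }, numeric(1))
  expect_true(all(diff(rec) < 0.02))  # non-increasing within MC tolerance
  expect_equal(rec[1], 1, tolerance = 1e-12)
})

test_that("polyA fraction is anti-monotone in degradation rate within class", {
  sim <- simulateDataset(simulationConfig(n_transcripts = 500, seed = 9))
  for (cls in c("stable", "unstable")) {
    sub <- sim$truth[sim$truth$class == cls, ]
    o <- order(sub$k_deg)
    expect_true(all(diff(sub$f_polyA[o]) <= 0))
  }
  expect_true(all(sim$truth$f_polyA > 0 & sim$truth$f_polyA <= 1))
  expect_true(all(sim$truth$k_deg > 0 & sim$truth$k_tx > 0))
})

test_that("planted gene sets and target pools are skewed as configured", {
  sim <- simulateDataset(simulationConfig(n_transcripts = 2000, seed = 13,
                                          planted_set_odds = 6,
                                          target_odds = 4))
  cls <- sim$truth$class
  names(cls) <- sim$truth$transcript_id
  base <- mean(cls == "unstable")
  planted.un <- sim$setTruth$term_id[sim$setTruth$planted &
                                       sim$setTruth$direction == "unstable"][1]
  frac <- mean(cls[sim$geneSets[[planted.un]]] == "unstable")
  expect_gt(frac, base + 0.15)

  pool <- unique(unlist(mirnaTargets(sim$mirnaTargets)))
  expect_gt(mean(cls[pool] == "unstable"), base + 0.1)

  null.sim <- simulateDataset(simulationConfig(n_transcripts = 2000, seed = 13))
  expect_false(any(null.sim$setTruth$planted))
})

test_that("a simulated bundle survives the write/read cycle", {
  sim <- simulateDataset(simulationConfig(n_transcripts = 150, seed = 3,
                                          n_gene_sets = 4, n_mirna_families = 5))
  d <- withr::local_tempdir()
  paths <- writeDatasetBundle(sim, d)
  expr <- readExpressionTable(paths$expression, paths$metadata)
  expect_equal(SummarizedExperiment::assay(expr, "rpkm"),
               SummarizedExperiment::assay(sim$expression, "rpkm"))
  sig <- readFeatureSignals(paths$signals)
  expect_equal(sig$exonic_rpkm, sim$signals$exonic_rpkm)
  expect_identical(geneSets(readGeneSets(paths$gene_sets)),
                   geneSets(sim$geneSets))
  tm <- readMirnaTargets(paths$mirna_targets)
  expect_setequal(names(tm), names(sim$mirnaTargets))
  for (nm in names(tm))
    expect_setequal(tm[[nm]], sim$mirnaTargets[[nm]])
  me <- readMirnaExpression(paths$mirna_expression)
  expect_equal(me$mean_expression, sim$mirnaExpression$mean_expression,
               tolerance = 1e-12)
})
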