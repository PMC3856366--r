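test_that("target partition is the union of family targets and its complement", {
  st <- makeStability(c(1, 2, 3, 4), ids = c("A", "B", "C", "D"))
  tm <- MirnaTargetMap(list(m1 = "A", m2 = c("A", "B"), m3 = c("E", "F")))
  p <- partitionByTargets(st, tm)
  expect_setequal(p$target_set, c("A", "B"))
  expect_setequal(p$nontarget_set, c("C", "D"))
  expect_equal(p$n_families_without_targets, 1L)

  none <- MirnaTargetMap(list(m1 = "ZZ"))
  expect_error(partitionByTargets(st, none), class = "patrseq_coverage_error")
})

test_that("partition sizes always sum to the table size", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    st <- makeStability(rlnorm(n))
    ids <- transcriptIds(st)
    fams <- lapply(1:5, function(j) sample(ids, sample(3:12, 1)))
    names(fams) <- paste0("m", 1:5)
    tm <- MirnaTargetMap(fams)
    p <- partitionByTargets(st, tm)
    expect_equal(length(p$target_set) + length(p$nontarget_set), n)
    expect_length(intersect(p$target_set, p$nontarget_set), 0L)
  }
})

test_that("bootstrap handles degenerate and separated groups", {
  st <- makeStability(rep(2, 10))
  ids <- transcriptIds(st)
  r <- targetsVsNontargetsTest(st, ids[1:5], ids[6:10], b = 200, seed = 4)
  expect_equal(r$bootstrap$observed_diff, 0)
  expect_equal(r$bootstrap$ci_low, 0)
  expect_equal(r$bootstrap$ci_high, 0)
  expect_equal(r$bootstrap$p_value, 1)

  sep <- makeStability(c(1, 1, 1, 5, 5, 5), ids = letters[1:6])
  rs <- targetsVsNontargetsTest(sep, letters[1:3], letters[4:6],
                                b = 500, seed = 4)
  expect_equal(rs$bootstrap$observed_diff, log2(1) - log2(5))
  expect_equal(rs$bootstrap$p_value, 1 / 500)
})

test_that("bootstrap detects a planted median shift and is seed-reproducible", {
  set.seed(79)
  n <- 500
  a <- 2^rnorm(n, -0.5, 0.5)
  b <- 2^rnorm(n, 0, 0.5)
  st <- makeStability(c(a, b))
  ids <- transcriptIds(st)
  r1 <- targetsVsNontargetsTest(st, ids[1:n], ids[(n + 1):(2 * n)],
                                b = 2000, seed = 11)
  expect_lt(r1$bootstrap$p_value, 0.01)
  expect_lt(r1$shift$p_value, 0.01)

  r2 <- targetsVsNontargetsTest(st, ids[1:n], ids[(n + 1):(2 * n)],
                                b = 2000, seed = 11)
  expect_identical(r1, r2)

  r3 <- targetsVsNontargetsTest(st, ids[1:n], ids[(n + 1):(2 * n)],
                                b = 2000, seed = 12)
  expect_equal(r3$bootstrap$observed_diff, r1$bootstrap$observed_diff)
  # Monte-Carlo error only
  expect_lt(abs(r3$bootstrap$ci_low - r1$bootstrap$ci_low), 0.2)
})

test_that("per-family tests flag forced-extreme families and compose", {
  set.seed(83)
  st <- makeStability(rlnorm(500))
  low20 <- names(sort(patr(st)))[1:20]
  rand <- sample(transcriptIds(st), 30)
  tm <- MirnaTargetMap(list(ext = low20, rnd = rand, abs = "none_such"))
  res <- perFamilyTests(st, tm)
  expect_equal(nrow(res), 2L)
  expect_equal(attr(res, "n_excluded"), 1L)
  ext <- res[res$family_id == "ext", ]
  expect_true(ext$lower_than_population)
  expect_lt(ext$fdr, 0.05)
  # p equals the generic shift test on the same set
  direct <- groupShiftTest(st, low20)
  expect_equal(ext$p_value, direct$p_value, tolerance = 1e-12)
})

test_that("random-sample families reject near the nominal rate before FDR", {
  set.seed(89)
  st <- makeStability(rlnorm(400))
  ids <- transcriptIds(st)
  n.rep <- 400
  rejected <- vapply(seq_len(n.rep), function(i) {
    groupShiftTest(st, sample(ids, 40))$p_value < 0.05
  }, logical(1))
  rate <- mean(rejected)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("expression-stability correlation recovers monotone relationships", {
  fam <- data.frame(family_id = paste0("m", 1:10),
                    median_patr = 1:10, stringsAsFactors = FALSE)
  up <- data.frame(family_id = paste0("m", 1:10), mean_expression = (1:10) * 2)
  r <- expressionStabilityCorrelation(fam, up)
  expect_equal(r$spearman_rho, 1)
  down <- data.frame(family_id = paste0("m", 1:10), mean_expression = 11 - (1:10))
  expect_equal(expressionStabilityCorrelation(fam, down)$spearman_rho, -1)

  expect_error(
    expressionStabilityCorrelation(fam[1:2, ], up),
    class = "patrseq_degenerate_error")
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  set.seed(97)
  for (i in 1:15) {
    n <- 50
    fam <- data.frame(family_id = sprintf("m%02d", 1:n),
                      median_patr = sample(rlnorm(n)))
    ex <- data.frame(family_id = sprintf("m%02d", 1:n),
                     mean_expression = sample(c(rlnorm(n - 5), rlnorm(5))))
    r <- expressionStabilityCorrelation(fam, ex)
    expect_equal(r$spearman_rho,
                 spearmanOracle(ex$mean_expression, fam$median_patr),
                 tolerance = 1e-12)
  }
})
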