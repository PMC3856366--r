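test_that("regression recovers exact linear relationships", {
  rpkm <- 2^seq(0.5, 6, length.out = 20)
  lp <- 2 * log2(rpkm) + 1
  st <- makeStability(2^lp, mean_pa = rpkm)
  r <- suppressWarnings(regressStabilityOnExpression(st))  # perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$intercept, 1, tolerance = 1e-10)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  flat <- makeStability(rep(4, 10), mean_pa = 1:10)
  rf <- regressStabilityOnExpression(flat)
  expect_equal(rf$slope, 0)
  expect_equal(rf$r_squared, 0)

  expect_error(regressStabilityOnExpression(makeStability(c(1, 2))),
               class = "patrseq_degenerate_error")
  const.x <- makeStability(c(1, 2, 3), mean_pa = rep(2, 3))
  expect_error(regressStabilityOnExpression(const.x),
               class = "patrseq_degenerate_error")
})

test_that("OLS matches the normal-equation oracle and r^2 = r*r", {
  set.seed(53)
  n <- 500
  rpkm <- exp(runif(n, -1, 5))
  lp <- 0.3 * log2(rpkm) + rnorm(n)
  st <- makeStability(2^lp, mean_pa = rpkm)
  r <- regressStabilityOnExpression(st)
  o <- olsOracle(log2(rpkm), lp)
  expect_equal(r$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(r$intercept, unname(o["intercept"]), tolerance = 1e-10)
  expect_equal(r$r_squared, r$r^2, tolerance = 1e-12)
})

test_that("stratum bounds are inclusive-lower exclusive-upper and partition", {
  set.seed(59)
  rpkm <- c(runif(40, 0.05, 0.999), runif(60, 1, 50))
  st <- makeStability(rlnorm(100), mean_pa = rpkm)
  all.r <- regressStabilityOnExpression(st)
  hi <- regressStabilityOnExpression(st, min_rpkm = 1)
  lo <- regressStabilityOnExpression(st, max_rpkm = 1)
  expect_equal(hi$n + lo$n, all.r$n)
  expect_equal(hi$n, sum(rpkm >= 1))
})

test_that("expression bins follow the half-open interval convention", {
  st <- makeStability(rep(2, 4), mean_pa = c(10.5, 1.5, 1.0, 80.999))
  b <- binByExpression(st)
  expect_identical(names(b)[vapply(b, length, 1L) > 0],
                   c("1-1.5", "10-11", "80-81"))
  expect_identical(names(b[["10-11"]]), "t001")
  expect_identical(names(b[["1-1.5"]]), "t003")  # 1.5 is excluded, 1.0 included

  bad <- data.frame(lower = c(1, 2), upper = c(3, 4),
                    label = c("a", "b"))
  expect_error(binByExpression(st, bad), class = "patrseq_spec_error")
})

test_that("bin membership matches an interval-scan oracle", {
  set.seed(61)
  st <- makeStability(rlnorm(1000), mean_pa = runif(1000, 0, 90))
  bins <- defaultExpressionBins()
  b <- binByExpression(st, bins)
  rpkm <- meanPaRpkm(st)
  for (i in seq_len(nrow(bins))) {
    oracle <- names(rpkm)[rpkm >= bins$lower[i] & rpkm < bins$upper[i]]
    expect_setequal(names(b[[bins$label[i]]]), oracle)
  }
})

test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  same.mean <- list(a = c(1, 3), b = c(2, 2))
  r <- anovaAcrossBins(same.mean, labels = c("a", "b"))
  expect_equal(r$f_statistic, 0)

  sep <- list(a = c(0, 0), b = c(10, 10))
  rs <- anovaAcrossBins(sep, labels = c("a", "b"))
  expect_true(rs$degenerate)
  expect_equal(rs$p_value, 0)

  set.seed(67)
  g <- list(a = rnorm(20), b = rnorm(15, 0.5), c = rnorm(25, -0.3))
  r3 <- anovaAcrossBins(g, labels = c("a", "b", "c"))
  y <- unlist(g); k <- 3; n <- length(y)
  means <- vapply(g, mean, 1); ns <- lengths(g)
  ss.b <- sum(ns * (means - mean(y))^2)
  ss.w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f.oracle <- (ss.b / (k - 1)) / (ss.w / (n - k))
  expect_equal(r3$f_statistic, f.oracle, tolerance = 1e-10)
  expect_equal(r3$p_value, stats::pf(f.oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(anovaAcrossBins(list(a = 1:3), labels = "a"),
               class = "patrseq_degenerate_error")
  expect_error(anovaAcrossBins(list(a = 1:3, b = 2), labels = c("a", "b")),
               class = "patrseq_degenerate_error")
})

test_that("bin shift tests agree with groupShiftTest and detect shifts", {
  set.seed(71)
  lp <- rnorm(300)
  names(lp) <- sprintf("t%03d", 1:300)
  binned <- list(binA = lp[1:40], binB = lp[41:90])
  res <- pairwiseBinShiftTests(binned, lp)
  # compositional identity with the generic shift machinery
  st <- makeStability(2^lp, ids = names(lp))
  direct <- groupShiftTest(st, names(binned$binA))
  expect_equal(res$p_value[res$label == "binA"], direct$p_value,
               tolerance = 1e-12)

  shifted <- lp
  shifted[1:60] <- shifted[1:60] - 5
  binned2 <- list(low = shifted[1:60])
  res2 <- pairwiseBinShiftTests(binned2, shifted)
  expect_lt(res2$p_value, 1e-4)
  expect_identical(res2$direction, "low_patr")
})
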