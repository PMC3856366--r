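test_that("expression filter removes non-coding and bottom-quantile transcripts", {
  pa <- matrix(rep(1:10, 4), 10, 4)
  tr <- matrix(rep(1:10, 4), 10, 4)
  expr <- makePairedExpr(pa, tr)  # summaries 1..10
  filt <- filterTranscripts(expr, 0.20)
  expect_equal(nrow(filt), 8L)
  expect_identical(rownames(filt), sprintf("t%02d", 3:10))
  log <- S4Vectors::metadata(filt)$filter_log
  expect_equal(log$n_lowexpr_removed, 2L)

  nc <- makePairedExpr(pa, tr, biotype = "non_coding")
  expect_error(filterTranscripts(nc), class = "patrseq_degenerate_error")
})

test_that("filter removal matches an independent sort-and-slice oracle", {
  set.seed(3)
  n <- 1000
  pa <- matrix(runif(n * 4, 0, 50), n, 4)
  tr <- matrix(runif(n * 4, 0, 50), n, 4)
  expr <- makePairedExpr(pa, tr)
  for (q in c(0.1, 0.2, 0.35)) {
    filt <- filterTranscripts(expr, q)
    summ <- rowMeans(cbind(pa, tr))
    # oracle: sort the summaries, drop the ceil(n*q) smallest
    keep.ids <- rownames(expr)[order(summ)][-(seq_len(ceiling(n * q)))]
    expect_setequal(rownames(filt), keep.ids)
  }
})

test_that("sample pairing covers each replicate-timepoint combination once", {
  expr <- makePairedExpr(matrix(1, 2, 4), matrix(1, 2, 4))
  pr <- pairSamples(expr)
  expect_equal(nrow(pr), 4L)
  expect_equal(pr$timepoint_zt, c(0, 0, 12, 12))
  expect_equal(pr$replicate, c(1L, 2L, 1L, 2L))
  expect_true(all(startsWith(pr$pa_sample_id, "PA_")))

  single <- makePairedExpr(matrix(1, 2, 1), matrix(1, 2, 1),
                           timepoints = 0, replicates = 1)
  expect_equal(nrow(pairSamples(single)), 1L)

  orphan <- expr[, colnames(expr) != "TR_ZT0_r1"]
  err <- tryCatch(pairSamples(orphan), error = identity)
  expect_s3_class(err, "patrseq_pairing_error")
  expect_match(conditionMessage(err), "PA_ZT0_r1")
})

test_that("PA/TR is the mean of per-sample ratios with log2 transform", {
  expr <- makePairedExpr(matrix(2, 1, 4), matrix(1, 1, 4))
  st <- computePatr(expr)
  expect_equal(unname(sampleRatios(st)[1, ]), rep(2, 4))
  expect_equal(unname(patr(st)), 2)
  expect_equal(unname(logPatr(st)), 1)

  same <- makePairedExpr(matrix(5, 3, 4), matrix(5, 3, 4))
  st <- computePatr(same)
  expect_equal(unname(patr(st)), rep(1, 3))
  expect_equal(unname(logPatr(st)), rep(0, 3))
})

test_that("patr matches a mean-of-elementwise-quotients oracle", {
  set.seed(8)
  n <- 200
  pa <- matrix(runif(n * 4, 0.01, 100), n, 4)
  tr <- matrix(runif(n * 4, 0.01, 100), n, 4)
  st <- computePatr(makePairedExpr(pa, tr))
  oracle <- vapply(seq_len(n), function(i) {
    s <- 0
    for (k in 1:4) s <- s + pa[i, k] / tr[i, k]
    s / 4
  }, numeric(1))
  expect_equal(unname(patr(st)), oracle, tolerance = 1e-12)
  expect_equal(unname(meanPaRpkm(st)), rowMeans(pa), tolerance = 1e-12)
})

test_that("transcripts with zero total-library signal are dropped and logged", {
  pa <- matrix(1, 3, 4)
  tr <- matrix(1, 3, 4)
  tr[2, 3] <- 0
  st <- computePatr(makePairedExpr(pa, tr))
  expect_equal(length(st), 2L)
  expect_false("t02" %in% transcriptIds(st))
  expect_equal(provenance(st)$n_dropped_zero_tr, 1L)
})

test_that("I/E ratio is intron over exon with zero-exon records skipped", {
  st <- makeStability(c(1, 2, 3))
  sig <- data.frame(transcript_id = c("t001", "t002", "t003"),
                    exonic_rpkm = c(4, 5, 0),
                    intronic_rpkm = c(2, 0, 7))
  st2 <- computeIeRatio(sig, st)
  expect_equal(unname(ieRatio(st2)), c(0.5, 0, NA))
  expect_equal(unname(ieRank(st2)), c(2, 1, NA))
  expect_equal(provenance(st2)$ie$n_skipped_zero_denominator, 1L)

  flipped <- computeIeRatio(sig, st, orientation = "exon_over_intron")
  expect_equal(unname(ieRatio(flipped)), c(2, NA, 0))
})

test_that("I/E ranks agree with an independent sort oracle under ties", {
  set.seed(13)
  n <- 100
  st <- makeStability(runif(n))
  ids <- transcriptIds(st)
  sig <- data.frame(transcript_id = ids,
                    exonic_rpkm = sample(1:5, n, TRUE),
                    intronic_rpkm = sample(0:5, n, TRUE))
  st2 <- computeIeRatio(sig, st)
  ratio <- sig$intronic_rpkm / sig$exonic_rpkm
  # oracle: average rank = mean position of equal values in the sort order
  ord <- order(ratio)
  pos <- integer(n); pos[ord] <- seq_len(n)
  oracle <- vapply(seq_len(n), function(i) mean(pos[ratio == ratio[i]]), numeric(1))
  expect_equal(unname(ieRank(st2)), oracle)
})

test_that("extreme-tail selection sizes and determinism", {
  st <- makeStability(sample(100))
  st5 <- selectExtremes(st, 0.05)
  expect_equal(sum(tailFlag(st5) == "top"), 5L)
  expect_equal(sum(tailFlag(st5) == "bottom"), 5L)

  st49 <- selectExtremes(st, 0.499)
  expect_equal(sum(tailFlag(st49) == "top"), 49L)
  expect_equal(sum(tailFlag(st49) == "bottom"), 49L)
  expect_false(any(tailFlag(st49) == "top" & tailFlag(st49) == "bottom"))

  tiny <- makeStability(c(1, 2, 3))
  expect_error(selectExtremes(tiny, 0.05), class = "patrseq_degenerate_error")
})

test_that("tails equal an independent full sort on random records", {
  set.seed(17)
  st <- makeStability(rlnorm(1000))
  st <- selectExtremes(st, 0.05)
  v <- patr(st)
  srt <- sort(v)
  bottom.oracle <- names(v)[v <= srt[50]]
  top.oracle <- names(v)[v >= srt[951]]
  expect_setequal(names(v)[tailFlag(st) == "bottom"], bottom.oracle)
  expect_setequal(names(v)[tailFlag(st) == "top"], top.oracle)
})

test_that("tail rank profiles reproduce forced anti-monotonicity", {
  set.seed(19)
  v <- rlnorm(200)
  st <- makeStability(v)
  ids <- transcriptIds(st)
  sig <- data.frame(transcript_id = ids, exonic_rpkm = 1,
                    intronic_rpkm = 1 / v)  # ie_ratio = 1/patr exactly
  st <- computeIeRatio(sig, st)
  st <- selectExtremes(st, 0.05)
  top <- tailRankProfile(st, "top")
  bottom <- tailRankProfile(st, "bottom")
  expect_lte(top$quartiles[["median"]], bottom$quartiles[["median"]])
  expect_equal(top$n, 10L)
  # profile equals a direct extraction
  direct <- ieRank(st)[tailFlag(st) == "top"]
  expect_equal(sort(top$ranks), sort(direct[!is.na(direct)]))
})

test_that("patr is scale-equivariant in the polyA channel and rank-stable", {
  set.seed(23)
  pa <- matrix(runif(50 * 4, 0.5, 20), 50, 4)
  tr <- matrix(runif(50 * 4, 0.5, 20), 50, 4)
  st1 <- computePatr(makePairedExpr(pa, tr))
  st2 <- computePatr(makePairedExpr(3 * pa, tr))
  expect_equal(unname(patr(st2)), 3 * unname(patr(st1)), tolerance = 1e-12)
  expect_equal(unname(logPatr(st2)), unname(logPatr(st1)) + log2(3),
               tolerance = 1e-12)
  expect_equal(patrRank(st2), patrRank(st1))
})

test_that("patr is invariant to transcript row order", {
  set.seed(29)
  pa <- matrix(runif(40 * 4, 0.5, 20), 40, 4)
  tr <- matrix(runif(40 * 4, 0.5, 20), 40, 4)
  expr <- makePairedExpr(pa, tr)
  perm <- sample(nrow(expr))
  st1 <- computePatr(expr)
  st2 <- computePatr(expr[perm, ])
  ids <- transcriptIds(st1)
  expect_equal(patr(st2)[ids], patr(st1)[ids])
  expect_equal(patrRank(st2)[ids], patrRank(st1)[ids])
})
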