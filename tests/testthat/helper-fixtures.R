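# Small in-code fixtures.

# Paired-design experiment with explicit rpkm values: 2 replicates x
# n_tp timepoints, polyA and total columns interleaved per combination.
makePairedExpr <- function(pa, tr, timepoints = c(0, 12), replicates = 1:2,
                           biotype = "coding", has_introns = TRUE,
                           ids = sprintf("t%02d", seq_len(nrow(pa)))) {
  grid <- expand.grid(replicate = replicates, timepoint_zt = timepoints)
  grid <- grid[order(grid$timepoint_zt, grid$replicate), ]
  stopifnot(ncol(pa) == nrow(grid), ncol(tr) == nrow(grid))
  pa.ids <- sprintf("PA_ZT%g_r%d", grid$timepoint_zt, grid$replicate)
  tr.ids <- sprintf("TR_ZT%g_r%d", grid$timepoint_zt, grid$replicate)
  rpkm <- cbind(pa, tr)
  colnames(rpkm) <- c(pa.ids, tr.ids)
  rownames(rpkm) <- ids
  ann <- data.frame(transcript_id = ids, gene_id = sub("^t", "g", ids),
                    biotype = rep_len(biotype, length(ids)),
                    has_introns = rep_len(has_introns, length(ids)),
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c(pa.ids, tr.ids),
                     library_type = rep(c("polyA", "total"), each = nrow(grid)),
                     replicate = rep(grid$replicate, 2),
                     timepoint_zt = rep(grid$timepoint_zt, 2),
                     stringsAsFactors = FALSE)
  RpkmExperiment(rpkm, ann, meta)
}

# A StabilityTable built directly from a patr vector (single trivial pair).
makeStability <- function(patr, ids = sprintf("t%03d", seq_along(patr)),
                          mean_pa = patr) {
  ratios <- matrix(patr, ncol = 1, dimnames = list(ids, "PA/TR"))
  pairing <- data.frame(pa_sample_id = "PA", tr_sample_id = "TR",
                        timepoint_zt = 0, replicate = 1L,
                        stringsAsFactors = FALSE)
  n <- length(patr)
  st <- S4Vectors::DataFrame(
    patr = patr, log_patr = ifelse(patr > 0, log2(patr), NA_real_),
    patr_rank = rank(patr, ties.method = "average"),
    ie_ratio = rep(NA_real_, n), ie_rank = rep(NA_real_, n),
    mean_pa_rpkm = mean_pa, tail_flag = rep("none", n), row.names = ids)
  methods::new("StabilityTable", stats = st, ratios = ratios,
               pairing = pairing, provenance = list())
}

randomExpr <- function(n = 20, seed = 1) {
  set.seed(seed)
  pa <- matrix(round(runif(n * 4, 0.1, 100), 4), n, 4)
  tr <- matrix(round(runif(n * 4, 0.1, 100), 4), n, 4)
  makePairedExpr(pa, tr,
                 biotype = sample(c("coding", "non_coding"), n, TRUE, c(0.9, 0.1)),
                 has_introns = sample(c(TRUE, FALSE), n, TRUE, c(0.8, 0.2)))
}
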