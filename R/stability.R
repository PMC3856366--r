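#' @include methods.R
NULL

#' Filter to expressed, protein-coding transcripts
#'
#' Removes non-coding transcripts, then removes the lowest-expressed
#' fraction of the coding transcripts. The expression summary is the mean
#' RPKM across all samples (polyA and total pooled), and a transcript is
#' kept when its summary is strictly above the inverse-ECDF empirical
#' quantile of the summaries at \code{bottom_quantile}; on distinct
#' summaries this removes exactly \code{ceiling(n * bottom_quantile)}
#' transcripts.
#'
#' @param expr an \linkS4class{RpkmExperiment}.
#' @param bottom_quantile fraction of lowest-expressed coding transcripts to
#'   drop; default 0.20.
#' @return The filtered \linkS4class{RpkmExperiment}, with filter counts in
#'   \code{metadata()} under \code{filter_log}.
#' @export
filterTranscripts <- function(expr, bottom_quantile = 0.20) {
  stopifnot(is(expr, "RpkmExperiment"))
  if (bottom_quantile < 0 || bottom_quantile >= 1)
    .valueError("bottom_quantile must be in [0, 1); got %g", bottom_quantile)
  coding <- rowData(expr)$biotype == "coding"
  n.noncoding <- sum(!coding)
  if (!any(coding))
    .degenerateError("no coding transcripts left after biotype filter")
  sub <- expr[coding, ]
  summ <- rowMeans(assay(sub, "rpkm"))
  if (bottom_quantile > 0) {
    thr <- .ecdfQuantile(summ, bottom_quantile)
    keep <- summ > thr
  } else {
    thr <- -Inf
    keep <- rep(TRUE, length(summ))
  }
  if (!any(keep))
    .degenerateError("no transcripts remain above the bottom %g quantile",
                     bottom_quantile)
  out <- sub[keep, ]
  metadata(out)$filter_log <- list(
    n_input = nrow(expr), n_noncoding_removed = n.noncoding,
    n_lowexpr_removed = sum(!keep), n_kept = sum(keep),
    bottom_quantile = bottom_quantile, threshold = thr,
    summary = "mean RPKM over all samples (polyA and total pooled)")
  out
}

#' Pair polyA and total samples by replicate and timepoint
#'
#' Each (replicate, timepoint) combination must contribute exactly one
#' polyA-selected and one total (rRNA-depleted) sample; the returned pairs
#' are ordered by (timepoint, replicate).
#'
#' @param expr an \linkS4class{RpkmExperiment}.
#' @return data.frame with columns \code{pa_sample_id}, \code{tr_sample_id},
#'   \code{timepoint_zt}, \code{replicate}.
#' @export
pairSamples <- function(expr) {
  stopifnot(is(expr, "RpkmExperiment"))
  cd <- as.data.frame(colData(expr))
  cd$sample_id <- colnames(expr)
  key <- paste(cd$timepoint_zt, cd$replicate, sep = "|")
  out <- lapply(unique(key), function(k) {
    grp <- cd[key == k, ]
    pa <- grp$sample_id[grp$library_type == "polyA"]
    tr <- grp$sample_id[grp$library_type == "total"]
    if (length(pa) != 1L || length(tr) != 1L)
      .pairingError(
        "replicate %s at ZT%s has %d polyA and %d total sample(s) (samples: %s)",
        grp$replicate[1], grp$timepoint_zt[1], length(pa), length(tr),
        paste(grp$sample_id, collapse = ", "))
    data.frame(pa_sample_id = pa, tr_sample_id = tr,
               timepoint_zt = grp$timepoint_zt[1],
               replicate = grp$replicate[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$timepoint_zt, out$replicate), , drop = FALSE]
}

#' Compute the PA/TR post-transcriptional-control coefficient
#'
#' For every transcript and every paired sample, the polyA RPKM is divided
#' by the total-library RPKM of the same replicate and timepoint; the PA/TR
#' coefficient is the arithmetic mean of these per-sample ratios (ratio
#' first, then mean — not a ratio of summed RPKMs). Transcripts with a zero
#' total-library value in any pair are dropped (the ratio is undefined) and
#' counted in the provenance. \code{log_patr} is log2(patr) where patr > 0,
#' NA otherwise; ranks are ascending with average ranks on ties (rank 1 =
#' lowest PA/TR = strongest post-transcriptional control).
#'
#' @param expr a filtered \linkS4class{RpkmExperiment}.
#' @param pairs sample pairing from \code{\link{pairSamples}}; computed if
#'   omitted.
#' @return A \linkS4class{StabilityTable}.
#' @export
computePatr <- function(expr, pairs = pairSamples(expr)) {
  stopifnot(is(expr, "RpkmExperiment"))
  m <- assay(expr, "rpkm")
  pa <- m[, pairs$pa_sample_id, drop = FALSE]
  tr <- m[, pairs$tr_sample_id, drop = FALSE]
  keep <- rowSums(tr == 0) == 0L
  n.dropped <- sum(!keep)
  if (!any(keep))
    .degenerateError("all transcripts have a zero total-library RPKM in some pair")
  pa <- pa[keep, , drop = FALSE]
  tr <- tr[keep, , drop = FALSE]
  ratios <- pa / tr
  if (any(tr <= 0))
    .patrStop("patrseq_internal_error",
              "zero/negative total RPKM survived the drop step")
  colnames(ratios) <- sprintf("%s/%s", pairs$pa_sample_id, pairs$tr_sample_id)
  patr <- rowMeans(ratios)
  log.patr <- ifelse(patr > 0, log2(patr), NA_real_)
  st <- DataFrame(patr = patr,
                  log_patr = log.patr,
                  patr_rank = .avgRank(patr),
                  ie_ratio = NA_real_, ie_rank = NA_real_,
                  mean_pa_rpkm = rowMeans(pa),
                  tail_flag = "none",
                  row.names = rownames(ratios))
  prov <- list(pairing = pairs, log_base = 2,
               n_dropped_zero_tr = n.dropped,
               averaging = "mean of per-sample PA/TR ratios")
  fl <- metadata(expr)$filter_log
  if (!is.null(fl)) prov$filter_log <- fl
  .newStabilityTable(st, ratios, pairs, prov)
}

#' Attach the intron/exon validation ratio and its ranks
#'
#' The I/E ratio is intronic over exonic total-library signal: intronic
#' reads track nascent transcription, so a high I/E means a large nascent
#' share relative to mature mRNA, i.e. fast turnover. Transcripts with zero
#' exonic signal are skipped (logged, not an error); ranks are ascending
#' with average ranks on ties over transcripts possessing an I/E ratio. An
#' orientation switch is provided because the ratio can also be reported
#' exon-over-intron.
#'
#' @param signals feature-signal data.frame (\code{transcript_id},
#'   \code{exonic_rpkm}, \code{intronic_rpkm}).
#' @param stability a \linkS4class{StabilityTable}.
#' @param orientation \code{"intron_over_exon"} (default) or
#'   \code{"exon_over_intron"}.
#' @return The updated \linkS4class{StabilityTable}.
#' @export
computeIeRatio <- function(signals, stability,
                           orientation = c("intron_over_exon", "exon_over_intron")) {
  stopifnot(is(stability, "StabilityTable"))
  orientation <- match.arg(orientation)
  ids <- rownames(stability@stats)
  sig <- signals[signals$transcript_id %in% ids, , drop = FALSE]
  num <- if (orientation == "intron_over_exon") sig$intronic_rpkm else sig$exonic_rpkm
  den <- if (orientation == "intron_over_exon") sig$exonic_rpkm else sig$intronic_rpkm
  ok <- den > 0
  ratio <- rep(NA_real_, nrow(stability@stats))
  names(ratio) <- ids
  ratio[sig$transcript_id[ok]] <- num[ok] / den[ok]
  st <- stability@stats
  st$ie_ratio <- unname(ratio)
  st$ie_rank <- unname(.avgRank(ratio))
  prov <- stability@provenance
  prov$ie <- list(orientation = orientation,
                  n_with_ratio = sum(ok),
                  n_skipped_zero_denominator = sum(!ok),
                  n_without_signal = sum(!(ids %in% sig$transcript_id)))
  .newStabilityTable(st, stability@ratios, stability@pairing, prov)
}

#' Flag the extreme tails of the PA/TR ranking
#'
#' Marks the \code{floor(fraction * n)} lowest-PA/TR transcripts as
#' \code{bottom} (strongest post-transcriptional control) and the same
#' number of highest as \code{top} (most stable). Ties at a tail boundary
#' are broken by transcript id, lexicographically, so the selection is
#' deterministic.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param fraction tail fraction in (0, 0.5); default 0.05.
#' @return The updated \linkS4class{StabilityTable}.
#' @export
selectExtremes <- function(stability, fraction = 0.05) {
  stopifnot(is(stability, "StabilityTable"))
  if (fraction <= 0 || fraction >= 0.5)
    .valueError("tail fraction must be in (0, 0.5); got %g", fraction)
  st <- stability@stats
  n <- nrow(st)
  k <- floor(fraction * n)
  if (k == 0L)
    .degenerateError("tail fraction %g of %d transcripts selects 0 records",
                     fraction, n)
  ord <- order(st$patr, rownames(st), method = "radix")
  flag <- rep("none", n)
  flag[ord[seq_len(k)]] <- "bottom"
  flag[ord[seq.int(n - k + 1L, n)]] <- "top"
  st$tail_flag <- flag
  prov <- stability@provenance
  prov$tail_fraction <- fraction
  .newStabilityTable(st, stability@ratios, stability@pairing, prov)
}

#' I/E rank profile of a PA/TR tail
#'
#' Extracts the intron/exon ranks of the transcripts in one PA/TR tail.
#' If PA/TR tracks stability, the top tail (most stable) should occupy low
#' I/E ranks (little nascent signal) and the bottom tail high ones.
#'
#' @param stability a \linkS4class{StabilityTable} with tails and I/E ranks
#'   assigned.
#' @param tail \code{"top"} or \code{"bottom"}.
#' @return list with \code{tail}, \code{ranks} (named numeric, NA-free),
#'   \code{n}, and \code{quartiles} (min, q1, median, q3, max).
#' @export
tailRankProfile <- function(stability, tail = c("top", "bottom")) {
  stopifnot(is(stability, "StabilityTable"))
  tail <- match.arg(tail)
  st <- stability@stats
  in.tail <- st$tail_flag == tail
  if (!any(in.tail))
    .degenerateError("no transcripts flagged '%s'; run selectExtremes first", tail)
  r <- st$ie_rank[in.tail]
  names(r) <- rownames(st)[in.tail]
  r <- r[!is.na(r)]
  if (!length(r))
    .degenerateError("'%s' tail has no transcripts with an I/E rank", tail)
  q <- unname(quantile(r, c(0, 0.25, 0.5, 0.75, 1)))
  list(tail = tail, ranks = r, n = length(r),
       quartiles = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]))
}
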