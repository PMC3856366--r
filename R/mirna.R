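#' @include enrichment.R
NULL

#' Partition transcripts into miRNA targets and non-targets
#'
#' The target set is the union of all family target lists intersected with
#' the stability table; the non-target set is its complement within the
#' table. Together they partition the table.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param targets a \linkS4class{MirnaTargetMap}.
#' @return list with character vectors \code{target_set},
#'   \code{nontarget_set}, and \code{n_families_without_targets} (families
#'   whose predicted targets are all absent from the table).
#' @export
partitionByTargets <- function(stability, targets) {
  stopifnot(is(stability, "StabilityTable"), is(targets, "MirnaTargetMap"))
  ids <- rownames(stability@stats)
  in.table <- lapply(targets@targets, function(t) intersect(t, ids))
  tgt <- unique(unlist(in.table, use.names = FALSE))
  if (!length(tgt))
    .coverageError("no predicted miRNA target is present in the stability table")
  list(target_set = tgt,
       nontarget_set = setdiff(ids, tgt),
       n_families_without_targets = sum(lengths(in.table) == 0L))
}

#' Compare miRNA targets with non-targets: Mann-Whitney plus bootstrap
#'
#' Two complementary tests of whether targets are less stable than
#' non-targets, both on log2 PA/TR: (i) a two-sided Mann-Whitney U test;
#' (ii) a stratified case-resampling bootstrap of the difference of group
#' medians (targets minus non-targets): each of \code{b} replicates
#' resamples both groups with replacement at their own sizes, giving a
#' percentile 95\% CI and a two-sided sign-crossing p-value
#' \code{2 * min(frac <= 0, frac >= 0)}, floored at \code{1/b}.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param target_set,nontarget_set transcript-id vectors (see
#'   \code{\link{partitionByTargets}}).
#' @param b number of bootstrap samples; default 10000.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{shift} (Mann-Whitney result: \code{n_targets},
#'   \code{n_nontargets}, \code{u_statistic}, \code{p_value},
#'   \code{median_target}, \code{median_nontarget}, \code{degenerate}) and
#'   \code{bootstrap} (\code{observed_diff}, \code{b}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{seed}).
#' @export
targetsVsNontargetsTest <- function(stability, target_set, nontarget_set,
                                    b = 10000L, seed = 1L) {
  stopifnot(is(stability, "StabilityTable"))
  lp <- logPatr(stability)
  x <- unname(lp[intersect(target_set, names(lp))])
  y <- unname(lp[intersect(nontarget_set, names(lp))])
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    .coverageError("both target and non-target groups must be non-empty")
  if (b < 100L)
    warning("fewer than 100 bootstrap samples; p-value resolution is poor")
  ts <- .shiftTest(x, y)
  obs <- median(x) - median(y)
  diffs <- .withSeed(seed, {
    vapply(seq_len(b), function(i) {
      median(x[sample.int(length(x), replace = TRUE)]) -
        median(y[sample.int(length(y), replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(quantile(diffs, c(0.025, 0.975)))
  p.boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p.boot <- min(1, max(p.boot, 1 / b))
  if (ts$degenerate && obs == 0) p.boot <- 1
  list(
    shift = list(n_targets = length(x), n_nontargets = length(y),
                 u_statistic = ts$u_statistic, p_value = ts$p_value,
                 median_target = median(x), median_nontarget = median(y),
                 degenerate = ts$degenerate),
    bootstrap = list(observed_diff = obs, b = as.integer(b),
                     ci_low = ci[1], ci_high = ci[2],
                     p_value = p.boot, seed = as.integer(seed)))
}

#' Per-family target stability tests
#'
#' For each miRNA family, the PA/TR values of its targets are compared with
#' the complement of the table (two-sided Mann-Whitney); the family's
#' target median is reported and p-values are Benjamini-Hochberg corrected
#' across families. A family is flagged \code{lower_than_population} when
#' its target median falls below the population median and its FDR is below
#' the threshold.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param targets a \linkS4class{MirnaTargetMap}.
#' @param fdr_threshold FDR cutoff for the flag; default 0.05.
#' @return data.frame with one row per tested family: \code{family_id},
#'   \code{family_name}, \code{n_targets_in_table}, \code{median_patr},
#'   \code{u_statistic}, \code{p_value}, \code{fdr},
#'   \code{lower_than_population}; attribute \code{n_excluded} counts
#'   families with no target in the table.
#' @export
perFamilyTests <- function(stability, targets, fdr_threshold = 0.05) {
  stopifnot(is(stability, "StabilityTable"), is(targets, "MirnaTargetMap"))
  ids <- names(targets@targets)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- tryCatch(groupShiftTest(stability, targets@targets[[i]], term_id = ids[i]),
                  patrseq_coverage_error = function(e) NULL)
    if (is.null(r)) next
    rows[[i]] <- data.frame(
      family_id = ids[i], family_name = targets@familyNames[i],
      n_targets_in_table = r$n_in_set, median_patr = r$median_patr,
      u_statistic = r$u_statistic, p_value = r$p_value,
      direction = r$direction, stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    .coverageError("no miRNA family has targets in the stability table")
  out <- do.call(rbind, rows[keep])
  out$fdr <- fdrAdjust(out$p_value)
  out$lower_than_population <- out$direction == "low_patr" &
    out$fdr < fdr_threshold
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Correlate miRNA expression with target stability across families
#'
#' Spearman rank correlation (average ranks on ties) between each family's
#' mean expression and the median PA/TR of its targets; two-sided p-value,
#' exact for n <= 9 without ties, t-approximation otherwise.
#'
#' @param families data.frame from \code{\link{perFamilyTests}} (needs
#'   \code{family_id}, \code{median_patr}).
#' @param expression data.frame from \code{\link{readMirnaExpression}}
#'   (needs \code{family_id}, \code{mean_expression}).
#' @return list with \code{n_families}, \code{spearman_rho}, \code{p_value}.
#' @export
expressionStabilityCorrelation <- function(families, expression) {
  m <- merge(families[, c("family_id", "median_patr")],
             expression[, c("family_id", "mean_expression")],
             by = "family_id")
  n <- nrow(m)
  if (n < 3L)
    .degenerateError("need >= 3 families with both stability and expression; have %d", n)
  no.ties <- !anyDuplicated(m$mean_expression) && !anyDuplicated(m$median_patr)
  ct <- suppressWarnings(
    stats::cor.test(m$mean_expression, m$median_patr, method = "spearman",
                    exact = (n <= 9L && no.ties)))
  list(n_families = n, spearman_rho = unname(ct$estimate),
       p_value = unname(ct$p.value))
}
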