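#' @include enrichment.R
NULL

#' Regress log PA/TR on log2 polyA expression
#'
#' Ordinary least squares of \code{log_patr} on \code{log2(mean_pa_rpkm)},
#' optionally restricted to an expression stratum
#' (\code{min_rpkm <= mean_pa_rpkm < max_rpkm}). Transcripts without a
#' finite log PA/TR or with zero polyA expression are excluded. The three
#' standard strata are all transcripts, those at or above 1 RPKM, and those
#' below 1 RPKM.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param min_rpkm optional inclusive lower bound on mean polyA RPKM.
#' @param max_rpkm optional exclusive upper bound.
#' @return list with \code{n}, \code{slope}, \code{intercept}, \code{r},
#'   \code{r_squared}, \code{p_value} (two-sided, slope != 0).
#' @export
regressStabilityOnExpression <- function(stability, min_rpkm = NULL,
                                         max_rpkm = NULL) {
  stopifnot(is(stability, "StabilityTable"))
  st <- stability@stats
  keep <- is.finite(st$log_patr) & st$mean_pa_rpkm > 0
  if (!is.null(min_rpkm)) keep <- keep & st$mean_pa_rpkm >= min_rpkm
  if (!is.null(max_rpkm)) keep <- keep & st$mean_pa_rpkm < max_rpkm
  x <- log2(st$mean_pa_rpkm[keep])
  y <- st$log_patr[keep]
  if (length(x) < 3L)
    .degenerateError("regression needs >= 3 records; have %d", length(x))
  if (stats::var(x) == 0)
    .degenerateError("expression predictor has zero variance")
  if (stats::var(y) == 0)
    return(list(n = length(x), slope = 0, intercept = y[1],
                r = 0, r_squared = 0, p_value = 1))
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  sm <- summary(fit)
  list(n = length(x),
       slope = unname(co[2]), intercept = unname(co[1]),
       r = stats::cor(x, y), r_squared = unname(sm$r.squared),
       p_value = unname(sm$coefficients[2, 4]))
}

#' Default unit-width expression bins
#'
#' The bins [1, 1.5), [10, 11), then unit bins at each decade step from
#' [20, 21) through [80, 81), on mean polyA RPKM.
#'
#' @return data.frame with columns \code{lower}, \code{upper}, \code{label}.
#' @export
defaultExpressionBins <- function() {
  lo <- c(1, 10, 20, 30, 40, 50, 60, 70, 80)
  hi <- c(1.5, 11, 21, 31, 41, 51, 61, 71, 81)
  data.frame(lower = lo, upper = hi,
             label = sprintf("%g-%g", lo, hi), stringsAsFactors = FALSE)
}

#' Assign transcripts to expression bins
#'
#' Each transcript falls in at most one half-open bin
#' (\code{lower <= mean_pa_rpkm < upper}); overlapping bins are rejected.
#' Returned vectors hold the finite log PA/TR values of each bin's
#' transcripts, named by transcript id; empty bins are returned empty.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param bins data.frame with \code{lower}, \code{upper}, \code{label};
#'   default \code{\link{defaultExpressionBins}()}.
#' @return named list, one numeric vector of log PA/TR per bin label.
#' @export
binByExpression <- function(stability, bins = defaultExpressionBins()) {
  stopifnot(is(stability, "StabilityTable"))
  if (any(bins$lower >= bins$upper))
    .specError("every bin must have lower < upper")
  ord <- order(bins$lower)
  b <- bins[ord, ]
  if (nrow(b) > 1 && any(b$upper[-nrow(b)] > b$lower[-1]))
    .specError("expression bins overlap")
  st <- stability@stats
  ok <- is.finite(st$log_patr)
  rpkm <- st$mean_pa_rpkm
  out <- lapply(seq_len(nrow(bins)), function(i) {
    in.bin <- ok & rpkm >= bins$lower[i] & rpkm < bins$upper[i]
    v <- st$log_patr[in.bin]
    names(v) <- rownames(st)[in.bin]
    v
  })
  names(out) <- bins$label
  out
}

#' One-way ANOVA of log PA/TR across expression bins
#'
#' Fixed-effects one-way ANOVA over the selected bins (default: the unit
#' bins spanning 20-80 RPKM). A zero within-group sum of squares with
#' distinct group means is reported as complete separation: p = 0 with a
#' degenerate flag.
#'
#' @param binned output of \code{\link{binByExpression}}.
#' @param labels bin labels to include; default all labels whose lower bound
#'   is in [20, 80].
#' @return list with \code{k_groups}, \code{group_ns}, \code{f_statistic},
#'   \code{p_value}, \code{degenerate}.
#' @export
anovaAcrossBins <- function(binned, labels = NULL) {
  if (is.null(labels)) {
    lo <- suppressWarnings(as.numeric(sub("-.*$", "", names(binned))))
    labels <- names(binned)[!is.na(lo) & lo >= 20 & lo <= 80]
  }
  miss <- setdiff(labels, names(binned))
  if (length(miss))
    .valueError("unknown bin label(s): %s", paste(miss, collapse = ", "))
  groups <- binned[labels]
  ns <- lengths(groups)
  if (length(groups) < 2L)
    .degenerateError("ANOVA needs >= 2 groups; have %d", length(groups))
  if (any(ns < 2L))
    .degenerateError("every group needs >= 2 values; smallest has %d", min(ns))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  ss.within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (ss.within == 0) {
    sep <- length(unique(tapply(y, g, mean))) > 1L
    return(list(k_groups = length(groups), group_ns = as.integer(ns),
                f_statistic = if (sep) Inf else 0,
                p_value = if (sep) 0 else 1, degenerate = TRUE))
  }
  av <- stats::anova(stats::lm(y ~ g))
  list(k_groups = length(groups), group_ns = as.integer(ns),
       f_statistic = av[["F value"]][1], p_value = av[["Pr(>F)"]][1],
       degenerate = FALSE)
}

#' Mann-Whitney shift test of each bin against the pooled complement
#'
#' Each bin's log PA/TR values are compared (two-sided Mann-Whitney) with
#' the pooled values of all transcripts not in that bin; p-values are
#' Benjamini-Hochberg adjusted across bins.
#'
#' @param binned output of \code{\link{binByExpression}} (named vectors).
#' @param reference named numeric vector of log PA/TR for all transcripts
#'   (names are transcript ids), e.g. \code{logPatr(stability)} without NAs.
#' @return data.frame with \code{label}, \code{n}, \code{median_log_patr},
#'   \code{u_statistic}, \code{p_value}, \code{fdr}, \code{direction}.
#' @export
pairwiseBinShiftTests <- function(binned, reference) {
  reference <- reference[is.finite(reference)]
  med.all <- median(reference)
  rows <- lapply(names(binned), function(lab) {
    x <- binned[[lab]]
    if (!length(x)) return(NULL)
    y <- reference[setdiff(names(reference), names(x))]
    if (!length(y))
      .degenerateError("bin '%s' covers the whole reference", lab)
    ts <- .shiftTest(unname(x), unname(y))
    data.frame(label = lab, n = length(x), median_log_patr = median(x),
               u_statistic = ts$u_statistic, p_value = ts$p_value,
               direction = if (median(x) < med.all) "low_patr" else "high_patr",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) .degenerateError("all bins are empty")
  out$fdr <- fdrAdjust(out$p_value)
  rownames(out) <- NULL
  out
}
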