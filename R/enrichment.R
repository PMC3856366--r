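#' @include methods.R
NULL

## Two-sided Mann-Whitney shared by the shift-test surfaces. Exact p when
## the combined sample is small and tie-free; normal approximation with tie
## and continuity correction otherwise. Returns U for the first group.
.shiftTest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  degenerate <- length(unique(c(x, y))) == 1L
  if (degenerate)
    return(list(u_statistic = nx * ny / 2, p_value = 1, degenerate = TRUE))
  exact <- (nx + ny) <= 20L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(u_statistic = unname(wt$statistic),
       p_value = min(1, unname(wt$p.value)),
       degenerate = FALSE)
}

#' Rank-shift test of a gene set against all other transcripts
#'
#' Two-sided Mann-Whitney U test comparing the PA/TR values of a set's
#' member transcripts against all non-member transcripts in the table.
#' The reported direction says which way the set is shifted:
#' \code{low_patr} (members below the table-wide median, i.e. less stable)
#' or \code{high_patr}.
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param members character vector of member transcript ids; ids absent
#'   from the table are ignored (their count is reported).
#' @param term_id optional label carried into the result.
#' @return list with \code{term_id}, \code{n_in_set}, \code{n_absent},
#'   \code{median_patr}, \code{quartiles} (q1, q3), \code{u_statistic},
#'   \code{p_value}, \code{direction}, \code{degenerate}.
#' @export
groupShiftTest <- function(stability, members, term_id = NA_character_) {
  stopifnot(is(stability, "StabilityTable"))
  v <- patr(stability)
  members <- unique(as.character(members))
  present <- members[members %in% names(v)]
  if (!length(present))
    .coverageError("no member of '%s' is present in the stability table",
                   if (is.na(term_id)) "<set>" else term_id)
  x <- unname(v[present])
  y <- unname(v[setdiff(names(v), present)])
  if (!length(y))
    .degenerateError("set covers the whole table; no comparison group")
  ts <- .shiftTest(x, y)
  qs <- unname(quantile(x, c(0.25, 0.75)))
  list(term_id = term_id,
       n_in_set = length(present),
       n_absent = length(members) - length(present),
       median_patr = median(x),
       quartiles = c(q1 = qs[1], q3 = qs[2]),
       u_statistic = ts$u_statistic,
       p_value = ts$p_value,
       direction = if (median(x) < median(v)) "low_patr" else "high_patr",
       degenerate = ts$degenerate)
}

#' Shift tests for every set in a collection
#'
#' Applies \code{\link{groupShiftTest}} to each set, with Benjamini-Hochberg
#' adjustment across the panel. Sets with no member in the table are
#' excluded (and counted in the \code{n_excluded} attribute).
#'
#' @param stability a \linkS4class{StabilityTable}.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @return data.frame with one row per tested set: \code{term_id},
#'   \code{term_name}, \code{n_in_set}, \code{median_patr}, \code{q1},
#'   \code{q3}, \code{u_statistic}, \code{p_value}, \code{fdr},
#'   \code{direction}.
#' @export
geneSetShiftTests <- function(stability, sets) {
  stopifnot(is(sets, "GeneSetCollection"))
  ids <- names(sets)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- tryCatch(groupShiftTest(stability, sets[[ids[i]]], term_id = ids[i]),
                  patrseq_coverage_error = function(e) NULL)
    if (is.null(r)) next
    rows[[i]] <- data.frame(
      term_id = ids[i], term_name = sets@termNames[i],
      n_in_set = r$n_in_set, median_patr = r$median_patr,
      q1 = r$quartiles[["q1"]], q3 = r$quartiles[["q3"]],
      u_statistic = r$u_statistic, p_value = r$p_value,
      direction = r$direction, stringsAsFactors = FALSE)
  }
  excluded <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    .coverageError("no gene set overlaps the stability table")
  out$fdr <- fdrAdjust(out$p_value)
  out <- out[order(out$fdr, out$p_value), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Hypergeometric over-representation of gene sets in a selection
#'
#' For each term, tests whether the selection (e.g. the bottom-5% PA/TR
#' tail) contains more set members than expected from the expressed
#' background: one-sided upper-tail hypergeometric p = P(X >= overlap) with
#' population = background size, successes = set members in the background,
#' draws = selection size. Set members outside the background are ignored;
#' terms with no member in the background are skipped. Benjamini-Hochberg
#' FDR is computed across the tested terms.
#'
#' @param selection character vector of selected transcript ids; must be a
#'   subset of \code{background}.
#' @param background character vector of expressed transcript ids.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @return data.frame sorted by FDR: \code{term_id}, \code{term_name},
#'   \code{overlap}, \code{set_size_in_background}, \code{selection_size},
#'   \code{background_size}, \code{p_value}, \code{fdr},
#'   \code{neg_log10_fdr}.
#' @export
oraTest <- function(selection, background, sets) {
  stopifnot(is(sets, "GeneSetCollection"))
  selection <- unique(as.character(selection))
  background <- unique(as.character(background))
  if (!all(selection %in% background))
    .valueError("selection contains %d id(s) outside the background",
                sum(!(selection %in% background)))
  N <- length(background); n <- length(selection)
  rows <- lapply(seq_along(sets@sets), function(i) {
    mem <- intersect(sets@sets[[i]], background)
    K <- length(mem)
    if (K == 0L) return(NULL)
    k <- length(intersect(mem, selection))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = names(sets@sets)[i], term_name = sets@termNames[i],
               overlap = k, set_size_in_background = K,
               selection_size = n, background_size = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    .coverageError("no gene set has members in the background")
  out$fdr <- fdrAdjust(out$p_value)
  out$neg_log10_fdr <- -log10(out$fdr)
  out <- out[order(out$fdr, out$p_value), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output preserves input
#' order and length, values capped at 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order.
#' @export
fdrAdjust <- function(p_values) {
  .checkProb(p_values)
  stats::p.adjust(p_values, method = "BH")
}
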