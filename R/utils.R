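## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats median quantile
NULL

## Classed conditions so callers (and tests) can distinguish failure modes.
.patrStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "patrseq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.formatError    <- function(fmt, ...) .patrStop("patrseq_format_error", fmt, ...)
.valueError     <- function(fmt, ...) .patrStop("patrseq_value_error", fmt, ...)
.pairingError   <- function(fmt, ...) .patrStop("patrseq_pairing_error", fmt, ...)
.degenerateError<- function(fmt, ...) .patrStop("patrseq_degenerate_error", fmt, ...)
.coverageError  <- function(fmt, ...) .patrStop("patrseq_coverage_error", fmt, ...)
.specError      <- function(fmt, ...) .patrStop("patrseq_spec_error", fmt, ...)

## Ascending ranks with average ranks on ties (1 = smallest).
.avgRank <- function(x) rank(x, ties.method = "average", na.last = "keep")

## Inverse-ECDF (type 1) empirical quantile: smallest observed value v with
## F(v) >= p. Chosen so that "bottom q" removes exactly ceiling(n*q) values
## when the summaries are distinct, i.e. a deterministic sort-and-slice.
.ecdfQuantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 1, names = FALSE))
}

## Run code with a locally seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

.checkProb <- function(p, what = "p-value vector") {
  if (length(p) == 0L) .valueError("%s is empty", what)
  if (anyNA(p) || any(p < 0 | p > 1))
    .valueError("%s contains values outside [0, 1]", what)
  invisible(p)
}

## Tab-separated writer/reader used for all interchange files: UTF-8, '.'
## decimal separator, full double precision via format(..., digits = 17).
.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) {
    s <- vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    s
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .patrStop("patrseq_io_error", "cannot write '%s': %s",
                             path, conditionMessage(ok))
  invisible(NULL)
}

.readTsv <- function(path, ...) {
  if (!file.exists(path)) .patrStop("patrseq_io_error", "file not found: '%s'", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8", ...)
}
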