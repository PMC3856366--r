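#' @include methods.R
NULL

#' Read an RPKM expression table with sample metadata
#'
#' The expression file is a TSV whose first four columns are
#' \code{transcript_id}, \code{gene_id}, \code{biotype}, \code{has_introns},
#' followed by one numeric RPKM column per sample. The metadata file is a
#' TSV with one row per sample: \code{sample_id}, \code{library_type}
#' (\code{polyA} or \code{total}), \code{replicate}, \code{timepoint_zt}.
#' Sample columns in the expression file are matched to metadata rows and
#' reordered to metadata row order.
#'
#' @param path expression TSV path.
#' @param metadata_path sample metadata TSV path.
#' @return A validated \linkS4class{RpkmExperiment}.
#' @seealso \code{\link{writeExpressionTable}}
#' @export
readExpressionTable <- function(path, metadata_path) {
  df <- .readTsv(path, colClasses = NA)
  need <- c("transcript_id", "gene_id", "biotype", "has_introns")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .formatError("expression table missing column(s): %s", paste(miss, collapse = ", "))
  meta <- .readTsv(metadata_path)
  mneed <- c("sample_id", "library_type", "replicate", "timepoint_zt")
  mmiss <- setdiff(mneed, colnames(meta))
  if (length(mmiss))
    .formatError("sample metadata missing column(s): %s", paste(mmiss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    .formatError("duplicate transcript_id: %s",
                 df$transcript_id[duplicated(df$transcript_id)][1])
  if (anyDuplicated(meta$sample_id))
    .formatError("duplicate sample_id: %s",
                 meta$sample_id[duplicated(meta$sample_id)][1])
  val.cols <- setdiff(colnames(df), need)
  miss.samp <- setdiff(meta$sample_id, val.cols)
  if (length(miss.samp))
    .formatError("sample '%s' in metadata has no expression column", miss.samp[1])
  extra <- setdiff(val.cols, meta$sample_id)
  if (length(extra))
    .formatError("expression column '%s' has no metadata row", extra[1])
  m <- as.matrix(df[, meta$sample_id, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, meta$sample_id, drop = FALSE],
                                              2, as.numeric))), arr.ind = TRUE)
    .valueError("non-numeric RPKM at row %d, sample '%s'",
                bad[1, 1], meta$sample_id[bad[1, 2]])
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    .valueError("missing RPKM at row %d (transcript '%s'), sample '%s'",
                bad[1, 1], df$transcript_id[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    .valueError("negative RPKM at row %d (transcript '%s'), sample '%s'",
                bad[1, 1], df$transcript_id[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  RpkmExperiment(m, df[, need], meta[, mneed])
}

#' Write an RpkmExperiment to expression + metadata TSV files
#'
#' @param expr an \linkS4class{RpkmExperiment}.
#' @param path expression TSV output path.
#' @param metadata_path metadata TSV output path.
#' @return Invisibly, \code{NULL}.
#' @export
writeExpressionTable <- function(expr, path, metadata_path) {
  rd <- rowData(expr)
  df <- data.frame(transcript_id = rownames(expr),
                   gene_id = rd$gene_id,
                   biotype = rd$biotype,
                   has_introns = rd$has_introns,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(assay(expr, "rpkm")))
  .writeTsv(df, path)
  cd <- colData(expr)
  meta <- data.frame(sample_id = colnames(expr),
                     library_type = cd$library_type,
                     replicate = cd$replicate,
                     timepoint_zt = cd$timepoint_zt,
                     stringsAsFactors = FALSE)
  .writeTsv(meta, metadata_path)
  invisible(NULL)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{term_id}, \code{term_name}, then member identifiers. Duplicate
#' members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetCollection}; empty file gives an empty
#'   collection.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) .patrStop("patrseq_io_error", "file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GeneSetCollection(list()))
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .formatError("GMT line %d has %d field(s); at least 3 required", i, length(f))
    ids[i] <- f[1]
    nm[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids))
    .formatError("duplicate term_id in GMT: %s", ids[duplicated(ids)][1])
  names(sets) <- ids
  GeneSetCollection(sets, nm)
}

#' Write gene sets to a GMT file
#'
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param path output GMT path.
#' @return Invisibly, \code{NULL}.
#' @export
writeGeneSets <- function(sets, path) {
  stopifnot(is(sets, "GeneSetCollection"))
  lines <- vapply(seq_along(sets@sets), function(i) {
    paste(c(names(sets@sets)[i], sets@termNames[i], sets@sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(NULL)
}

#' Read a miRNA family -> target table (TargetScanFly-style TSV)
#'
#' Expects a header row and at least a family-identifier column and a target
#' transcript/gene identifier column; extra columns are ignored. Targets are
#' aggregated across rows per family, with set semantics (duplicates
#' collapsed). The identifier columns are configurable because TargetScan
#' releases differ in whether targets are given as gene symbols or
#' transcript ids.
#'
#' @param path TSV path.
#' @param family_col name of the family-id column (default
#'   \code{"miR family"} with \code{"family_id"} as fallback).
#' @param target_col name of the target-id column (default
#'   \code{"Transcript ID"} with \code{"target_id"} as fallback).
#' @param name_col optional column with a display name for the family.
#' @return A \linkS4class{MirnaTargetMap}.
#' @export
readMirnaTargets <- function(path,
                             family_col = c("miR family", "family_id"),
                             target_col = c("Transcript ID", "target_id"),
                             name_col = NULL) {
  df <- .readTsv(path)
  pick <- function(cands, what) {
    hit <- cands[cands %in% colnames(df)]
    if (!length(hit))
      .formatError("miRNA target table lacks a %s column; expected one of: %s",
                   what, paste(cands, collapse = ", "))
    hit[1]
  }
  fc <- pick(family_col, "family identifier")
  tc <- pick(target_col, "target identifier")
  fam <- as.character(df[[fc]])
  tgt <- as.character(df[[tc]])
  keep <- nzchar(fam) & nzchar(tgt)
  targets <- split(tgt[keep], fam[keep])
  nms <- names(targets)
  if (!is.null(name_col) && name_col %in% colnames(df)) {
    lut <- tapply(as.character(df[[name_col]])[keep], fam[keep], function(x) x[1])
    nms <- unname(lut[names(targets)])
  }
  MirnaTargetMap(targets, nms)
}

#' Write a MirnaTargetMap as a two-column TSV
#'
#' @param targets a \linkS4class{MirnaTargetMap}.
#' @param path output path; columns \code{family_id}, \code{target_id}.
#' @return Invisibly, \code{NULL}.
#' @export
writeMirnaTargets <- function(targets, path) {
  stopifnot(is(targets, "MirnaTargetMap"))
  df <- data.frame(
    family_id = rep(names(targets@targets), lengths(targets@targets)),
    target_id = unlist(targets@targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  .writeTsv(df, path)
  invisible(NULL)
}

#' Read summarized miRNA expression across timepoints
#'
#' TSV with a \code{family_id} column plus one numeric column per timepoint
#' (already summarized, e.g. RMA values). The per-family
#' \code{mean_expression} is the arithmetic mean of the timepoint columns.
#'
#' @param path TSV path.
#' @return data.frame with \code{family_id}, the timepoint columns, and
#'   \code{mean_expression}.
#' @export
readMirnaExpression <- function(path) {
  df <- .readTsv(path)
  if (!("family_id" %in% colnames(df)))
    .formatError("miRNA expression table missing 'family_id' column")
  tp <- setdiff(colnames(df), c("family_id", "mean_expression"))
  if (!length(tp))
    .formatError("miRNA expression table has no timepoint columns")
  for (col in tp) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      .valueError("non-numeric expression at row %d, column '%s'", bad, col)
    }
    if (anyNA(v))
      .valueError("missing expression at row %d, column '%s'", which(is.na(v))[1], col)
  }
  out <- df[, c("family_id", tp), drop = FALSE]
  out$mean_expression <- rowMeans(as.matrix(df[, tp, drop = FALSE]))
  out
}

#' Write summarized miRNA expression
#'
#' @param mexpr data.frame as returned by \code{\link{readMirnaExpression}}.
#' @param path output TSV path.
#' @return Invisibly, \code{NULL}.
#' @export
writeMirnaExpression <- function(mexpr, path) {
  .writeTsv(mexpr, path)
  invisible(NULL)
}

#' Read / write per-transcript exonic and intronic signal
#'
#' TSV with columns \code{transcript_id}, \code{exonic_rpkm},
#' \code{intronic_rpkm} (mean over total-library samples). Only transcripts
#' with annotated introns belong in this table.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
readFeatureSignals <- function(path) {
  df <- .readTsv(path)
  need <- c("transcript_id", "exonic_rpkm", "intronic_rpkm")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .formatError("feature signal table missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    .formatError("duplicate transcript_id: %s",
                 df$transcript_id[duplicated(df$transcript_id)][1])
  for (col in c("exonic_rpkm", "intronic_rpkm")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0))
      .valueError("column '%s' must be non-negative finite numeric", col)
  }
  df[, need]
}

#' @rdname readFeatureSignals
#' @param signals data.frame with the three feature-signal columns.
#' @export
writeFeatureSignals <- function(signals, path) {
  .writeTsv(signals[, c("transcript_id", "exonic_rpkm", "intronic_rpkm")], path)
  invisible(NULL)
}

#' Write a StabilityTable to TSV
#'
#' One row per transcript: \code{transcript_id}, \code{patr},
#' \code{log_patr}, \code{patr_rank}, \code{ie_ratio}, \code{ie_rank},
#' \code{mean_pa_rpkm}, \code{tail_flag}, then one
#' \code{ratio:<pa_sample>:<tr_sample>} column per sample pair. Doubles are
#' written at full precision so that read-back reproduces the values
#' exactly.
#'
#' @param table a \linkS4class{StabilityTable}.
#' @param path output TSV path.
#' @return Invisibly, \code{NULL}.
#' @seealso \code{\link{readStabilityTable}}
#' @export
writeStabilityTable <- function(table, path) {
  stopifnot(is(table, "StabilityTable"))
  st <- table@stats
  df <- data.frame(transcript_id = rownames(st),
                   patr = st$patr, log_patr = st$log_patr,
                   patr_rank = st$patr_rank,
                   ie_ratio = st$ie_ratio, ie_rank = st$ie_rank,
                   mean_pa_rpkm = st$mean_pa_rpkm,
                   tail_flag = st$tail_flag,
                   stringsAsFactors = FALSE)
  rat <- table@ratios
  if (ncol(rat)) {
    cn <- sprintf("ratio:%s:%s", table@pairing$pa_sample_id,
                  table@pairing$tr_sample_id)
    rat <- as.data.frame(rat)
    colnames(rat) <- cn
    df <- cbind(df, rat)
  }
  .writeTsv(df, path)
  invisible(NULL)
}

#' Read a StabilityTable written by writeStabilityTable
#'
#' @param path TSV path.
#' @return A \linkS4class{StabilityTable}. Pairing timepoint/replicate
#'   metadata is not stored in the TSV and is returned as NA.
#' @export
readStabilityTable <- function(path) {
  df <- .readTsv(path)
  need <- c("transcript_id", "patr", "log_patr", "patr_rank", "ie_ratio",
            "ie_rank", "mean_pa_rpkm", "tail_flag")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .formatError("stability table missing column(s): %s",
                 paste(miss, collapse = ", "))
  rat.cols <- grep("^ratio:", colnames(df), value = TRUE)
  ratios <- as.matrix(df[, rat.cols, drop = FALSE])
  rownames(ratios) <- df$transcript_id
  parts <- strsplit(sub("^ratio:", "", rat.cols), ":", fixed = TRUE)
  pairing <- data.frame(
    pa_sample_id = vapply(parts, `[`, character(1), 1),
    tr_sample_id = vapply(parts, `[`, character(1), 2),
    timepoint_zt = NA_real_, replicate = NA_integer_,
    stringsAsFactors = FALSE)
  st <- DataFrame(patr = as.numeric(df$patr),
                  log_patr = as.numeric(df$log_patr),
                  patr_rank = as.numeric(df$patr_rank),
                  ie_ratio = as.numeric(df$ie_ratio),
                  ie_rank = as.numeric(df$ie_rank),
                  mean_pa_rpkm = as.numeric(df$mean_pa_rpkm),
                  tail_flag = as.character(df$tail_flag),
                  row.names = df$transcript_id)
  .newStabilityTable(st, ratios, pairing, list(source = path))
}
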