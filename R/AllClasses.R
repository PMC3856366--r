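#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' RpkmExperiment: transcripts x samples RPKM with library metadata
#'
#' Container for paired polyA-selected and total (rRNA-depleted) RNA-seq
#' quantifications. Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"rpkm"} holds non-negative RPKM values, \code{rowData} carries the
#' transcript annotation (\code{gene_id}, \code{biotype} in
#' \code{\{"coding","non_coding"\}}, \code{has_introns}), and \code{colData}
#' the sample metadata (\code{library_type} in \code{\{"polyA","total"\}},
#' \code{replicate}, \code{timepoint_zt} in zeitgeber hours).
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @seealso \code{\link{RpkmExperiment}} (constructor),
#'   \code{\link{readExpressionTable}}, \code{\link{filterTranscripts}}
#' @exportClass RpkmExperiment
setClass("RpkmExperiment", contains = "SummarizedExperiment")

.validRpkmExperiment <- function(object) {
  msgs <- character(0)
  if (!("rpkm" %in% assayNames(object)))
    msgs <- c(msgs, "assay 'rpkm' is required")
  else {
    m <- assay(object, "rpkm")
    if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
      msgs <- c(msgs, "rpkm values must be finite and non-missing")
    else if (any(m < 0))
      msgs <- c(msgs, "rpkm values must be non-negative")
  }
  rd <- rowData(object)
  for (col in c("gene_id", "biotype", "has_introns"))
    if (!(col %in% colnames(rd)))
      msgs <- c(msgs, sprintf("rowData column '%s' is required", col))
  if ("biotype" %in% colnames(rd) &&
      !all(rd$biotype %in% c("coding", "non_coding")))
    msgs <- c(msgs, "biotype must be 'coding' or 'non_coding'")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, sprintf("duplicate transcript_id: %s",
                            rownames(object)[duplicated(rownames(object))][1]))
  cd <- colData(object)
  for (col in c("library_type", "replicate", "timepoint_zt"))
    if (!(col %in% colnames(cd)))
      msgs <- c(msgs, sprintf("colData column '%s' is required", col))
  if ("library_type" %in% colnames(cd) &&
      !all(cd$library_type %in% c("polyA", "total")))
    msgs <- c(msgs, "library_type must be 'polyA' or 'total'")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, sprintf("duplicate sample_id: %s",
                            colnames(object)[duplicated(colnames(object))][1]))
  if (length(msgs)) msgs else TRUE
}
setValidity("RpkmExperiment", .validRpkmExperiment)

#' Construct an RpkmExperiment
#'
#' @param rpkm numeric matrix, transcripts x samples, non-negative RPKM;
#'   rownames are transcript ids, colnames sample ids.
#' @param annotations data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{biotype}, \code{has_introns}, one row per rpkm row.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{library_type}, \code{replicate}, \code{timepoint_zt}, one row per
#'   rpkm column, in column order.
#' @return A validated \linkS4class{RpkmExperiment}.
#' @examples
#' rpkm <- matrix(1:8, 2, 4,
#'                dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
#' ann <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
#'                   biotype = "coding", has_introns = TRUE)
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    library_type = rep(c("polyA", "total"), 2),
#'                    replicate = c(1, 1, 2, 2), timepoint_zt = 0)
#' se <- RpkmExperiment(rpkm, ann, meta)
#' @export
RpkmExperiment <- function(rpkm, annotations, samples) {
  rpkm <- as.matrix(rpkm)
  storage.mode(rpkm) <- "double"
  if (anyDuplicated(annotations$transcript_id))
    .formatError("duplicate transcript_id: %s",
                 annotations$transcript_id[duplicated(annotations$transcript_id)][1])
  if (anyDuplicated(samples$sample_id))
    .formatError("duplicate sample_id: %s",
                 samples$sample_id[duplicated(samples$sample_id)][1])
  if (nrow(rpkm) != nrow(annotations))
    .formatError("rpkm has %d rows but %d annotations", nrow(rpkm), nrow(annotations))
  if (ncol(rpkm) != nrow(samples))
    .formatError("rpkm has %d columns but %d sample metadata rows",
                 ncol(rpkm), nrow(samples))
  rownames(rpkm) <- annotations$transcript_id
  colnames(rpkm) <- samples$sample_id
  rd <- DataFrame(gene_id = annotations$gene_id,
                  biotype = annotations$biotype,
                  has_introns = as.logical(annotations$has_introns),
                  row.names = annotations$transcript_id)
  cd <- DataFrame(library_type = samples$library_type,
                  replicate = as.integer(samples$replicate),
                  timepoint_zt = as.numeric(samples$timepoint_zt),
                  row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(rpkm = rpkm), rowData = rd, colData = cd)
  obj <- new("RpkmExperiment", se)
  v <- .validRpkmExperiment(obj)
  if (!isTRUE(v)) .valueError("%s", paste(v, collapse = "; "))
  obj
}

#' StabilityTable: per-transcript PA/TR stability records
#'
#' Holds the PA/TR coefficient (mean of per-sample polyA/total RPKM ratios),
#' its log2, ascending average-tie ranks, the intron/exon validation ratio
#' and rank where available, a polyA expression summary, and extreme-tail
#' flags, together with the sample pairing and filtering provenance.
#'
#' @slot stats \link[S4Vectors]{DataFrame} with columns \code{patr},
#'   \code{log_patr}, \code{patr_rank}, \code{ie_ratio}, \code{ie_rank},
#'   \code{mean_pa_rpkm}, \code{tail_flag}; rownames are transcript ids.
#' @slot ratios numeric matrix of per-sample PA/TR ratios (transcripts x
#'   pairs); \code{patr} is its row mean.
#' @slot pairing data.frame with columns \code{pa_sample_id},
#'   \code{tr_sample_id}, \code{timepoint_zt}, \code{replicate}, one row per
#'   ratio column.
#' @slot provenance list of processing parameters (filter quantile, log
#'   base, dropped-transcript counts, orientation of the I/E ratio).
#' @seealso \code{\link{computePatr}}, \code{\link{computeIeRatio}},
#'   \code{\link{selectExtremes}}
#' @exportClass StabilityTable
setClass("StabilityTable",
         representation(stats = "DataFrame", ratios = "matrix",
                        pairing = "data.frame", provenance = "list"))

setValidity("StabilityTable", function(object) {
  msgs <- character(0)
  st <- object@stats
  need <- c("patr", "log_patr", "patr_rank", "ie_ratio", "ie_rank",
            "mean_pa_rpkm", "tail_flag")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    msgs <- c(msgs, sprintf("stats columns missing: %s", paste(miss, collapse = ", ")))
  if (nrow(st) != nrow(object@ratios))
    msgs <- c(msgs, "stats and ratios disagree on transcript count")
  if (nrow(object@pairing) != ncol(object@ratios))
    msgs <- c(msgs, "pairing does not cover every ratio column")
  if (nrow(st) > 0 && "patr" %in% colnames(st)) {
    if (max(abs(st$patr - rowMeans(object@ratios))) > 1e-8)
      msgs <- c(msgs, "patr must equal the row mean of per-sample ratios")
    if (!all(st$tail_flag %in% c("top", "bottom", "none")))
      msgs <- c(msgs, "tail_flag must be 'top', 'bottom' or 'none'")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named sets of transcript identifiers
#'
#' GO-term-like flat gene sets mapping a term id to a member set. Members
#' are stored deduplicated; empty sets are rejected.
#'
#' @slot sets named list of character vectors (term_id -> member ids).
#' @slot termNames character vector of human-readable names, parallel to
#'   \code{sets}.
#' @seealso \code{\link{readGeneSets}}, \code{\link{oraTest}},
#'   \code{\link{groupShiftTest}}
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", termNames = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character(0)
  if (length(object@sets) != length(object@termNames))
    msgs <- c(msgs, "sets and termNames lengths differ")
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msgs <- c(msgs, "sets must have unique term ids as names")
    sizes <- lengths(object@sets)
    if (any(sizes == 0L))
      msgs <- c(msgs, "every gene set must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
      msgs <- c(msgs, "gene-set members must be unique within a set")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member transcript ids;
#'   duplicates within a set are collapsed.
#' @param termNames optional character vector of term names (defaults to the
#'   term ids).
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, termNames = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(termNames)) termNames <- names(sets)
  if (is.null(termNames)) termNames <- character(0)
  obj <- new("GeneSetCollection", sets = sets,
             termNames = as.character(termNames))
  validObject(obj)
  obj
}

#' MirnaTargetMap: conserved miRNA families and their predicted targets
#'
#' @slot targets named list of character vectors (family_id -> target
#'   transcript ids), deduplicated and non-empty.
#' @slot familyNames character vector of family names, parallel to
#'   \code{targets}.
#' @seealso \code{\link{readMirnaTargets}}, \code{\link{partitionByTargets}},
#'   \code{\link{perFamilyTests}}
#' @exportClass MirnaTargetMap
setClass("MirnaTargetMap",
         representation(targets = "list", familyNames = "character"))

setValidity("MirnaTargetMap", function(object) {
  msgs <- character(0)
  if (length(object@targets) != length(object@familyNames))
    msgs <- c(msgs, "targets and familyNames lengths differ")
  if (length(object@targets)) {
    if (is.null(names(object@targets)) || anyDuplicated(names(object@targets)))
      msgs <- c(msgs, "targets must have unique family ids as names")
    if (any(lengths(object@targets) == 0L))
      msgs <- c(msgs, "every family's target set must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MirnaTargetMap
#'
#' @param targets named list of character vectors of target ids per family;
#'   duplicates are collapsed.
#' @param familyNames optional family names (defaults to family ids).
#' @return A \linkS4class{MirnaTargetMap}.
#' @export
MirnaTargetMap <- function(targets, familyNames = NULL) {
  targets <- lapply(targets, function(x) unique(as.character(x)))
  if (is.null(familyNames)) familyNames <- names(targets)
  if (is.null(familyNames)) familyNames <- character(0)
  obj <- new("MirnaTargetMap", targets = targets,
             familyNames = as.character(familyNames))
  validObject(obj)
  obj
}
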