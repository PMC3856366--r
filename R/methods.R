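#' @include AllGenerics.R
NULL

.stCol <- function(x, col) {
  v <- x@stats[[col]]
  names(v) <- rownames(x@stats)
  v
}

#' @rdname accessors
#' @export
setMethod("patr", "StabilityTable", function(x) .stCol(x, "patr"))
#' @rdname accessors
#' @export
setMethod("logPatr", "StabilityTable", function(x) .stCol(x, "log_patr"))
#' @rdname accessors
#' @export
setMethod("patrRank", "StabilityTable", function(x) .stCol(x, "patr_rank"))
#' @rdname accessors
#' @export
setMethod("ieRatio", "StabilityTable", function(x) .stCol(x, "ie_ratio"))
#' @rdname accessors
#' @export
setMethod("ieRank", "StabilityTable", function(x) .stCol(x, "ie_rank"))
#' @rdname accessors
#' @export
setMethod("meanPaRpkm", "StabilityTable", function(x) .stCol(x, "mean_pa_rpkm"))
#' @rdname accessors
#' @export
setMethod("tailFlag", "StabilityTable", function(x) .stCol(x, "tail_flag"))
#' @rdname accessors
#' @export
setMethod("sampleRatios", "StabilityTable", function(x) x@ratios)
#' @rdname accessors
#' @export
setMethod("samplePairing", "StabilityTable", function(x) x@pairing)
#' @rdname accessors
#' @export
setMethod("provenance", "StabilityTable", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("transcriptIds", "StabilityTable", function(x) rownames(x@stats))
#' @rdname accessors
#' @export
setMethod("transcriptIds", "RpkmExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("mirnaTargets", "MirnaTargetMap", function(x) x@targets)

#' @describeIn StabilityTable-class number of transcripts
#' @param x a StabilityTable
#' @export
setMethod("length", "StabilityTable", function(x) nrow(x@stats))
#' @describeIn GeneSetCollection-class number of sets
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))
#' @describeIn MirnaTargetMap-class number of families
#' @export
setMethod("length", "MirnaTargetMap", function(x) length(x@targets))

#' @describeIn GeneSetCollection-class term ids
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))
#' @describeIn MirnaTargetMap-class family ids
#' @export
setMethod("names", "MirnaTargetMap", function(x) names(x@targets))

#' @describeIn GeneSetCollection-class extract one member set by term id
#' @param i term or family id (or index)
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])
#' @describeIn MirnaTargetMap-class extract one target set by family id
#' @export
setMethod("[[", "MirnaTargetMap", function(x, i) x@targets[[i]])

setMethod("show", "StabilityTable", function(object) {
  st <- object@stats
  cat(sprintf("StabilityTable with %d transcripts, %d sample pairs\n",
              nrow(st), ncol(object@ratios)))
  if (nrow(st)) {
    cat(sprintf("  patr: median %.4g [%.4g, %.4g]\n",
                median(st$patr), min(st$patr), max(st$patr)))
    cat(sprintf("  I/E ratio available for %d transcripts\n",
                sum(!is.na(st$ie_ratio))))
    cat(sprintf("  tails: %d top, %d bottom\n",
                sum(st$tail_flag == "top"), sum(st$tail_flag == "bottom")))
  }
  pv <- object@provenance
  if (length(pv))
    cat("  provenance:", paste(names(pv), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d sets", length(object@sets)))
  if (length(object@sets))
    cat(sprintf(" (sizes %d..%d)", min(lengths(object@sets)),
                max(lengths(object@sets))))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "MirnaTargetMap", function(object) {
  cat(sprintf("MirnaTargetMap with %d families", length(object@targets)))
  if (length(object@targets))
    cat(sprintf(" (target-set sizes %d..%d)", min(lengths(object@targets)),
                max(lengths(object@targets))))
  cat("\n")
  invisible(NULL)
})

## Assemble a StabilityTable from its parts (internal; validated).
.newStabilityTable <- function(stats, ratios, pairing, provenance) {
  obj <- new("StabilityTable", stats = stats, ratios = ratios,
             pairing = pairing, provenance = provenance)
  validObject(obj)
  obj
}
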