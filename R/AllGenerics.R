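#' @include AllClasses.R
NULL

#' Accessors for stability and set containers
#'
#' \code{patr} returns the PA/TR coefficient (mean polyA/total RPKM ratio);
#' \code{logPatr} its log2 (NA where patr is 0); \code{patrRank} and
#' \code{ieRank} the ascending average-tie ranks; \code{ieRatio} the
#' intron/exon signal ratio (NA where unavailable); \code{meanPaRpkm} the
#' mean polyA-library RPKM; \code{tailFlag} the extreme-tail assignment;
#' \code{sampleRatios} the per-sample ratio matrix; \code{samplePairing} the
#' polyA/total sample pairing; \code{provenance} the processing parameters;
#' \code{transcriptIds} the transcript identifiers; \code{geneSets} and
#' \code{mirnaTargets} the underlying named lists.
#'
#' @param x a \linkS4class{StabilityTable}, \linkS4class{GeneSetCollection}
#'   or \linkS4class{MirnaTargetMap}.
#' @return Named vectors/matrices parallel to the transcripts of \code{x},
#'   or the named member list for collections.
#' @name accessors
#' @aliases patr logPatr patrRank ieRatio ieRank meanPaRpkm tailFlag
#'   sampleRatios samplePairing provenance transcriptIds geneSets mirnaTargets
NULL

#' @rdname accessors
#' @export
setGeneric("patr", function(x) standardGeneric("patr"))
#' @rdname accessors
#' @export
setGeneric("logPatr", function(x) standardGeneric("logPatr"))
#' @rdname accessors
#' @export
setGeneric("patrRank", function(x) standardGeneric("patrRank"))
#' @rdname accessors
#' @export
setGeneric("ieRatio", function(x) standardGeneric("ieRatio"))
#' @rdname accessors
#' @export
setGeneric("ieRank", function(x) standardGeneric("ieRank"))
#' @rdname accessors
#' @export
setGeneric("meanPaRpkm", function(x) standardGeneric("meanPaRpkm"))
#' @rdname accessors
#' @export
setGeneric("tailFlag", function(x) standardGeneric("tailFlag"))
#' @rdname accessors
#' @export
setGeneric("sampleRatios", function(x) standardGeneric("sampleRatios"))
#' @rdname accessors
#' @export
setGeneric("samplePairing", function(x) standardGeneric("samplePairing"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("mirnaTargets", function(x) standardGeneric("mirnaTargets"))
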