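#' Accessors for CaptureExperiment objects
#'
#' \code{abundance()} returns the protein-by-sample abundance matrix
#' (\code{NA} marks not-detected cells), \code{peptideCounts()} the matching
#' unique-peptide count matrix, and \code{isNormalized()} whether
#' [normalizeAbundance()] has been applied.
#'
#' @param object a [CaptureExperiment-class].
#' @return \code{abundance} and \code{peptideCounts} return numeric/integer
#'   matrices; \code{isNormalized} a logical scalar.
#' @name CaptureExperiment-accessors
NULL

#' @rdname CaptureExperiment-accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @rdname CaptureExperiment-accessors
#' @export
setMethod("abundance", "CaptureExperiment", function(object) {
  assay(object, "abundance")
})

#' @rdname CaptureExperiment-accessors
#' @export
setGeneric("peptideCounts", function(object) standardGeneric("peptideCounts"))

#' @rdname CaptureExperiment-accessors
#' @export
setMethod("peptideCounts", "CaptureExperiment", function(object) {
  assay(object, "npep")
})

#' @rdname CaptureExperiment-accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname CaptureExperiment-accessors
#' @export
setMethod("isNormalized", "CaptureExperiment", function(object) {
  isTRUE(metadata(object)$normalized)
})

#' Accessors for GroundTruth objects
#'
#' @param object a [GroundTruth-class].
#' @return \code{truthCatalog} returns the protein catalog data.frame;
#'   \code{duplicateMap} the duplicate-to-canonical accession map;
#'   \code{querySequence} the named query amino-acid sequence.
#' @name GroundTruth-accessors
NULL

#' @rdname GroundTruth-accessors
#' @export
setGeneric("truthCatalog", function(object) standardGeneric("truthCatalog"))

#' @rdname GroundTruth-accessors
#' @export
setMethod("truthCatalog", "GroundTruth", function(object) object@catalog)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("duplicateMap", function(object) standardGeneric("duplicateMap"))

#' @rdname GroundTruth-accessors
#' @export
setMethod("duplicateMap", "GroundTruth", function(object) object@duplicateMap)

#' @rdname GroundTruth-accessors
#' @export
setGeneric("querySequence", function(object) standardGeneric("querySequence"))

#' @rdname GroundTruth-accessors
#' @export
setMethod("querySequence", "GroundTruth", function(object) object@querySequence)
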