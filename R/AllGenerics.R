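#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Accessor generics for the central data classes: per-position reactivity
#' scores, aligned coverage, the normalization factor, event-count matrices,
#' pair tables and dot-bracket renderings.
#'
#' @param x An object of the appropriate class.
#' @return The slot contents (a vector, matrix or string, see the method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactivity", function(x) standardGeneric("reactivity"))
#' @rdname accessors
#' @export
setGeneric("positionCoverage", function(x) standardGeneric("positionCoverage"))
#' @rdname accessors
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))
#' @rdname accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))
#' @rdname accessors
#' @export
setGeneric("modelEnergy", function(x) standardGeneric("modelEnergy"))

#' @rdname accessors
#' @export
setMethod("reactivity", "ReactivityProfile", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("positionCoverage", "ReactivityProfile", function(x) x@coverage)
#' @rdname accessors
#' @export
setMethod("positionCoverage", "MutationCounts", function(x) x@coverage)
#' @rdname accessors
#' @export
setMethod("normFactor", "ReactivityProfile", function(x) x@normFactor)
#' @rdname accessors
#' @export
setMethod("eventCounts", "MutationCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)
#' @rdname accessors
#' @export
setMethod("transcriptId", "MutationCounts", function(x) x@transcript)
#' @rdname accessors
#' @export
setMethod("transcriptId", "ReactivityProfile", function(x) x@transcript)
#' @rdname accessors
#' @export
setMethod("rnaSequence", "SecondaryStructure", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("rnaSequence", "ReactivityProfile", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("rnaSequence", "MirnaAnnotation", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("modelEnergy", "CoordinateModel", function(x) x@energy)

#' @rdname accessors
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) {
  pairsToDotBracket(x@pairTable)
})
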