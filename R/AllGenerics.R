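#' Accessors for cfEnds containers
#'
#' @param object A cfEnds S4 object.
#' @return The corresponding slot value; \code{motifFrequencies} returns
#'   counts normalised by the number of usable ends.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(object) standardGeneric("motifCounts"))

#' @rdname accessors
#' @export
setGeneric("motifFrequencies",
           function(object) standardGeneric("motifFrequencies"))

#' @rdname accessors
#' @export
setGeneric("nEnds", function(object) standardGeneric("nEnds"))

#' @rdname accessors
#' @export
setGeneric("motifClass", function(object) standardGeneric("motifClass"))

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(object) standardGeneric("kmerLength"))

#' @rdname accessors
#' @export
setGeneric("sizeRange", function(object) standardGeneric("sizeRange"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("oofScores", function(object) standardGeneric("oofScores"))

#' @rdname accessors
#' @export
setGeneric("caseProbabilities",
           function(object) standardGeneric("caseProbabilities"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))

#' @rdname accessors
#' @export
setGeneric("auprValue", function(object) standardGeneric("auprValue"))

#' @rdname accessors
#' @export
setGeneric("sensAtSpec", function(object) standardGeneric("sensAtSpec"))

#' @rdname accessors
#' @export
setGeneric("profilePositions",
           function(object) standardGeneric("profilePositions"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("endType", function(object) standardGeneric("endType"))
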