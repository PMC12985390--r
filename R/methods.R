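#' @rdname accessors
#' @export
setMethod("motifCounts", "MotifSpectrum", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("motifFrequencies", "MotifSpectrum", function(object) {
  if (object@nEnds == 0) {
    warning("spectrum has zero usable ends; frequencies undefined")
    return(setNames(rep(NA_real_, length(object@counts)),
                    names(object@counts)))
  }
  object@counts / object@nEnds
})

#' @rdname accessors
#' @export
setMethod("nEnds", "MotifSpectrum", function(object) object@nEnds)

#' @rdname accessors
#' @export
setMethod("motifClass", "MotifSpectrum", function(object) object@motifClass)

#' @rdname accessors
#' @export
setMethod("kmerLength", "MotifSpectrum", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("sizeRange", "MotifSpectrum", function(object) object@sizeRange)

setMethod("show", "MotifSpectrum", function(object) {
  rng <- if (all(is.na(object@sizeRange))) "all sizes" else
    sprintf("[%g,%g) nt", object@sizeRange[1], object@sizeRange[2])
  cat(sprintf("MotifSpectrum: %s, k=%d, %s\n", object@motifClass,
              object@k, rng))
  cat(sprintf("  %d motifs, %g usable ends", length(object@counts),
              object@nEnds))
  if (!is.na(object@sampleId)) cat(sprintf(", sample %s", object@sampleId))
  cat("\n")
  if (object@nEnds > 0) {
    top <- sort(motifFrequencies(object), decreasing = TRUE)[1:5]
    cat("  top motifs:",
        paste(sprintf("%s (%.3g)", names(top), top), collapse = ", "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("fragments", "FragmentCohort", function(object) object@fragments)

#' @rdname accessors
#' @export
setMethod("sampleIds", "FragmentCohort",
          function(object) names(object@fragments))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "FragmentCohort", function(object) object@labels)

setMethod("show", "FragmentCohort", function(object) {
  tab <- table(object@labels)
  cat(sprintf("FragmentCohort: %d samples (%d control, %d case)\n",
              length(object@fragments), tab[["control"]], tab[["case"]]))
  cat(sprintf("  fragments per sample: %s (median)\n",
              format(median(lengths(object@fragments)))))
})

#' @rdname accessors
#' @export
setMethod("profilePositions", "CleavageProfile",
          function(object) object@positions)

#' @rdname accessors
#' @export
setMethod("profileValues", "CleavageProfile",
          function(object) setNames(object@meanProportion,
                                    object@positions))

#' @rdname accessors
#' @export
setMethod("endType", "CleavageProfile", function(object) object@endType)

setMethod("show", "CleavageProfile", function(object) {
  cat(sprintf("CleavageProfile: %s ends, %d positions\n",
              object@endType, length(object@positions)))
  print(round(profileValues(object), 3))
})

#' @rdname accessors
#' @export
setMethod("oofScores", "ClassifierResult", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("caseProbabilities", "ClassifierResult",
          function(object) object@probabilities)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "ClassifierResult", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("aucValue", "ClassifierResult", function(object) object@auc)

#' @rdname accessors
#' @export
setMethod("auprValue", "ClassifierResult", function(object) object@aupr)

#' @rdname accessors
#' @export
setMethod("sensAtSpec", "ClassifierResult", function(object) object@sensAtSpec)

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf("ClassifierResult: %d samples, AUC = %.3f, AUPR = %.3f\n",
              length(object@labels), object@auc, object@aupr))
  cat("  sensitivity at specificity:\n")
  print(round(object@sensAtSpec, 3))
})
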