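#' @import methods
#' @importFrom stats median sd cor.test p.adjust quantile rbinom rnorm runif
#'   setNames wilcox.test predict complete.cases
#' @importFrom utils head read.delim write.table packageVersion
NULL

MOTIF_CLASSES <- c("PREM", "EM5", "EM3", "POEM")

#' MotifSpectrum: a per-sample k-mer end-motif frequency vector
#'
#' Container for the counts and frequencies of all 4^k k-mers observed at
#' one class of fragment end (PREM, EM5, EM3 or POEM), optionally restricted
#' to a half-open fragment-size stratum.
#'
#' @slot motifClass One of \code{"PREM"}, \code{"EM5"}, \code{"EM3"},
#'   \code{"POEM"} (or \code{"FOUR_END"} for duplex 4-end spectra).
#' @slot k Integer motif length.
#' @slot sizeRange Numeric of length 2 giving the half-open size stratum
#'   \code{[lo, hi)} in nt, or \code{NA_real_} twice for "all sizes".
#' @slot counts Named integer vector over the full motif domain (zeros kept).
#' @slot nEnds Total number of usable ends (sum of counts).
#' @slot sampleId Sample identifier (may be \code{NA}).
#'
#' @export
setClass("MotifSpectrum",
  representation(
    motifClass = "character",
    k = "integer",
    sizeRange = "numeric",
    counts = "numeric",
    nEnds = "numeric",
    sampleId = "character"
  )
)

setValidity("MotifSpectrum", function(object) {
  msg <- character()
  if (length(object@motifClass) != 1L)
    msg <- c(msg, "motifClass must be length 1")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by motif")
  if (!isTRUE(all.equal(sum(object@counts), object@nEnds)))
    msg <- c(msg, "nEnds must equal sum(counts)")
  if (length(msg)) msg else TRUE
})

#' FragmentCohort: labelled per-sample fragment collections
#'
#' A two-group cohort of aligned cfDNA fragments: one
#' \linkS4class{GRanges} of fragments per sample plus a case/control label.
#'
#' @slot fragments A \code{GRangesList}, one element per sample.
#' @slot labels Factor with levels \code{control}, \code{case}.
#'
#' @export
setClass("FragmentCohort",
  representation(fragments = "GRangesList", labels = "factor")
)

setValidity("FragmentCohort", function(object) {
  msg <- character()
  ids <- names(object@fragments)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(object@labels) != length(object@fragments))
    msg <- c(msg, "one label per sample required")
  if (!all(levels(object@labels) %in% c("control", "case")))
    msg <- c(msg, "labels must use levels control/case")
  if (any(lengths(object@fragments) == 0))
    msg <- c(msg, "every sample needs at least one fragment")
  if (length(msg)) msg else TRUE
})

#' CleavageProfile: mean cleavage proportions around a CpG set
#'
#' Holds the per-position mean cleavage proportion (in percent) of one end
#' type within a window centred on the C of a Watson-strand CpG.
#'
#' @slot endType \code{"5p"} or \code{"3p"}.
#' @slot positions Integer offsets relative to the CpG C (position 0).
#' @slot meanProportion Numeric percentages in [0, 100], one per position.
#' @slot nSites Number of CpG sites contributing per position.
#'
#' @export
setClass("CleavageProfile",
  representation(
    endType = "character",
    positions = "integer",
    meanProportion = "numeric",
    nSites = "integer"
  )
)

setValidity("CleavageProfile", function(object) {
  msg <- character()
  if (!object@endType %in% c("5p", "3p"))
    msg <- c(msg, "endType must be '5p' or '3p'")
  n <- length(object@positions)
  if (length(object@meanProportion) != n || length(object@nSites) != n)
    msg <- c(msg, "positions, meanProportion and nSites must align")
  ok <- is.finite(object@meanProportion)
  if (any(object@meanProportion[ok] < 0 | object@meanProportion[ok] > 100))
    msg <- c(msg, "proportions must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' ClassifierResult: out-of-fold scores and ROC summaries
#'
#' Result of leave-one-out SVM classification: one out-of-fold score and
#' case probability per sample, with AUC, AUPR and sensitivity at fixed
#' specificity thresholds.
#'
#' @slot scores Out-of-fold case scores (higher = more case-like).
#' @slot probabilities Platt-scaled case probabilities.
#' @slot labels Factor with levels \code{control}, \code{case}.
#' @slot auc Area under the ROC curve.
#' @slot aupr Area under the precision-recall curve.
#' @slot sensAtSpec Named numeric, sensitivity at specificity thresholds.
#' @slot seed Integer seed used.
#'
#' @export
setClass("ClassifierResult",
  representation(
    scores = "numeric",
    probabilities = "numeric",
    labels = "factor",
    auc = "numeric",
    aupr = "numeric",
    sensAtSpec = "numeric",
    seed = "integer"
  )
)

setValidity("ClassifierResult", function(object) {
  n <- length(object@labels)
  if (length(object@scores) != n || length(object@probabilities) != n)
    return("scores and probabilities must have one entry per sample")
  TRUE
})
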