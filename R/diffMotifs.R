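#' Motif frequency matrix for a set of samples
#'
#' Convenience helper: one \code{\link{motifSpectrum}} per sample, bound
#' into a motifs x samples frequency matrix.
#'
#' @param grList Named list/\code{GRangesList} of per-sample fragment
#'   \code{GRanges}.
#' @param genome Reference \code{DNAStringSet}.
#' @inheritParams motifSpectrum
#' @return Numeric matrix (4^k motifs x samples), columns named by sample.
#' @export
spectrumMatrix <- function(grList, genome, motifClass = "EM5", k = 4,
                           sizeRange = "all") {
  ids <- names(grList) %||% paste0("sample", seq_along(grList))
  cols <- lapply(seq_along(grList), function(i) {
    motifFrequencies(motifSpectrum(grList[[i]], genome, motifClass, k,
                                   sizeRange, sampleId = ids[i]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  m
}

#' Differential end motifs between two groups
#'
#' Per motif: group medians, fold change of medians (case/control),
#' relative percentage change, two-sided Wilcoxon rank-sum p value and
#' Benjamini-Hochberg adjusted q over all motifs of the class. A motif is
#' \code{increased} when q < alpha and fold change > 1, \code{decreased}
#' when q < alpha and fold change < 1, otherwise \code{ns}.
#'
#' Exact p values are used for small groups without ties (the default
#' behaviour of \code{\link[stats]{wilcox.test}}); with ties or larger
#' groups the normal approximation with continuity correction applies.
#' When a group median is 0, the fold change uses a pseudo-frequency of
#' \code{1/(2 * nEndsTypical)}.
#'
#' @param caseMat,controlMat Frequency matrices (motifs x samples) over
#'   the same motif domain, as from \code{\link{spectrumMatrix}}.
#' @param alpha Significance level on the adjusted p value.
#' @param nEndsTypical Typical number of usable ends per sample, used only
#'   for the zero-median pseudo-frequency (default 1e6).
#' @return \code{data.frame} with one row per motif: \code{motif},
#'   \code{median_case}, \code{median_control}, \code{fold_change},
#'   \code{rel_pct_change}, \code{p}, \code{q}, \code{direction}.
#' @export
differentialMotifs <- function(caseMat, controlMat, alpha = 0.05,
                               nEndsTypical = 1e6) {
  if (!identical(rownames(caseMat), rownames(controlMat)))
    stop("case and control matrices must share the same motif domain")
  if (ncol(caseMat) < 2 || ncol(controlMat) < 2)
    stop("need at least 2 samples per group")
  motifs <- rownames(caseMat)
  medCase <- apply(caseMat, 1, median)
  medCtrl <- apply(controlMat, 1, median)
  pseudo <- 1 / (2 * nEndsTypical)
  fc <- ifelse(medCase == 0 & medCtrl == 0, 1,
        ifelse(medCtrl == 0, medCase / pseudo,
        ifelse(medCase == 0, pseudo / medCtrl, medCase / medCtrl)))
  relPct <- ifelse(medCtrl == 0, NA_real_,
                   (medCase - medCtrl) / medCtrl * 100)
  p <- vapply(seq_along(motifs), function(i) {
    x <- caseMat[i, ]; y <- controlMat[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  direction <- rep("ns", length(motifs))
  direction[q < alpha & fc > 1] <- "increased"
  direction[q < alpha & fc < 1] <- "decreased"
  data.frame(motif = motifs, median_case = medCase,
             median_control = medCtrl, fold_change = fc,
             rel_pct_change = relPct, p = p, q = q,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Top differential motifs by relative percentage change
#'
#' Ranks significant motifs within each direction by the magnitude of
#' their relative percentage change of medians. Motifs with a zero control
#' median are excluded from the ranking.
#'
#' @param table Output of \code{\link{differentialMotifs}}.
#' @param n Number of motifs per direction.
#' @return List with character vectors \code{increased} and
#'   \code{decreased}.
#' @export
rankTopMotifs <- function(table, n = 5) {
  usable <- table[!is.na(table$rel_pct_change), ]
  if (nrow(usable) < nrow(table))
    message(nrow(table) - nrow(usable),
            " motif(s) with zero control median excluded from ranking")
  pick <- function(dir) {
    sub <- usable[usable$direction == dir, ]
    sub <- sub[order(-abs(sub$rel_pct_change)), ]
    head(sub$motif, n)
  }
  list(increased = pick("increased"), decreased = pick("decreased"))
}

#' End-motif ratio (EMR)
#'
#' Per-sample ratio of the cumulative frequency of the case-increased
#' motif set to that of the case-decreased set.
#'
#' @param freq Named frequency vector for one sample (or a
#'   \linkS4class{MotifSpectrum}).
#' @param increasedSet,decreasedSet Disjoint, nonempty motif sets.
#' @return The EMR value (scalar); \code{NA} with a warning when the
#'   decreased-set cumulative frequency is 0.
#' @export
endMotifRatio <- function(freq, increasedSet, decreasedSet) {
  freq <- .asFreq(freq)
  if (length(increasedSet) == 0 || length(decreasedSet) == 0)
    stop("motif sets must be nonempty")
  if (length(intersect(increasedSet, decreasedSet)) > 0)
    stop("increased and decreased motif sets must be disjoint")
  if (!all(c(increasedSet, decreasedSet) %in% names(freq)))
    stop("motif set contains motifs outside the spectrum domain")
  den <- sum(freq[decreasedSet])
  if (den == 0) {
    warning("decreased-set cumulative frequency is 0; EMR undefined")
    return(NA_real_)
  }
  sum(freq[increasedSet]) / den
}

#' Row-wise Z-score standardisation
#'
#' Standardises each motif row of a frequency matrix to mean 0 and
#' (sample, n-1) SD 1, the transformation used for motif heatmaps.
#' Zero-variance rows map to all zeros.
#'
#' @param mat Numeric matrix (motifs x samples), >= 2 columns.
#' @return Matrix of the same shape.
#' @export
rowZscore <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  m <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  z <- (mat - m) / s
  zero <- s == 0
  if (any(zero)) {
    message(sum(zero), " zero-variance row(s) set to 0")
    z[zero, ] <- 0
  }
  z
}

#' Pearson correlation between two motif spectra
#'
#' @param a,b Named frequency vectors or \linkS4class{MotifSpectrum}
#'   objects over the same motif domain.
#' @return List with \code{r} and \code{p} from a Pearson correlation
#'   test over the paired motif frequencies.
#' @export
correlateSpectra <- function(a, b) {
  fa <- .asFreq(a); fb <- .asFreq(b)
  if (!setequal(names(fa), names(fb)))
    stop("spectra must share the same motif domain")
  fb <- fb[names(fa)]
  if (sd(fa) == 0 || sd(fb) == 0) stop("zero-variance spectrum")
  ct <- cor.test(fa, fb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
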