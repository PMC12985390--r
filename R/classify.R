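#' Assemble a feature matrix from a cohort
#'
#' Concatenates, in deterministic (class, stratum, motif) order, the
#' per-sample end-motif spectra of the requested motif classes and size
#' strata. With the four classes, k = 4 and the three default strata this
#' yields the 3,072-feature representation (4 classes x 256 motifs x 3
#' strata). FRAGMA feature vectors can be appended via
#' \code{fragmaConfig}.
#'
#' @param cohort A \linkS4class{FragmentCohort}.
#' @param genome Reference \code{DNAStringSet}.
#' @param classes Motif classes to include.
#' @param k Motif length.
#' @param strata Size-strata matrix, or \code{NULL} for a single
#'   all-sizes stratum.
#' @param fragmaConfig Optional list with elements \code{cpgTable},
#'   \code{labels}, \code{endType} (and optionally \code{window},
#'   \code{minDepth}) to append FRAGMA cleavage features.
#' @return Numeric matrix (samples x features) with a
#'   \code{"provenance"} attribute mapping features to (module, class,
#'   stratum).
#' @export
assembleFeatures <- function(cohort, genome,
                             classes = c("PREM", "EM5", "EM3", "POEM"),
                             k = 4, strata = defaultSizeStrata(),
                             fragmaConfig = NULL) {
  grl <- fragments(cohort)
  ids <- sampleIds(cohort)
  strataList <- if (is.null(strata)) list(all = "all") else
    lapply(seq_len(nrow(strata)), function(i) strata[i, ])
  if (!is.null(strata))
    names(strataList) <- rownames(strata) %||%
      paste0(strata[, 1], "-", strata[, 2])

  blocks <- list()
  prov <- character()
  for (cls in classes) {
    for (sname in names(strataList)) {
      rng <- strataList[[sname]]
      block <- t(vapply(seq_along(grl), function(i) {
        spec <- suppressWarnings(
          motifSpectrum(grl[[i]], genome, cls, k, rng, ids[i]))
        if (nEnds(spec) == 0)
          stop("sample ", ids[i], " has no usable ends in stratum ",
               sname, " for class ", cls)
        motifFrequencies(spec)
      }, numeric(4^k)))
      colnames(block) <- paste(cls, sname, colnames(block), sep = ":")
      blocks[[length(blocks) + 1L]] <- block
      prov <- c(prov, setNames(rep(paste("end_motifs", cls, sname),
                                   ncol(block)), colnames(block)))
    }
  }
  if (!is.null(fragmaConfig)) {
    fc <- fragmaConfig
    block <- t(vapply(seq_along(grl), function(i) {
      fragmaFeatures(grl[[i]], fc$cpgTable, fc$labels,
                     endType = fc$endType %||% "3p",
                     window = fc$window %||% 5,
                     minDepth = fc$minDepth %||% 1)
    }, numeric(4 * (2 * (fragmaConfig$window %||% 5) + 1))))
    colnames(block) <- paste0("FRAGMA:", fc$endType %||% "3p", ":",
                              colnames(block))
    blocks[[length(blocks) + 1L]] <- block
    prov <- c(prov, setNames(rep("fragma", ncol(block)),
                             colnames(block)))
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- ids
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  attr(x, "provenance") <- prov
  x
}

#' Leave-one-out SVM classification
#'
#' For each sample, trains a linear-kernel SVM (cost 1) on all other
#' samples and scores the held-out sample. Feature standardisation is
#' fitted on the training split only (within-fold), so no information
#' leaks from the held-out sample. Case probabilities are Platt-scaled
#' within the training fold.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Factor/character of \code{case}/\code{control}.
#' @param seed Integer seed (Platt scaling uses internal cross-validation).
#' @param cost SVM cost parameter.
#' @return A \linkS4class{ClassifierResult}.
#' @export
loocvSvm <- function(x, labels, seed = 1L, cost = 1) {
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (any(table(labels) < 2) || nlevels(droplevels(labels)) < 2)
    stop("need at least 2 samples per class")
  n <- nrow(x)
  scores <- numeric(n)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- (x[i, ] - mu) / sg
    set.seed(seed + i)
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE, probability = TRUE)
    pr <- predict(fit, t(xte), decision.values = TRUE,
                  probability = TRUE)
    dv <- attr(pr, "decision.values")[1, 1]
    # orient the decision value so that higher means more case-like
    if (grepl("^control/", colnames(attr(pr, "decision.values"))[1]))
      dv <- -dv
    scores[i] <- dv
    probs[i] <- attr(pr, "probabilities")[1, "case"]
  }
  met <- rocMetrics(scores, labels)
  new("ClassifierResult", scores = scores, probabilities = probs,
      labels = labels, auc = met$auc, aupr = met$aupr,
      sensAtSpec = met$sensAtSpec, seed = as.integer(seed))
}

#' ROC and precision-recall metrics
#'
#' AUC is computed as the Mann-Whitney U statistic divided by
#' \code{nCase * nControl} (tied scores count 0.5). AUPR is the average
#' precision over the ranked positives. Sensitivity at a specificity
#' threshold is the highest sensitivity among operating points whose
#' specificity is at least the threshold.
#'
#' @param scores Numeric case scores (higher = more case-like).
#' @param labels Factor/character of \code{case}/\code{control}.
#' @param specThresholds Specificity thresholds for the sensitivity
#'   read-outs.
#' @return List with \code{auc}, \code{aupr} and named \code{sensAtSpec}.
#' @export
rocMetrics <- function(scores, labels,
                       specThresholds = c(0.80, 0.85, 0.90, 0.95)) {
  isCase <- as.character(labels) == "case"
  nCase <- sum(isCase); nCtrl <- sum(!isCase)
  if (nCase == 0 || nCtrl == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[isCase]) - nCase * (nCase + 1) / 2) / (nCase * nCtrl)

  ord <- order(-scores)
  tp <- cumsum(isCase[ord])
  prec <- tp / seq_along(tp)
  aupr <- sum(prec[isCase[ord]]) / nCase

  fp <- cumsum(!isCase[ord])
  sens <- tp / nCase
  spec <- 1 - fp / nCtrl
  sas <- vapply(specThresholds, function(th) {
    ok <- c(TRUE, spec >= th)   # include the all-negative operating point
    max(c(0, sens)[ok])
  }, numeric(1))
  names(sas) <- paste0("spec", specThresholds)
  list(auc = auc, aupr = aupr, sensAtSpec = sas)
}

#' DeLong test comparing two paired AUCs
#'
#' Two-sided DeLong comparison of the ROC curves of two score vectors
#' computed on the same samples.
#'
#' @param scoresA,scoresB Paired score vectors.
#' @param labels Shared labels.
#' @return Two-sided p value.
#' @export
compareAucDelong <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("scores and labels must be paired (equal lengths)")
  if (isTRUE(all.equal(scoresA, scoresB))) return(1)
  resp <- as.integer(as.character(labels) == "case")
  ra <- pROC::roc(resp, scoresA, quiet = TRUE, direction = "<")
  rb <- pROC::roc(resp, scoresB, quiet = TRUE, direction = "<")
  as.numeric(pROC::roc.test(ra, rb, method = "delong",
                            paired = TRUE)$p.value)
}

#' Bootstrap confidence intervals for AUC and AUPR
#'
#' Stratified bootstrap (resampling samples within each class) with
#' percentile 95\% confidence intervals. When \code{scoresB} is given, a
#' paired bootstrap p value for the AUC difference is also returned.
#'
#' @param scores Case scores.
#' @param labels Labels.
#' @param nBoot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param scoresB Optional paired second score vector.
#' @return List with \code{auc}, \code{aucCI}, \code{aupr},
#'   \code{auprCI} and, when \code{scoresB} is given, \code{pDiff}.
#' @export
bootstrapMetrics <- function(scores, labels, nBoot = 1000, seed = 1L,
                             scoresB = NULL) {
  stopifnot(nBoot >= 100)
  labels <- factor(as.character(labels), levels = c("control", "case"))
  idxCase <- which(labels == "case")
  idxCtrl <- which(labels == "control")
  set.seed(seed)
  aucs <- numeric(nBoot); auprs <- numeric(nBoot)
  dif <- if (is.null(scoresB)) NULL else numeric(nBoot)
  for (b in seq_len(nBoot)) {
    idx <- c(sample(idxCase, replace = TRUE),
             sample(idxCtrl, replace = TRUE))
    m <- rocMetrics(scores[idx], labels[idx])
    aucs[b] <- m$auc; auprs[b] <- m$aupr
    if (!is.null(scoresB))
      dif[b] <- m$auc - rocMetrics(scoresB[idx], labels[idx])$auc
  }
  point <- rocMetrics(scores, labels)
  out <- list(auc = point$auc,
              aucCI = unname(quantile(aucs, c(0.025, 0.975))),
              aupr = point$aupr,
              auprCI = unname(quantile(auprs, c(0.025, 0.975))))
  if (!is.null(scoresB)) {
    pLow <- mean(dif <= 0); pHigh <- mean(dif >= 0)
    out$pDiff <- min(1, 2 * min(pLow, pHigh))
  }
  out
}

#' Downsampling performance curve
#'
#' For each grid level, subsamples that many fragments (without
#' replacement) from every sample, re-assembles the feature matrix and
#' re-runs leave-one-out SVM classification. Levels exceeding the
#' smallest per-sample fragment count are skipped with a warning.
#'
#' @param cohort A \linkS4class{FragmentCohort}.
#' @param genome Reference \code{DNAStringSet}.
#' @param grid Fragment counts to evaluate.
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{assembleFeatures}}.
#' @return Named numeric vector of AUCs, one per evaluated level.
#' @export
downsampleCurve <- function(cohort, genome,
                            grid = c(500, 1000, 2000, 3000, 4000, 5000,
                                     10000, 20000, 30000, 40000),
                            seed = 1L, ...) {
  stopifnot(length(grid) >= 1)
  grl <- fragments(cohort)
  labs <- sampleLabels(cohort)
  minFrag <- min(lengths(grl))
  out <- setNames(rep(NA_real_, length(grid)), grid)
  for (g in seq_along(grid)) {
    nSel <- grid[g]
    if (nSel > minFrag) {
      warning("level ", nSel, " exceeds the smallest sample (",
              minFrag, " fragments); skipped")
      next
    }
    set.seed(seed + g)
    sub <- lapply(grl, function(gr) gr[sample(length(gr), nSel)])
    names(sub) <- names(grl)
    subCohort <- FragmentCohort(sub, labs)
    res <- loocvSvm(assembleFeatures(subCohort, genome, ...),
                    labs, seed = seed)
    out[g] <- aucValue(res)
  }
  out
}
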