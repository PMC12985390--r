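CPG_CLASSES <- c("tissue_hyper", "tissue_hypo", "hcc_specific_hyper",
                 "hcc_specific_hypo", "unclassified")

#' Classify CpG sites by methylation density
#'
#' Applies the 70\%/30\% rules to a CpG methylation table:
#' \itemize{
#'   \item \code{tissue_hyper}: density > 70 in every configured tissue;
#'   \item \code{tissue_hypo}: density < 30 in every configured tissue;
#'   \item \code{hcc_specific_hyper}: tumour > 70 and buffy coat < 30;
#'   \item \code{hcc_specific_hypo}: tumour < 30 and buffy coat > 70.
#' }
#' HCC-specific labels take precedence when a site satisfies both an
#' HCC-specific and a tissue-wide rule. Sites matching no rule are
#' \code{unclassified}.
#'
#' @param cpgTable \code{data.frame} with columns \code{chrom}, \code{pos}
#'   (0-based position of the Watson-strand C) and one percentage column
#'   per tissue.
#' @param tissues Character vector naming the tissue columns used by the
#'   tissue-wide rules.
#' @param tumorCol,buffyCol Column names used by the HCC-specific rules.
#' @return Factor of labels, one per row of \code{cpgTable}.
#' @export
classifyCpGs <- function(cpgTable, tissues,
                         tumorCol = "hcc_tumor", buffyCol = "buffy_coat") {
  need <- unique(c(tissues, tumorCol, buffyCol))
  missing <- setdiff(need, names(cpgTable))
  if (length(missing))
    stop("missing tissue column(s): ", paste(missing, collapse = ", "))
  dens <- as.matrix(cpgTable[, tissues, drop = FALSE])
  tumor <- cpgTable[[tumorCol]]
  buffy <- cpgTable[[buffyCol]]
  lab <- rep("unclassified", nrow(cpgTable))
  lab[apply(dens > 70, 1, all)] <- "tissue_hyper"
  lab[apply(dens < 30, 1, all)] <- "tissue_hypo"
  lab[tumor > 70 & buffy < 30] <- "hcc_specific_hyper"
  lab[tumor < 30 & buffy > 70] <- "hcc_specific_hypo"
  factor(lab, levels = CPG_CLASSES)
}

# Genomic position (1-based) of the molecule's 5'/3' terminal base.
.endPositions <- function(gr, endType) {
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (endType == "5p")
    ifelse(minus, GenomicRanges::end(gr), GenomicRanges::start(gr))
  else
    ifelse(minus, GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Cleavage proportion at a single site
#'
#' Percentage of fragments covering a genomic site whose 5' (or 3')
#' terminal base lies exactly at that site, in the molecule's own
#' orientation:
#' \deqn{\mathrm{proportion} = \frac{\#\ \mathrm{ends\ at\ } i}
#'   {\mathrm{depth\ at\ } i} \times 100.}
#'
#' @param gr Fragment \code{GRanges}.
#' @param chrom Contig name.
#' @param pos 0-based genomic position of the site.
#' @param endType \code{"5p"} or \code{"3p"}.
#' @return Percentage in [0, 100], or \code{NA} when depth is 0.
#' @export
cleavageProportion <- function(gr, chrom, pos, endType = c("5p", "3p")) {
  endType <- match.arg(endType)
  pos1 <- pos + 1L
  onChrom <- as.character(GenomicRanges::seqnames(gr)) == chrom
  gr <- gr[onChrom]
  covering <- GenomicRanges::start(gr) <= pos1 &
    GenomicRanges::end(gr) >= pos1
  depth <- sum(covering)
  if (depth == 0) {
    warning("no coverage at site; proportion undefined")
    return(NA_real_)
  }
  ends <- .endPositions(gr, endType)
  sum(covering & ends == pos1) / depth * 100
}

#' Cleavage profile around a CpG set
#'
#' For each CpG (anchored at the Watson-strand C, relative position 0) and
#' each offset in \code{-window..window}, computes the cleavage proportion
#' of the requested end type and averages it (unweighted) across sites.
#' Watson- and Crick-strand fragments are merged in the 5'-to-3' direction:
#' plus-strand fragments are read on the Watson frame (site = C position +
#' offset) while minus-strand fragments are read on the symmetric Crick
#' frame anchored at the G (site = G position - offset), exploiting the
#' symmetry of CpG methylation.
#'
#' @param gr Fragment \code{GRanges}.
#' @param cpgSites \code{data.frame} with columns \code{chrom}, \code{pos}
#'   (0-based Watson C).
#' @param endType \code{"5p"} or \code{"3p"}.
#' @param window Half-width of the profile window (default 5 nt).
#' @param minDepth Minimum merged depth for a site/position cell to enter
#'   the mean (default 1).
#' @param pooled When \code{TRUE}, pool end and depth counts across sites
#'   before forming proportions instead of averaging per-site proportions.
#' @return A \linkS4class{CleavageProfile}.
#' @export
cleavageProfile <- function(gr, cpgSites, endType = c("5p", "3p"),
                            window = 5, minDepth = 1, pooled = FALSE) {
  endType <- match.arg(endType)
  if (nrow(cpgSites) == 0) stop("empty CpG set")
  offsets <- -window:window
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  chromF <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  endPos <- .endPositions(gr, endType)

  nOff <- length(offsets)
  endMat <- matrix(0, nrow(cpgSites), nOff)
  depMat <- matrix(0, nrow(cpgSites), nOff)
  for (i in seq_len(nrow(cpgSites))) {
    onChrom <- chromF == cpgSites$chrom[i]
    cPos1 <- cpgSites$pos[i] + 1L   # Watson C, 1-based
    gPos1 <- cPos1 + 1L             # Watson G = Crick C
    # genomic site interrogated per offset, by fragment strand
    for (j in seq_len(nOff)) {
      siteP <- cPos1 + offsets[j]   # plus-strand (Watson) frame
      siteM <- gPos1 - offsets[j]   # minus-strand (Crick) frame
      covP <- onChrom & !minus & s <= siteP & e >= siteP
      covM <- onChrom & minus & s <= siteM & e >= siteM
      depMat[i, j] <- sum(covP) + sum(covM)
      endMat[i, j] <- sum(covP & endPos == siteP) +
        sum(covM & endPos == siteM)
    }
  }
  if (all(depMat == 0)) stop("no coverage at any CpG site")
  if (pooled) {
    meanProp <- ifelse(colSums(depMat) > 0,
                       colSums(endMat) / colSums(depMat) * 100, NA_real_)
    nSites <- colSums(depMat > 0)
  } else {
    prop <- ifelse(depMat >= minDepth, endMat / depMat * 100, NA)
    meanProp <- colMeans(prop, na.rm = TRUE)
    nSites <- colSums(!is.na(prop))
  }
  new("CleavageProfile", endType = endType, positions = as.integer(offsets),
      meanProportion = as.numeric(meanProp), nSites = as.integer(nSites))
}

#' FRAGMA feature vector for one sample
#'
#' Concatenates the cleavage profiles of the four differentially
#' methylated CpG categories (tissue-wide hyper/hypo and HCC-specific
#' hyper/hypo) into a single feature vector: 4 categories x (2*window+1)
#' positions, in fixed (category, position-ascending) order.
#'
#' @param gr Fragment \code{GRanges} for one sample.
#' @param cpgTable CpG table with a \code{label} column (as produced by
#'   \code{\link{classifyCpGs}}, stored in the table) or a factor passed
#'   via \code{labels}.
#' @param labels Optional factor of CpG class labels, one per row of
#'   \code{cpgTable}.
#' @param endType \code{"5p"} or \code{"3p"}.
#' @param window Profile half-width (default 5).
#' @param minDepth Minimum per-cell depth (default 1).
#' @return Named numeric vector of length \code{4 * (2*window + 1)}.
#' @export
fragmaFeatures <- function(gr, cpgTable, labels = NULL,
                           endType = c("5p", "3p"), window = 5,
                           minDepth = 1) {
  endType <- match.arg(endType)
  if (is.null(labels)) labels <- cpgTable$label
  if (is.null(labels)) stop("CpG labels required")
  cats <- setdiff(CPG_CLASSES, "unclassified")
  feats <- lapply(cats, function(cat) {
    sites <- cpgTable[labels == cat, , drop = FALSE]
    if (nrow(sites) == 0) stop("CpG category empty: ", cat)
    prof <- cleavageProfile(gr, sites, endType, window, minDepth)
    setNames(prof@meanProportion,
             paste0(cat, ":", prof@positions))
  })
  unlist(feats)
}
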