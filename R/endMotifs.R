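#' Extract the four end-motif classes from fragments
#'
#' For every fragment, determines the four k-mer end motifs in the
#' molecule's own 5'-to-3' frame:
#' \itemize{
#'   \item EM5: first k bases of the fragment sequence;
#'   \item EM3: last k bases of the fragment sequence;
#'   \item PREM: the k reference bases immediately upstream of the 5' end;
#'   \item POEM: the k reference bases immediately downstream of the 3'
#'     end.
#' }
#' For minus-strand fragments the definitions are applied to the reverse
#' complement of the locus, so that all motifs are reported 5'-to-3' as the
#' sequenced molecule reads them. Ends within k of a contig boundary, and
#' motifs containing N, are unavailable (\code{NA}).
#'
#' @param gr Fragment \code{GRanges} (1-based, as from
#'   \code{\link{loadFragments}}).
#' @param genome Reference \code{DNAStringSet}.
#' @param k Motif length (default 4).
#' @return \code{data.frame} with character columns \code{prem},
#'   \code{em5}, \code{em3}, \code{poem} (NA = unavailable), one row per
#'   fragment.
#' @export
extractEndMotifs <- function(gr, genome, k = 4) {
  stopifnot(k >= 1)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  w <- e - s + 1L

  # genomic intervals of each motif, before strand flipping
  up <- cbind(s - k, s - 1L)      # flank upstream of the interval
  five <- cbind(s, s + k - 1L)    # first k bases of the interval
  three <- cbind(e - k + 1L, e)   # last k bases of the interval
  down <- cbind(e + 1L, e + k)    # flank downstream of the interval

  seqUp <- extractGenomeSeq(genome, chrom, up[, 1], up[, 2])
  seqFive <- extractGenomeSeq(genome, chrom, five[, 1], five[, 2])
  seqThree <- extractGenomeSeq(genome, chrom, three[, 1], three[, 2])
  seqDown <- extractGenomeSeq(genome, chrom, down[, 1], down[, 2])

  # fragments shorter than k have no EM5/EM3
  short <- w < k
  seqFive[short] <- NA_character_
  seqThree[short] <- NA_character_

  prem <- ifelse(minus, revComp(seqDown), seqUp)
  em5 <- ifelse(minus, revComp(seqThree), seqFive)
  em3 <- ifelse(minus, revComp(seqFive), seqThree)
  poem <- ifelse(minus, revComp(seqUp), seqDown)

  data.frame(prem = prem, em5 = em5, em3 = em3, poem = poem,
             stringsAsFactors = FALSE)
}

#' Build a per-sample end-motif spectrum
#'
#' Counts the k-mer motifs of one end class over all fragments whose size
#' falls in \code{sizeRange}, over the full 4^k motif domain (zeros kept).
#' Unavailable motifs are excluded from both numerator and denominator, so
#' frequencies always sum to 1 when any usable end exists.
#'
#' @param gr Fragment \code{GRanges}.
#' @param genome Reference \code{DNAStringSet}.
#' @param motifClass One of \code{"PREM"}, \code{"EM5"}, \code{"EM3"},
#'   \code{"POEM"}.
#' @param k Motif length.
#' @param sizeRange Half-open size stratum \code{c(lo, hi)} in nt, or
#'   \code{"all"}.
#' @param sampleId Optional sample identifier stored in the spectrum.
#' @return A \linkS4class{MotifSpectrum}.
#' @export
motifSpectrum <- function(gr, genome, motifClass = "EM5", k = 4,
                          sizeRange = "all", sampleId = NA_character_) {
  motifClass <- match.arg(toupper(motifClass), MOTIF_CLASSES)
  rng <- if (identical(sizeRange, "all")) c(NA_real_, NA_real_) else {
    stopifnot(length(sizeRange) == 2, sizeRange[1] < sizeRange[2])
    as.numeric(sizeRange)
  }
  if (!all(is.na(rng))) {
    w <- GenomicRanges::width(gr)
    gr <- gr[w >= rng[1] & w < rng[2]]
  }
  motifs <- extractEndMotifs(gr, genome, k)[[tolower(motifClass)]]
  counts <- countOverDomain(motifs, allKmers(k))
  spec <- new("MotifSpectrum", motifClass = motifClass, k = as.integer(k),
              sizeRange = rng, counts = counts, nEnds = sum(counts),
              sampleId = as.character(sampleId))
  if (spec@nEnds == 0) warning("no usable ends in spectrum")
  spec
}

#' Expected genome-wide k-mer frequencies
#'
#' Slides a k-nt window with step 1 over both strands of every contig and
#' counts each k-mer; windows containing N do not contribute. This is the
#' composition baseline used by \code{\link{correctFrequencies}}.
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param k Motif length.
#' @return Named numeric frequency vector over all 4^k motifs (sums to 1).
#' @export
expectedGenomeFrequency <- function(genome, k = 4) {
  if (all(Biostrings::width(genome) < k))
    stop("genome shorter than k")
  fwd <- colSums(Biostrings::oligonucleotideFrequency(genome, width = k))
  dom <- allKmers(k)
  fwd <- fwd[dom]
  rev <- setNames(as.numeric(fwd), revComp(dom))[dom]
  counts <- as.numeric(fwd) + rev
  if (sum(counts) == 0) stop("no N-free windows in genome")
  setNames(counts / sum(counts), dom)
}

#' Correct plasma motif frequencies against a sonicated control
#'
#' Applies, motif-wise,
#' \deqn{F^{corr}_i = \frac{F^{plasma}_i}{F^{sonicated}_i} \times
#'   F^{expected}_i}
#' and renormalises the corrected vector to sum to 1. The sonicated
#' spectrum captures pre-analytical bias shared by both preparations; the
#' expected vector is the genome composition baseline from
#' \code{\link{expectedGenomeFrequency}}. When the sonicated spectrum is
#' given as counts containing zeros, a pseudocount of 0.5 is added to every
#' sonicated count before forming the ratio.
#'
#' @param plasma \linkS4class{MotifSpectrum} or named frequency vector.
#' @param sonicated \linkS4class{MotifSpectrum} or named frequency vector.
#' @param expected Named frequency vector (must sum to 1).
#' @return Named corrected frequency vector, summing to 1.
#' @export
correctFrequencies <- function(plasma, sonicated, expected) {
  fPlasma <- .asFreq(plasma)
  fSon <- .asFreq(sonicated, pseudocount = 0.5)
  dom <- names(expected)
  if (is.null(dom) || !setequal(names(fPlasma), dom) ||
      !setequal(names(fSon), dom))
    stop("motif domains of plasma, sonicated and expected must match")
  if (abs(sum(expected) - 1) > 1e-6)
    stop("expected frequency vector must sum to 1")
  fPlasma <- fPlasma[dom]
  fSon <- fSon[dom]
  if (any(fSon == 0))
    stop("sonicated frequencies must be positive after pseudocount")
  corr <- fPlasma / fSon * expected
  corr / sum(corr)
}

# Frequencies from a spectrum or a ready-made frequency vector.  The
# pseudocount (on counts) is applied only when counts are available and
# contain zeros, so exact algebraic identities hold on zero-free input.
.asFreq <- function(x, pseudocount = 0) {
  if (is(x, "MotifSpectrum")) {
    cts <- motifCounts(x)
    if (pseudocount > 0 && any(cts == 0)) cts <- cts + pseudocount
    return(cts / sum(cts))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a MotifSpectrum or named numeric vector")
}

#' Fragment size profile and mode detection
#'
#' Histogram of fragment sizes at 1-nt resolution, with local maxima
#' reported as modes. A size is a mode when its count is the strict
#' maximum within a +/- \code{span} window and exceeds
#' \code{minProminence} times the mean count.
#'
#' @param gr Fragment \code{GRanges}.
#' @param span Half-width of the local-maximum window (nt).
#' @param minProminence Minimum count, as a multiple of the mean per-size
#'   count, for a mode to be reported.
#' @return List with \code{histogram} (named counts per integer size) and
#'   \code{modes} (integer sizes of detected local maxima).
#' @export
sizeProfile <- function(gr, span = 5, minProminence = 2) {
  if (length(gr) == 0) {
    warning("no fragments; empty size profile")
    return(list(histogram = integer(0), modes = integer(0)))
  }
  w <- GenomicRanges::width(gr)
  rng <- range(w)
  sizes <- rng[1]:rng[2]
  counts <- countOverDomain(as.character(w), as.character(sizes))
  modes <- integer(0)
  thr <- minProminence * mean(counts)
  for (i in seq_along(sizes)) {
    lo <- max(1, i - span); hi <- min(length(sizes), i + span)
    if (counts[i] >= thr && counts[i] == max(counts[lo:hi]) &&
        sum(counts[lo:hi] == counts[i]) == 1) {
      # refine the raw argmax by a windowed centroid (two passes), which
      # is robust to count noise on broad peaks
      ctr <- i
      for (pass in 1:2) {
        w <- max(1, ctr - span):min(length(sizes), ctr + span)
        ctr <- round(sum(sizes[w] * counts[w]) / sum(counts[w])) -
          sizes[1] + 1
      }
      modes <- c(modes, sizes[ctr])
    }
  }
  list(histogram = counts, modes = unique(modes))
}

#' Default fragment-size strata
#'
#' Half-open strata \code{[42,70)}, \code{[70,166)}, \code{[166,601)} nt:
#' the sub-mononucleosomal short population, the intermediate range up to
#' the mononucleosome peak, and everything longer (601 encodes the 600-nt
#' retention cap, upper bound exclusive).
#'
#' @return Numeric matrix with columns \code{lo}, \code{hi}.
#' @export
defaultSizeStrata <- function() {
  m <- cbind(lo = c(42, 70, 166), hi = c(70, 166, 601))
  rownames(m) <- c("42-70", "70-166", "166-601")
  m
}

#' Assign fragments to size strata
#'
#' Each fragment goes to the single half-open stratum \code{[lo, hi)}
#' containing its size; fragments outside all strata are dropped (count
#' reported via a message).
#'
#' @param gr Fragment \code{GRanges}.
#' @param strata Matrix as from \code{\link{defaultSizeStrata}}; intervals
#'   must be non-overlapping and ascending.
#' @return Named list of \code{GRanges}, one per stratum.
#' @export
stratifyBySize <- function(gr, strata = defaultSizeStrata()) {
  stopifnot(ncol(strata) == 2, all(strata[, 1] < strata[, 2]))
  if (nrow(strata) > 1 &&
      any(strata[-nrow(strata), 2] > strata[-1, 1]))
    stop("strata overlap or are not ascending")
  w <- GenomicRanges::width(gr)
  out <- vector("list", nrow(strata))
  names(out) <- rownames(strata) %||%
    paste0(strata[, 1], "-", strata[, 2])
  assigned <- rep(FALSE, length(gr))
  for (i in seq_len(nrow(strata))) {
    sel <- w >= strata[i, 1] & w < strata[i, 2]
    out[[i]] <- gr[sel]
    assigned <- assigned | sel
  }
  if (any(!assigned))
    message(sum(!assigned), " fragment(s) outside all strata dropped")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
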