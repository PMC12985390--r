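NUCLEASES <- c("DFFB", "DNASE1", "DNASE1L3")

#' Default nuclease cutting-signature table
#'
#' Dinucleotide end motifs attributed to the three plasma nucleases from
#' knockout-vs-wild-type comparisons: a 5' 2-mer set and a 3' 2-mer set
#' per nuclease. The sets are disjoint within each end type, so every
#' 2-mer maps to at most one nuclease.
#'
#' @return Named list (per nuclease) of lists with elements \code{five}
#'   and \code{three}.
#' @export
nucleaseSignatures <- function() {
  list(
    DNASE1L3 = list(five = "GG", three = "CT"),
    DNASE1 = list(five = "CT", three = "CG"),
    DFFB = list(five = c("AC", "AT", "AA", "AG", "GA"),
                three = c("GC", "GT", "AG", "GG", "TC"))
  )
}

#' The six unordered nuclease-pair labels
#'
#' @return Character vector of the 6 pair categories.
#' @export
nucleasePairLabels <- function() {
  c("DFFB-DFFB", "DNASE1-DNASE1", "DNASE1L3-DNASE1L3",
    "DFFB-DNASE1", "DFFB-DNASE1L3", "DNASE1-DNASE1L3")
}

#' Build the stem-loop adapter pool
#'
#' Deterministically synthesises the pool of 41 stem-loop adapters: 1
#' blunt adapter plus, for each overhang length 1..20, one adapter with a
#' 5' overhang and one with a 3' overhang. Each adapter carries a 6-mer
#' barcode; barcodes are chosen by a deterministic greedy lexicographic
#' scan enforcing a pairwise Hamming distance of at least 3, so a single
#' sequencing substitution always decodes to a unique adapter (a
#' distance-2 code would leave 1-error words equidistant from two
#' codewords).
#'
#' @return \code{data.frame} with columns \code{barcode}, \code{kind}
#'   (\code{blunt}, \code{five_prime}, \code{three_prime}) and
#'   \code{overhang_len}.
#' @export
buildAdapterPool <- function() {
  kind <- c("blunt", rep("five_prime", 20), rep("three_prime", 20))
  len <- c(0L, 1:20, 1:20)
  bases <- c("A", "C", "G", "T")
  picked <- matrix(0L, 0, 6)
  idx <- 0L
  while (nrow(picked) < 41L && idx < 4096L) {
    d <- integer(6); x <- idx
    for (j in 6:1) { d[j] <- x %% 4L; x <- x %/% 4L }
    if (nrow(picked) == 0 ||
        min(rowSums(picked != matrix(d, nrow(picked), 6,
                                     byrow = TRUE))) >= 3)
      picked <- rbind(picked, d)
    idx <- idx + 1L
  }
  barcode <- apply(picked, 1, function(d)
    paste(bases[d + 1L], collapse = ""))
  data.frame(barcode = unname(barcode), kind = kind, overhang_len = len,
             stringsAsFactors = FALSE)
}

# Left/right end modality of duplex molecules from their geometry.
# mols: data.frame(chrom, w_start, w_end, c_start, c_end), 0-based
# half-open; Watson = plus strand, Crick = minus strand.
.endModalities <- function(mols, side) {
  if (side == "left") {
    d <- mols$c_start - mols$w_start
    kind <- ifelse(d > 0, "five_prime", ifelse(d < 0, "three_prime",
                                               "blunt"))
  } else {
    d <- mols$w_end - mols$c_end
    kind <- ifelse(d > 0, "three_prime", ifelse(d < 0, "five_prime",
                                                "blunt"))
  }
  data.frame(kind = kind, overhang_len = abs(d),
             stringsAsFactors = FALSE)
}

#' Jagged-end type of duplex molecules
#'
#' Classifies each side of every duplex molecule as blunt, 5'-jagged (the
#' 5'-terminated strand protrudes) or 3'-jagged, with the overhang length.
#'
#' @param mols Duplex molecule \code{data.frame} with 0-based half-open
#'   columns \code{chrom}, \code{w_start}, \code{w_end}, \code{c_start},
#'   \code{c_end} (Watson = plus strand, Crick = minus strand).
#' @param side \code{"left"} or \code{"right"}.
#' @return \code{data.frame} with columns \code{type} (\code{blunt},
#'   \code{five_prime_jagged}, \code{three_prime_jagged}) and
#'   \code{length}.
#' @export
jaggedType <- function(mols, side = c("left", "right")) {
  side <- match.arg(side)
  if (any(mols$c_start >= mols$w_end | mols$w_start >= mols$c_end))
    stop("Watson and Crick intervals must overlap")
  mod <- .endModalities(mols, side)
  type <- ifelse(mod$kind == "blunt", "blunt",
                 paste0(mod$kind, "_jagged"))
  data.frame(type = type, length = mod$overhang_len,
             stringsAsFactors = FALSE)
}

#' Encode duplex molecules as barcoded read records
#'
#' Selects, for each side of each molecule, the stem-loop adapter whose
#' end modality (kind and overhang length) matches the molecule's
#' geometry, and emits a read record carrying the Watson interval plus
#' the two adapter barcodes. Molecules with an overhang longer than 20 nt
#' have no matching adapter and are dropped as unligatable (mimicking
#' exonuclease removal of incompletely circularised products).
#'
#' @param mols Duplex molecule \code{data.frame} (see
#'   \code{\link{jaggedType}}).
#' @param pool Adapter pool from \code{\link{buildAdapterPool}}.
#' @return List with \code{records} (\code{data.frame}: \code{chrom},
#'   \code{w_start}, \code{w_end}, \code{left_barcode},
#'   \code{right_barcode}) and \code{dropped} (integer count of
#'   unligatable molecules).
#' @export
encodeMolecules <- function(mols, pool = buildAdapterPool()) {
  left <- .endModalities(mols, "left")
  right <- .endModalities(mols, "right")
  key <- function(kind, len) paste0(kind, ":", ifelse(kind == "blunt",
                                                      0L, len))
  poolKey <- setNames(pool$barcode, key(pool$kind, pool$overhang_len))
  lb <- poolKey[key(left$kind, left$overhang_len)]
  rb <- poolKey[key(right$kind, right$overhang_len)]
  ok <- !is.na(lb) & !is.na(rb)
  records <- data.frame(chrom = mols$chrom[ok],
                        w_start = mols$w_start[ok],
                        w_end = mols$w_end[ok],
                        left_barcode = unname(lb[ok]),
                        right_barcode = unname(rb[ok]),
                        stringsAsFactors = FALSE)
  list(records = records, dropped = sum(!ok))
}

# Decode one barcode against the pool with <= 1 mismatch rescue.
# Returns the pool row index or NA when no unique match exists.
.matchBarcode <- function(codes, pool) {
  exact <- match(codes, pool$barcode)
  todo <- which(is.na(exact) & !is.na(codes))
  for (i in todo) {
    d <- vapply(pool$barcode, hammingDist, numeric(1), a = codes[i])
    hit <- which(d <= 1)
    if (length(hit) == 1) exact[i] <- hit
  }
  exact
}

#' Decode barcoded read records back to duplex molecules
#'
#' Inverse of \code{\link{encodeMolecules}}: looks up both barcodes
#' (rescuing single substitutions, which the distance-2 barcode code makes
#' unambiguous) and reconstructs the Crick interval from the Watson
#' interval and the decoded end modalities. Records whose barcodes cannot
#' be resolved uniquely are rejected and counted.
#'
#' @param records Read-record \code{data.frame} from
#'   \code{\link{encodeMolecules}}.
#' @param pool Adapter pool.
#' @return List with \code{molecules} (duplex \code{data.frame}) and
#'   \code{rejected} (integer count).
#' @export
decodeReads <- function(records, pool = buildAdapterPool()) {
  li <- .matchBarcode(records$left_barcode, pool)
  ri <- .matchBarcode(records$right_barcode, pool)
  ok <- !is.na(li) & !is.na(ri)
  lKind <- pool$kind[li[ok]]; lLen <- pool$overhang_len[li[ok]]
  rKind <- pool$kind[ri[ok]]; rLen <- pool$overhang_len[ri[ok]]
  ws <- records$w_start[ok]; we <- records$w_end[ok]
  cs <- ws + ifelse(lKind == "five_prime", lLen,
                    ifelse(lKind == "three_prime", -lLen, 0L))
  ce <- we - ifelse(rKind == "three_prime", rLen,
                    ifelse(rKind == "five_prime", -rLen, 0L))
  mols <- data.frame(chrom = records$chrom[ok], w_start = ws, w_end = we,
                     c_start = cs, c_end = ce, stringsAsFactors = FALSE)
  list(molecules = mols, rejected = sum(!ok))
}

# Terminal k-mers of duplex molecules (5'->3' in each strand's own frame).
# Returns NA for out-of-bounds or N-containing motifs; zero lengths give
# empty strings.
.duplexEndSeqs <- function(mols, genome, a, b, cc, d) {
  n <- nrow(mols)
  emp <- rep("", n)
  w5 <- if (a > 0) extractGenomeSeq(genome, mols$chrom,
                                    mols$w_start + 1L,
                                    mols$w_start + a) else emp
  w3 <- if (b > 0) extractGenomeSeq(genome, mols$chrom,
                                    mols$w_end - b + 1L,
                                    mols$w_end) else emp
  c5 <- if (cc > 0) revComp(extractGenomeSeq(genome, mols$chrom,
                                             mols$c_end - cc + 1L,
                                             mols$c_end)) else emp
  c3 <- if (d > 0) revComp(extractGenomeSeq(genome, mols$chrom,
                                            mols$c_start + 1L,
                                            mols$c_start + d)) else emp
  list(w5 = w5, w3 = w3, c5 = c5, c3 = c3)
}

.renderFourEnd <- function(w5, w3, c5, c3) {
  paste0(w5, "\u2192", w3, c3, "\u2190", c5)
}

#' 4-end motif of duplex molecules
#'
#' Reads the Watson-strand 5' a-mer and 3' b-mer and the Crick-strand 5'
#' c-mer and 3' d-mer (each in its strand's own 5'-to-3' frame) and
#' renders the canonical flattened notation: Watson motifs in the
#' numerator read left to right, Crick motifs in the denominator displayed
#' antiparallel (3' end first), e.g. \code{"A→TT←A"} for a blunt
#' duplex whose Watson strand is ACGT.
#'
#' @param mols Duplex molecule \code{data.frame}.
#' @param genome Reference \code{DNAStringSet}.
#' @param spec Integer vector \code{c(a, b, c, d)} of motif lengths for
#'   (Watson-5', Watson-3', Crick-5', Crick-3'); at least one > 0.
#' @return Character vector of motif strings (\code{NA} when any requested
#'   motif is out of bounds or contains N).
#' @export
fourEndMotif <- function(mols, genome, spec = c(1, 1, 1, 1)) {
  stopifnot(length(spec) == 4, all(spec >= 0), sum(spec) > 0)
  sq <- .duplexEndSeqs(mols, genome, spec[1], spec[2], spec[3], spec[4])
  out <- .renderFourEnd(sq$w5, sq$w3, sq$c5, sq$c3)
  out[is.na(sq$w5) | is.na(sq$w3) | is.na(sq$c5) | is.na(sq$c3)] <-
    NA_character_
  out
}

#' Motif domain of a 4-end spec
#'
#' @param spec Integer vector \code{c(a, b, c, d)}.
#' @return Character vector of all 4^(a+b+c+d) rendered motif strings.
#' @export
fourEndMotifSpace <- function(spec = c(1, 1, 1, 1)) {
  stopifnot(length(spec) == 4, all(spec >= 0), sum(spec) > 0)
  part <- function(len) if (len == 0) "" else allKmers(len)
  g <- expand.grid(w5 = part(spec[1]), w3 = part(spec[2]),
                   c5 = part(spec[3]), c3 = part(spec[4]),
                   stringsAsFactors = FALSE)
  sort(.renderFourEnd(g$w5, g$w3, g$c5, g$c3))
}

#' 4-end motif spectrum
#'
#' Frequency vector of the rendered 4-end motifs of a molecule set over
#' the full motif domain of the spec.
#'
#' @inheritParams fourEndMotif
#' @return A \linkS4class{MotifSpectrum} with class \code{"FOUR_END"}.
#' @export
fourEndSpectrum <- function(mols, genome, spec = c(1, 1, 1, 1)) {
  motifs <- fourEndMotif(mols, genome, spec)
  counts <- countOverDomain(motifs, fourEndMotifSpace(spec))
  if (sum(counts) == 0) stop("no usable molecules for 4-end spectrum")
  new("MotifSpectrum", motifClass = "FOUR_END",
      k = as.integer(sum(spec)), sizeRange = c(NA_real_, NA_real_),
      counts = counts, nEnds = sum(counts), sampleId = NA_character_)
}

# Map 2-mers to the unique nuclease owning them at the given end type.
.nucleaseLookup <- function(signatures, end) {
  all2 <- unlist(lapply(signatures, `[[`, end))
  nuc <- rep(names(signatures), lengths(lapply(signatures, `[[`, end)))
  dup <- all2[duplicated(all2)]
  keep <- !all2 %in% dup   # motifs claimed by >1 nuclease are ambiguous
  setNames(nuc[keep], all2[keep])
}

#' Attribute one fragment side to a nuclease pair
#'
#' At the chosen side of each duplex molecule, the 5' 2-mer of one strand
#' and the 3' 2-mer of the complementary strand are looked up in the
#' nuclease signature table; the unordered pair of matching nucleases is
#' returned. Sides where either 2-mer matches no nuclease (or an
#' ambiguous one) are \code{unassigned}.
#'
#' @param mols Duplex molecule \code{data.frame}.
#' @param genome Reference \code{DNAStringSet}.
#' @param signatures Signature table from \code{\link{nucleaseSignatures}}.
#' @param side \code{"left"} (Watson 5' + Crick 3') or \code{"right"}
#'   (Crick 5' + Watson 3').
#' @return Character vector of pair labels (see
#'   \code{\link{nucleasePairLabels}}) or \code{"unassigned"}.
#' @export
assignNucleasePair <- function(mols, genome,
                               signatures = nucleaseSignatures(),
                               side = c("left", "right")) {
  side <- match.arg(side)
  sq <- .duplexEndSeqs(mols, genome, 2, 2, 2, 2)
  if (side == "left") { five <- sq$w5; three <- sq$c3 }
  else { five <- sq$c5; three <- sq$w3 }
  lut5 <- .nucleaseLookup(signatures, "five")
  lut3 <- .nucleaseLookup(signatures, "three")
  n5 <- lut5[five]
  n3 <- lut3[three]
  ok <- !is.na(n5) & !is.na(n3)
  lab <- rep("unassigned", nrow(mols))
  if (any(ok)) {
    ordi <- function(x) match(x, NUCLEASES)
    first <- ifelse(ordi(n5[ok]) <= ordi(n3[ok]), n5[ok], n3[ok])
    second <- ifelse(ordi(n5[ok]) <= ordi(n3[ok]), n3[ok], n5[ok])
    lab[ok] <- paste0(first, "-", second)
  }
  lab
}

#' Size-stratified nuclease-signature abundance
#'
#' Observed/expected normalised abundance of the six nuclease-pair labels
#' per fragment-size bin. Observed label frequencies are computed from
#' both sides of every molecule. Expected frequencies come from redrawing
#' \code{expectedFactor} times as many blunt duplexes uniformly at random
#' from the genome with the observed size multiset, which captures genome
#' composition without any cleavage preference.
#'
#' @param mols Duplex molecule \code{data.frame}.
#' @param genome Reference \code{DNAStringSet}.
#' @param signatures Signature table.
#' @param sizeBins Matrix with columns \code{lo}, \code{hi} (half-open bp
#'   bins); default \code{defaultDuplexSizeBins()}.
#' @param seed Integer seed for the expected-frequency redraw.
#' @param expectedFactor Simulated-to-observed molecule ratio.
#' @return Numeric matrix (bins x 6 labels); rows for empty bins are
#'   \code{NA}.
#' @export
signatureSizeAbundance <- function(mols, genome,
                                   signatures = nucleaseSignatures(),
                                   sizeBins = defaultDuplexSizeBins(),
                                   seed = 1L, expectedFactor = 10) {
  stopifnot(ncol(sizeBins) == 2, all(sizeBins[, 1] < sizeBins[, 2]))
  labels <- nucleasePairLabels()
  size <- mols$w_end - mols$w_start
  obsLab <- c(assignNucleasePair(mols, genome, signatures, "left"),
              assignNucleasePair(mols, genome, signatures, "right"))
  obsSize <- rep(size, 2)

  set.seed(seed)
  nSim <- round(expectedFactor * nrow(mols))
  # resample whole (size, jagged-offset) geometries so the expected
  # frequencies reflect composition only, not end geometry
  pick <- sample(nrow(mols), nSim, replace = TRUE)
  simSize <- size[pick]
  simOffL <- mols$c_start[pick] - mols$w_start[pick]
  simOffR <- mols$c_end[pick] - mols$w_end[pick]
  lens <- Biostrings::width(genome)
  ctg <- sample(names(genome), nSim, replace = TRUE,
                prob = lens / sum(lens))
  pad <- 25L
  maxStart <- setNames(lens, names(genome))[ctg] - simSize - 2L * pad
  keep <- maxStart >= 0
  start <- pad + floor(runif(sum(keep)) * (maxStart[keep] + 1))
  sim <- data.frame(chrom = ctg[keep], w_start = start,
                    w_end = start + simSize[keep],
                    c_start = start + simOffL[keep],
                    c_end = start + simSize[keep] + simOffR[keep],
                    stringsAsFactors = FALSE)
  simLab <- c(assignNucleasePair(sim, genome, signatures, "left"),
              assignNucleasePair(sim, genome, signatures, "right"))
  simSize2 <- rep(sim$w_end - sim$w_start, 2)

  out <- matrix(NA_real_, nrow(sizeBins), length(labels),
                dimnames = list(rownames(sizeBins) %||%
                                  paste0(sizeBins[, 1], "-", sizeBins[, 2]),
                                labels))
  for (i in seq_len(nrow(sizeBins))) {
    inObs <- obsSize >= sizeBins[i, 1] & obsSize < sizeBins[i, 2]
    inSim <- simSize2 >= sizeBins[i, 1] & simSize2 < sizeBins[i, 2]
    if (!any(inObs)) next
    obsFreq <- countOverDomain(obsLab[inObs], labels) / sum(inObs)
    expFreq <- countOverDomain(simLab[inSim], labels) / max(sum(inSim), 1)
    out[i, ] <- ifelse(expFreq > 0, obsFreq / expFreq, NA_real_)
  }
  out
}

#' Default duplex size bins
#'
#' Half-open bp bins spanning the fragment-size regimes relevant to
#' nuclease engagement: \code{[20,130)}, \code{[130,200)},
#' \code{[200,400)}, \code{[400,600)}, \code{[600,1000)}.
#'
#' @return Numeric matrix with columns \code{lo}, \code{hi}.
#' @export
defaultDuplexSizeBins <- function() {
  m <- cbind(lo = c(20, 130, 200, 400, 600),
             hi = c(130, 200, 400, 600, 1000))
  rownames(m) <- paste0(m[, "lo"], "-", m[, "hi"])
  m
}
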