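#' Enumerate the k-mer motif domain
#'
#' All 4^k DNA k-mers over {A,C,G,T}, in alphabetical order.
#'
#' @param k Motif length (>= 1).
#' @return Character vector of length 4^k.
#' @export
allKmers <- function(k) {
  stopifnot(k >= 1)
  sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
}

# Reverse complement of a character vector of DNA strings (NA preserved).
revComp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok])))
  }
  out
}

# Extract genome subsequences for 1-based closed intervals, vectorised.
# Intervals outside the contig, or naming unknown contigs, yield NA.
# Returned strings containing non-ACGT characters are set to NA when
# dropAmbiguous is TRUE.
extractGenomeSeq <- function(genome, chrom, start, end,
                             dropAmbiguous = TRUE) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  out <- rep(NA_character_, n)
  lens <- setNames(Biostrings::width(genome), names(genome))
  known <- chrom %in% names(genome)
  inb <- known & !is.na(start) & !is.na(end) &
    start >= 1 & end <= lens[ifelse(known, chrom, names(genome)[1])] &
    start <= end
  inb[is.na(inb)] <- FALSE
  for (ctg in unique(chrom[inb])) {
    idx <- which(inb & chrom == ctg)
    v <- Biostrings::extractAt(genome[[ctg]],
                               IRanges::IRanges(start[idx], end[idx]))
    out[idx] <- as.character(v)
  }
  if (dropAmbiguous) {
    bad <- !is.na(out) & grepl("[^ACGT]", out)
    out[bad] <- NA_character_
  }
  out
}

# Named count vector over a fixed motif domain.
countOverDomain <- function(motifs, domain) {
  motifs <- motifs[!is.na(motifs)]
  tab <- table(factor(motifs, levels = domain))
  setNames(as.numeric(tab), domain)
}

# Hamming distance between two equal-length strings.
hammingDist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
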