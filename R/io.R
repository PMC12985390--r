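#' Load a reference genome from FASTA
#'
#' Reads a FASTA file into a \code{DNAStringSet}. Sequences are uppercased
#' and any character outside {A,C,G,T,N} is mapped to N. Contig names are
#' taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet}, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AACCGGTTACGTAACCGGTT"), fa)
#' genome <- loadReference(fa)
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  if (any(nchar(chr) == 0)) stop("empty contig in FASTA")
  genome <- Biostrings::DNAStringSet(chr)
  names(genome) <- nm
  genome
}

#' Load aligned fragments from a BED-like TSV
#'
#' Reads fragment records with columns \code{chrom}, \code{start},
#' \code{end}, \code{strand} and optional \code{mismatches}, \code{mapq}.
#' Coordinates are 0-based half-open on input (BED convention) unless
#' \code{oneBased = TRUE}, and are stored 1-based in the returned
#' \code{GRanges} (so \code{width()} equals fragment size in nt).
#'
#' @param path Path to a TSV/BED file (header optional; columns recognised
#'   by name when a header naming \code{chrom} is present, else by
#'   position).
#' @param sampleId Sample identifier attached to every fragment.
#' @param genome Optional \code{DNAStringSet}; when given, intervals are
#'   validated against contig bounds.
#' @param oneBased Set \code{TRUE} if the file uses 1-based inclusive
#'   coordinates; they are converted on load.
#' @return A \code{GRanges} in file order with metadata columns
#'   \code{sample_id} and, when present, \code{mismatches}, \code{mapq}.
#' @export
loadFragments <- function(path, sampleId = "sample1", genome = NULL,
                          oneBased = FALSE) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  first <- readLines(path, n = 1)
  hasHeader <- grepl("chrom", first)
  df <- read.delim(path, header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!hasHeader) {
    nms <- c("chrom", "start", "end", "strand", "mismatches", "mapq")
    names(df) <- nms[seq_len(min(ncol(df), length(nms)))]
  }
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(df)))
    stop("fragment file must provide columns: ", paste(req, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  start0 <- if (oneBased) df$start - 1L else df$start
  end0 <- df$end
  if (any(start0 >= end0))
    stop("invalid interval (start >= end) at line(s): ",
         paste(head(which(start0 >= end0)), collapse = ", "))
  if (any(start0 < 0)) stop("negative start coordinate")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$sample_id <- sampleId
  if ("mismatches" %in% names(df))
    S4Vectors::mcols(gr)$mismatches <- as.integer(df$mismatches)
  if ("mapq" %in% names(df))
    S4Vectors::mcols(gr)$mapq <- as.integer(df$mapq)
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chrom %in% names(genome)))
      stop("fragment contig absent from genome: ",
           paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
    if (any(GenomicRanges::end(gr) > lens[chrom]))
      stop("fragment interval out of contig bounds")
  }
  gr
}

#' Write fragments to a canonical BED-like TSV
#'
#' Inverse of \code{\link{loadFragments}}: writes 0-based half-open
#' coordinates with a header line. \code{loadFragments} followed by
#' \code{writeFragments} reproduces a canonical file byte-identically.
#'
#' @param gr A fragment \code{GRanges}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  for (col in c("mismatches", "mapq"))
    if (col %in% names(S4Vectors::mcols(gr)))
      df[[col]] <- S4Vectors::mcols(gr)[[col]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply alignment-level fragment filters
#'
#' Retains fragments whose size lies within \code{[minSize, maxSize]}
#' (inclusive on both ends) and, when the corresponding metadata columns
#' are present, with at most \code{maxMismatches} mismatches and mapping
#' quality at least \code{minMapq}. Filters whose columns are absent are
#' skipped with a message. Defaults follow short-read practice (insert
#' 20-600 bp, <= 2 mismatches); \code{minMapq = 30} is typical for
#' long-read duplex data.
#'
#' @param gr Fragment \code{GRanges}.
#' @param minSize,maxSize Inclusive size bounds in nt.
#' @param maxMismatches Maximum allowed mismatches (applied only when the
#'   \code{mismatches} column exists).
#' @param minMapq Minimum mapping quality (applied only when the
#'   \code{mapq} column exists); default \code{NULL} skips the filter.
#' @return List with elements \code{fragments} (the retained
#'   \code{GRanges}) and \code{report} (named integer: removed per rule).
#' @export
applyAlignmentFilters <- function(gr, minSize = 20, maxSize = 600,
                                  maxMismatches = 2, minMapq = NULL) {
  stopifnot(minSize >= 0, maxSize >= minSize)
  n0 <- length(gr)
  report <- c(size = 0L, mismatches = 0L, mapq = 0L)
  keep <- rep(TRUE, n0)

  w <- GenomicRanges::width(gr)
  bad <- keep & (w < minSize | w > maxSize)
  report["size"] <- sum(bad)
  keep <- keep & !bad

  if (!is.null(maxMismatches)) {
    if ("mismatches" %in% names(S4Vectors::mcols(gr))) {
      mm <- S4Vectors::mcols(gr)$mismatches
      bad <- keep & !is.na(mm) & mm > maxMismatches
      report["mismatches"] <- sum(bad)
      keep <- keep & !bad
    } else {
      message("mismatch column absent; mismatch filter skipped")
    }
  }
  if (!is.null(minMapq)) {
    if ("mapq" %in% names(S4Vectors::mcols(gr))) {
      mq <- S4Vectors::mcols(gr)$mapq
      bad <- keep & !is.na(mq) & mq < minMapq
      report["mapq"] <- sum(bad)
      keep <- keep & !bad
    } else {
      message("mapq column absent; mapq filter skipped")
    }
  }
  out <- gr[keep]
  if (length(out) == 0) warning("all fragments removed by filters")
  list(fragments = out, report = report)
}

#' Assemble a FragmentCohort
#'
#' @param fragmentList Named list (or \code{GRangesList}) of per-sample
#'   fragment \code{GRanges}.
#' @param labels Character/factor of \code{"case"}/\code{"control"}, one
#'   per sample.
#' @return A \linkS4class{FragmentCohort}.
#' @export
FragmentCohort <- function(fragmentList, labels) {
  if (!is(fragmentList, "GRangesList"))
    fragmentList <- GenomicRanges::GRangesList(fragmentList)
  new("FragmentCohort", fragments = fragmentList,
      labels = factor(labels, levels = c("control", "case")))
}
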