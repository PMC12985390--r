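# Independent pure-string oracles used to cross-check the
# Biostrings-based implementation. They share no code with the package.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevComp <- function(s) {
  if (is.na(s)) return(NA_character_)
  paste(rev(.COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# End-motif quartet by direct substring slicing on a character genome.
# Coordinates are 0-based half-open.
oracleQuartet <- function(seqStr, start0, end0, strand, k) {
  L <- nchar(seqStr)
  cut <- function(a, b) {
    if (a < 0 || b > L || a >= b) return(NA_character_)
    s <- substr(seqStr, a + 1, b)
    if (grepl("[^ACGT]", s)) NA_character_ else s
  }
  up <- cut(start0 - k, start0)
  five <- cut(start0, start0 + k)
  three <- cut(end0 - k, end0)
  down <- cut(end0, end0 + k)
  if (end0 - start0 < k) { five <- NA_character_; three <- NA_character_ }
  if (strand == "+") {
    list(prem = up, em5 = five, em3 = three, poem = down)
  } else {
    list(prem = oracleRevComp(down), em5 = oracleRevComp(three),
         em3 = oracleRevComp(five), poem = oracleRevComp(up))
  }
}

# Brute-force spectrum: tabulate oracle motifs over the full 4^k domain.
oracleSpectrum <- function(seqStr, start0, end0, strand, k, class) {
  motifs <- vapply(seq_along(start0), function(i) {
    oracleQuartet(seqStr, start0[i], end0[i], strand[i], k)[[class]]
  }, character(1))
  motifs <- motifs[!is.na(motifs)]
  dom <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                stringsAsFactors = FALSE)[, k:1,
                                                          drop = FALSE],
                    1, paste, collapse = ""))
  tab <- table(factor(motifs, levels = dom))
  setNames(as.numeric(tab), dom)
}

# 4-end motif oracle by direct base pairing on a character genome.
oracleFourEnd <- function(seqStr, wStart0, wEnd0, cStart0, cEnd0, spec) {
  piece <- function(a, b) substr(seqStr, a + 1, b)
  w <- piece(wStart0, wEnd0)
  crick <- oracleRevComp(piece(cStart0, cEnd0))
  w5 <- substr(w, 1, spec[1])
  w3 <- substr(w, nchar(w) - spec[2] + 1, nchar(w))
  if (spec[2] == 0) w3 <- ""
  c5 <- substr(crick, 1, spec[3])
  c3 <- substr(crick, nchar(crick) - spec[4] + 1, nchar(crick))
  if (spec[4] == 0) c3 <- ""
  paste0(w5, "\u2192", w3, c3, "\u2190", c5)
}

# Random character genome and random fragments on it (0-based half-open).
randomGenomeStr <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

randomFragments0 <- function(L, n, seed, minSize = 20, maxSize = 120) {
  set.seed(seed)
  size <- sample(minSize:maxSize, n, replace = TRUE)
  start0 <- vapply(size, function(s) sample(0:(L - s), 1), numeric(1))
  data.frame(start0 = start0, end0 = start0 + size,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

asGenome <- function(seqStr, name = "chr1") {
  g <- Biostrings::DNAStringSet(seqStr)
  names(g) <- name
  g
}

asGRanges <- function(df, chrom = "chr1") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(df$start0 + 1, df$end0),
                         strand = df$strand)
}

TOY_GENOME <- "AACCGGTTACGTAACCGGTT"
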