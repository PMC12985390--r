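#' Simulation configuration
#'
#' Bundles the generative parameters of the fragment simulator. The
#' defaults encode the study conditions the simulator emulates: a bimodal
#' fragment-size distribution with peaks at 52 and 166 nt (the short
#' component carrying a mild 10-nt periodic comb), motif-biased cleavage,
#' methylation-dependent cutting near hypermethylated CpGs (5' ends at
#' the C, 3' ends 1 nt before it), and case-group effects that down-weight
#' the short-size component and shift selected end-motif contexts.
#'
#' @param genomeLength Reference length in bp.
#' @param gcFraction GC content of the simulated reference.
#' @param sizeMeans,sizeSds,sizeWeights Two-component size mixture (nt).
#' @param combAmplitude Amplitude of the 10-nt cosine comb on the short
#'   component (0 = off).
#' @param combPeriod Comb period in nt.
#' @param cutBias5,cutBias3 Named 4-mer -> weight maps for the 5'-side
#'   (EM5) and 3'-side (EM3) cleavage contexts; unnamed motifs have
#'   weight 1.
#' @param groupEffect5,groupEffect3 Extra multiplicative weights applied
#'   to case samples only.
#' @param caseSizeShift Multipliers on the case-group size density for the
#'   short (42-70), mid (70-166) and long (>166) ranges.
#' @param methylFrac Fraction of fragments anchored at hypermethylated
#'   CpGs.
#' @param methylOffset5,methylOffset3 Offsets (nt, relative to the CpG C)
#'   at which anchored 5'/3' ends are placed.
#' @param jaggedProbs Probabilities of blunt / 5'-overhang / 3'-overhang
#'   per duplex side.
#' @param jaggedMaxLen Maximum overhang length drawn (1..20 support).
#' @param nFragments Fragments per sample.
#' @param nSamples Samples per group.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(genomeLength = 2e5, gcFraction = 0.42,
                      sizeMeans = c(52, 166), sizeSds = c(6, 15),
                      sizeWeights = c(0.35, 0.65),
                      combAmplitude = 0.3, combPeriod = 10,
                      cutBias5 = c(CCCA = 3, CCAG = 2.5, CCTG = 2.5),
                      cutBias3 = c(TTTT = 3, ATTT = 2.5, TTCT = 2.5),
                      groupEffect5 = numeric(), groupEffect3 = numeric(),
                      caseSizeShift = c(short = 0.6, mid = 1.2,
                                        long = 0.9),
                      methylFrac = 0.05, methylOffset5 = 0L,
                      methylOffset3 = -1L,
                      jaggedProbs = c(blunt = 0.4, five_prime = 0.35,
                                      three_prime = 0.25),
                      jaggedMaxLen = 12L,
                      nFragments = 5000L, nSamples = 20L) {
  stopifnot(gcFraction > 0, gcFraction < 1,
            length(sizeMeans) == 2, all(sizeWeights > 0),
            abs(sum(jaggedProbs) - 1) < 1e-8,
            jaggedMaxLen >= 1, jaggedMaxLen <= 20)
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the requested GC fraction; deterministic under a seed.
#'
#' @param config A \code{\link{simConfig}}.
#' @param seed Integer seed.
#' @param contigName Contig name.
#' @return A \code{DNAStringSet} with one contig.
#' @export
simulateReference <- function(config = simConfig(), seed = 1L,
                              contigName = "sim1") {
  set.seed(seed)
  gc <- config$gcFraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), config$genomeLength, replace = TRUE, prob = p)
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- contigName
  genome
}

#' Simulate a CpG methylation table
#'
#' Finds CpG sites in the genome and assigns per-tissue methylation
#' densities so that the four analysis categories (tissue-wide
#' hyper/hypo, HCC-specific hyper/hypo) are each populated and respect
#' the 70/30 classification rules by construction.
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param tissues Normal-tissue column names (must include
#'   \code{buffyCol}).
#' @param tumorCol,buffyCol Tumour and buffy-coat column names.
#' @param proportions Category proportions (tissue_hyper, tissue_hypo,
#'   hcc_specific_hyper, hcc_specific_hypo, unclassified).
#' @param seed Integer seed.
#' @return \code{data.frame}: \code{chrom}, \code{pos} (0-based C), one
#'   density column per tissue/tumour, and the generating \code{label}.
#' @export
simulateMethylome <- function(genome,
                              tissues = c("buffy_coat", "liver", "colon"),
                              tumorCol = "hcc_tumor",
                              buffyCol = "buffy_coat",
                              proportions = c(0.25, 0.25, 0.15, 0.15,
                                              0.20),
                              seed = 1L) {
  set.seed(seed)
  sites <- do.call(rbind, lapply(names(genome), function(ctg) {
    hits <- Biostrings::matchPattern("CG", genome[[ctg]])
    data.frame(chrom = ctg, pos = BiocGenerics::start(hits) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (nrow(sites) < 100) stop("too few CpGs in genome (need >= 100)")
  labels <- sample(CPG_CLASSES, nrow(sites), replace = TRUE,
                   prob = proportions)
  n <- nrow(sites)
  hi <- function(m) runif(m, 75, 95)
  lo <- function(m) runif(m, 2, 25)
  mid <- function(m) runif(m, 35, 65)
  cols <- unique(c(tissues, tumorCol))
  dens <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (j in cols) dens[, j] <- mid(n)
  isTH <- labels == "tissue_hyper"
  isTL <- labels == "tissue_hypo"
  isHH <- labels == "hcc_specific_hyper"
  isHL <- labels == "hcc_specific_hypo"
  for (j in cols) {
    dens[isTH, j] <- hi(sum(isTH))
    dens[isTL, j] <- lo(sum(isTL))
  }
  dens[isHH, tumorCol] <- hi(sum(isHH))
  dens[isHH, buffyCol] <- lo(sum(isHH))
  dens[isHL, tumorCol] <- lo(sum(isHL))
  dens[isHL, buffyCol] <- hi(sum(isHL))
  cbind(sites, as.data.frame(dens),
        data.frame(label = factor(labels, levels = CPG_CLASSES)))
}

# Size density of the two-component mixture on an integer grid, with the
# 10-nt comb on the short component and optional case-group range shifts.
.sizeDensity <- function(config, sizes, isCase) {
  d1 <- exp(-(sizes - config$sizeMeans[1])^2 / (2 * config$sizeSds[1]^2))
  d1 <- d1 * (1 + config$combAmplitude *
                cos(2 * pi * (sizes - config$sizeMeans[1]) /
                      config$combPeriod))
  d2 <- exp(-(sizes - config$sizeMeans[2])^2 / (2 * config$sizeSds[2]^2))
  w <- config$sizeWeights / sum(config$sizeWeights)
  dens <- w[1] * d1 / sum(d1) + w[2] * d2 / sum(d2)
  if (isCase) {
    shift <- rep(1, length(sizes))
    shift[sizes >= 42 & sizes < 70] <- config$caseSizeShift[["short"]]
    shift[sizes >= 70 & sizes < 166] <- config$caseSizeShift[["mid"]]
    shift[sizes >= 166] <- config$caseSizeShift[["long"]]
    dens <- dens * shift
  }
  dens / sum(dens)
}

# Per-position 4-mer index of the plus strand (NA where the window is
# incomplete or contains N); used to score cleavage contexts quickly.
.kmerIndex <- function(genome, k = 4) {
  lapply(seq_along(genome), function(ci) {
    s <- as.character(genome[[ci]])
    L <- nchar(s)
    if (L < k) return(rep(NA_integer_, L))
    kmers <- substring(s, 1:(L - k + 1), k:L)
    idx <- match(kmers, allKmers(k))
    c(idx, rep(NA_integer_, k - 1))
  })
}

# Weight-per-position lookup from a named bias map (log-free, >= 0).
.biasVector <- function(kmerIdx, bias, k = 4) {
  w <- rep(1, 4^k)
  if (length(bias)) w[match(names(bias), allKmers(k))] <- bias
  out <- w[kmerIdx]
  out[is.na(out)] <- 0
  out
}

#' Simulate a two-group fragment cohort
#'
#' Draws fragments per sample by (1) sampling a size from the bimodal
#' mixture (case samples apply the configured range shifts), (2)
#' rejection-sampling a start position with acceptance probability
#' proportional to the product of the 5'-side and 3'-side 4-mer context
#' weights (case samples additionally apply the group effects), and (3)
#' re-anchoring a configured fraction of fragments so their 5' (or 3')
#' end sits at the configured offset from a hypermethylated CpG. Plus and
#' minus strands are emitted 50/50; motif contexts are evaluated in the
#' molecule's own frame.
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param methylome Optional CpG table from
#'   \code{\link{simulateMethylome}} (required when
#'   \code{config$methylFrac > 0}).
#' @param config A \code{\link{simConfig}}.
#' @param seed Integer seed.
#' @return A \linkS4class{FragmentCohort} with \code{nSamples} controls
#'   followed by \code{nSamples} cases.
#' @export
simulateCohort <- function(genome, methylome = NULL,
                           config = simConfig(), seed = 1L) {
  set.seed(seed)
  k <- 4
  kidx <- .kmerIndex(genome, k)
  lens <- Biostrings::width(genome)
  dom <- allKmers(k)
  rcIdx <- match(revComp(dom), dom)

  hyperSites <- NULL
  if (config$methylFrac > 0) {
    if (is.null(methylome))
      stop("methylome required when methylFrac > 0")
    hyperSites <- methylome[methylome$label %in%
                              c("tissue_hyper", "hcc_specific_hyper"), ]
    if (nrow(hyperSites) == 0) stop("no hypermethylated CpGs available")
  }

  sizes <- 20:600
  densCtrl <- .sizeDensity(config, sizes, isCase = FALSE)
  densCase <- .sizeDensity(config, sizes, isCase = TRUE)

  drawSample <- function(isCase) {
    b5 <- config$cutBias5
    b3 <- config$cutBias3
    if (isCase) {
      for (m in names(config$groupEffect5))
        b5[m] <- (if (m %in% names(b5)) b5[m] else 1) *
          config$groupEffect5[m]
      for (m in names(config$groupEffect3))
        b3[m] <- (if (m %in% names(b3)) b3[m] else 1) *
          config$groupEffect3[m]
    }
    w5map <- rep(1, 4^k)
    if (length(b5)) w5map[match(names(b5), dom)] <- b5
    w3map <- rep(1, 4^k)
    if (length(b3)) w3map[match(names(b3), dom)] <- b3
    maxW <- max(w5map) * max(w3map)

    n <- config$nFragments
    out <- vector("list", 0)
    got <- 0L
    dens <- if (isCase) densCase else densCtrl
    while (got < n) {
      m <- min(4L * (n - got), 4L * n)
      sz <- sample(sizes, m, replace = TRUE, prob = dens)
      ci <- if (length(genome) == 1) rep(1L, m) else
        sample(seq_along(genome), m, replace = TRUE,
               prob = lens / sum(lens))
      maxS <- lens[ci] - sz + 1L
      ok0 <- maxS >= 1L
      st <- ifelse(ok0, 1L + floor(runif(m) * maxS), NA_integer_)
      en <- st + sz - 1L
      strandMinus <- runif(m) < 0.5
      # molecule-frame EM5/EM3 4-mer indices
      i5 <- integer(m); i3 <- integer(m)
      for (cc in unique(ci)) {
        sel <- which(ci == cc & ok0)
        kv <- kidx[[cc]]
        plus5 <- kv[st[sel]]
        plus3 <- kv[pmax(en[sel] - k + 1L, 1L)]
        i5[sel] <- ifelse(strandMinus[sel], rcIdx[plus3], plus5)
        i3[sel] <- ifelse(strandMinus[sel], rcIdx[plus5], plus3)
      }
      wgt <- w5map[i5] * w3map[i3]
      wgt[is.na(wgt)] <- 0
      acc <- ok0 & runif(m) < wgt / maxW
      if (any(acc)) {
        out[[length(out) + 1L]] <- data.frame(
          ci = ci[acc], st = st[acc], en = en[acc],
          minus = strandMinus[acc])
        got <- got + sum(acc)
      }
    }
    df <- do.call(rbind, out)[seq_len(n), ]

    # methylation-anchored re-placement
    if (config$methylFrac > 0) {
      nAnchor <- rbinom(1, n, config$methylFrac)
      if (nAnchor > 0) {
        pick <- sample(nrow(hyperSites), nAnchor, replace = TRUE)
        rows <- sample(n, nAnchor)
        cPos1 <- hyperSites$pos[pick] + 1L
        ctgIdx <- match(hyperSites$chrom[pick], names(genome))
        anchor5 <- runif(nAnchor) < 0.5
        sz <- df$en[rows] - df$st[rows] + 1L
        minus <- df$minus[rows]
        # Watson frame: 5' end at C + offset5; 3' end at C + offset3.
        # Crick frame mirrors about the G (C position + 1).
        st <- integer(nAnchor); en <- integer(nAnchor)
        for (j in seq_len(nAnchor)) {
          if (!minus[j] && anchor5[j]) {
            st[j] <- cPos1[j] + config$methylOffset5
            en[j] <- st[j] + sz[j] - 1L
          } else if (!minus[j] && !anchor5[j]) {
            en[j] <- cPos1[j] + config$methylOffset3
            st[j] <- en[j] - sz[j] + 1L
          } else if (minus[j] && anchor5[j]) {
            en[j] <- (cPos1[j] + 1L) - config$methylOffset5
            st[j] <- en[j] - sz[j] + 1L
          } else {
            st[j] <- (cPos1[j] + 1L) - config$methylOffset3
            en[j] <- st[j] + sz[j] - 1L
          }
        }
        okA <- st >= 1L & en <= lens[ctgIdx]
        df$ci[rows[okA]] <- ctgIdx[okA]
        df$st[rows[okA]] <- st[okA]
        df$en[rows[okA]] <- en[okA]
      }
    }
    GenomicRanges::GRanges(
      seqnames = names(genome)[df$ci],
      ranges = IRanges::IRanges(df$st, df$en),
      strand = ifelse(df$minus, "-", "+"))
  }

  nS <- config$nSamples
  frags <- c(lapply(seq_len(nS), function(i) drawSample(FALSE)),
             lapply(seq_len(nS), function(i) drawSample(TRUE)))
  names(frags) <- c(paste0("control", seq_len(nS)),
                    paste0("case", seq_len(nS)))
  FragmentCohort(frags, rep(c("control", "case"), each = nS))
}

#' Simulate duplex molecules with jagged ends
#'
#' Draws duplex cores from the size mixture at uniform positions, then
#' draws each side's end modality from the jagged mixture. When a
#' nuclease model is supplied, cut sites are chosen so that the 5' 2-mer
#' of one strand and the 3' 2-mer of the complementary strand at each
#' side match the signature of a nuclease drawn by activity weight
#' (rejection sampling against the genome sequence).
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param config A \code{\link{simConfig}}.
#' @param nMolecules Number of molecules.
#' @param nucleaseModel Optional named numeric of activity weights (e.g.
#'   \code{c(DNASE1L3 = 1)}), using \code{\link{nucleaseSignatures}}.
#' @param seed Integer seed.
#' @return List with \code{molecules} (duplex \code{data.frame}) and
#'   \code{records} (barcoded read records from
#'   \code{\link{encodeMolecules}}).
#' @export
simulateDsMolecules <- function(genome, config = simConfig(),
                                nMolecules = 2000, nucleaseModel = NULL,
                                seed = 1L) {
  set.seed(seed)
  lens <- Biostrings::width(genome)
  sizes <- 20:600
  dens <- .sizeDensity(config, sizes, isCase = FALSE)

  sigs <- nucleaseSignatures()
  # per-position plus-strand 2-mer strings for signature matching
  twoMer <- lapply(seq_along(genome), function(ci) {
    s <- as.character(genome[[ci]])
    L <- nchar(s)
    c(substring(s, 1:(L - 1), 2:L), NA_character_)
  })

  drawJag <- function(n) {
    kind <- sample(names(config$jaggedProbs), n, replace = TRUE,
                   prob = config$jaggedProbs)
    len <- ifelse(kind == "blunt", 0L,
                  sample.int(config$jaggedMaxLen, n, replace = TRUE))
    data.frame(kind = kind, len = len, stringsAsFactors = FALSE)
  }

  n <- nMolecules
  ci <- if (length(genome) == 1) rep(1L, n) else
    sample(seq_along(genome), n, replace = TRUE, prob = lens / sum(lens))
  sz <- sample(sizes, n, replace = TRUE, prob = dens)
  ws <- integer(n); we <- integer(n)
  cs <- integer(n); ce <- integer(n)
  jagL <- drawJag(n); jagR <- drawJag(n)

  if (is.null(nucleaseModel)) {
    maxS <- lens[ci] - sz - 45L
    st <- 22L + floor(runif(n) * pmax(maxS, 1))
    ws <- st; we <- st + sz
    cs <- ws + ifelse(jagL$kind == "five_prime", jagL$len,
                      ifelse(jagL$kind == "three_prime", -jagL$len, 0L))
    ce <- we + ifelse(jagR$kind == "five_prime", jagR$len,
                      ifelse(jagR$kind == "three_prime", -jagR$len, 0L))
  } else {
    nucNames <- names(nucleaseModel)
    stopifnot(all(nucNames %in% names(sigs)), length(nucNames) >= 1)
    for (i in seq_len(n)) {
      nucL <- sample(nucNames, 1, prob = nucleaseModel)
      nucR <- sample(nucNames, 1, prob = nucleaseModel)
      tm <- twoMer[[ci[i]]]
      L <- lens[ci[i]]
      repeat {
        w_s <- 25L + sample.int(max(L - sz[i] - 55L, 1L), 1)
        # left side: Watson 5' 2-mer at w_s, Crick 3' 2-mer revcomp at c_s
        if (!tm[w_s] %in% sigs[[nucL]]$five) next
        offL <- (-config$jaggedMaxLen):config$jaggedMaxLen
        candL <- w_s + offL
        okL <- candL >= 1 & candL <= L - 1 &
          revComp(tm[candL]) %in% sigs[[nucL]]$three
        if (!any(okL)) next
        c_s <- sample(rep(candL[okL], 2), 1)
        # right side: Watson 3' 2-mer is the last two Watson bases
        # (positions w_e-2..w_e-1); Crick 5' 2-mer ends at c_e-1
        w_e <- w_s + sz[i]
        if (w_e - 1L > L || !tm[w_e - 2L] %in% sigs[[nucR]]$three) next
        candR <- w_e + offL
        okR <- candR >= 3 & candR - 1L <= L &
          revComp(tm[candR - 2L]) %in% sigs[[nucR]]$five
        if (!any(okR)) next
        c_e <- sample(rep(candR[okR], 2), 1)
        ws[i] <- w_s; we[i] <- w_e; cs[i] <- c_s; ce[i] <- c_e
        break
      }
    }
  }
  # overlap sanity: drop degenerate geometries
  mols <- data.frame(chrom = names(genome)[ci], w_start = ws - 1L,
                     w_end = we - 1L, c_start = cs - 1L,
                     c_end = ce - 1L, stringsAsFactors = FALSE)
  ok <- mols$c_start < mols$w_end & mols$w_start < mols$c_end &
    mols$w_start >= 0 & mols$c_start >= 0
  mols <- mols[ok, ]
  enc <- encodeMolecules(mols)
  list(molecules = mols, records = enc$records)
}

#' Simulate a sonicated (uniform-cut) control
#'
#' Fragments cut uniformly at random with no motif bias; with many
#' fragments the end-motif spectrum converges to
#' \code{\link{expectedGenomeFrequency}}.
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param n Number of fragments.
#' @param config A \code{\link{simConfig}} (size mixture only).
#' @param seed Integer seed.
#' @return A fragment \code{GRanges}.
#' @export
simulateSonicated <- function(genome, n = 10000, config = simConfig(),
                              seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  lens <- Biostrings::width(genome)
  sizes <- 20:600
  dens <- .sizeDensity(config, sizes, isCase = FALSE)
  ci <- if (length(genome) == 1) rep(1L, n) else
    sample(seq_along(genome), n, replace = TRUE, prob = lens / sum(lens))
  sz <- sample(sizes, n, replace = TRUE, prob = dens)
  maxS <- lens[ci] - sz + 1L
  keep <- maxS >= 1L
  st <- 1L + floor(runif(sum(keep)) * maxS[keep])
  GenomicRanges::GRanges(
    seqnames = names(genome)[ci[keep]],
    ranges = IRanges::IRanges(st, st + sz[keep] - 1L),
    strand = ifelse(runif(sum(keep)) < 0.5, "-", "+"))
}
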