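genome <- asGenome(TOY_GENOME)

test_that("end-motif quartet matches hand-derived values on both strands", {
  plus <- extractEndMotifs(asGRanges(data.frame(start0 = 8, end0 = 16,
                                                strand = "+")), genome, 4)
  expect_equal(as.character(plus[1, ]), c("GGTT", "ACGT", "AACC", "GGTT"))

  minus <- extractEndMotifs(asGRanges(data.frame(start0 = 8, end0 = 16,
                                                 strand = "-")), genome, 4)
  expect_equal(as.character(minus[1, ]), c("AACC", "GGTT", "ACGT", "AACC"))

  # upstream flank out of bounds -> PREM unavailable
  left <- extractEndMotifs(asGRanges(data.frame(start0 = 0, end0 = 8,
                                                strand = "+")), genome, 4)
  expect_true(is.na(left$prem))
  expect_equal(left$em5, "AACC")

  # fragment shorter than k loses EM5/EM3 but keeps flanks
  tiny <- extractEndMotifs(asGRanges(data.frame(start0 = 8, end0 = 10,
                                                strand = "+")), genome, 4)
  expect_true(is.na(tiny$em5) && is.na(tiny$em3))
  expect_equal(tiny$poem, "GTAA")

  # N in the motif window -> unavailable
  gN <- asGenome("AACCGGTTACNTAACCGGTT")
  withN <- extractEndMotifs(asGRanges(data.frame(start0 = 8, end0 = 16,
                                                 strand = "+")), gN, 4)
  expect_true(is.na(withN$em5))
  expect_equal(withN$prem, "GGTT")
})

test_that("quartets agree with the string-slicing oracle on random fragments", {
  L <- 500
  seqStr <- randomGenomeStr(L, seed = 11)
  frags <- randomFragments0(L, 200, seed = 12, minSize = 3, maxSize = 60)
  got <- extractEndMotifs(asGRanges(frags), asGenome(seqStr), 4)
  for (i in seq_len(nrow(frags))) {
    exp <- oracleQuartet(seqStr, frags$start0[i], frags$end0[i],
                         frags$strand[i], 4)
    expect_identical(unname(unlist(got[i, ])), unname(unlist(exp)),
                     info = paste("fragment", i))
  }
})

test_that("motif spectra cover the 4^k domain and match brute-force counts", {
  L <- 800
  seqStr <- randomGenomeStr(L, seed = 21)
  frags <- randomFragments0(L, 100, seed = 22)
  gr <- asGRanges(frags)
  g <- asGenome(seqStr)
  for (cls in c("prem", "em5", "em3", "poem")) {
    spec <- motifSpectrum(gr, g, toupper(cls), k = 4)
    expect_length(motifCounts(spec), 256)
    expect_equal(motifCounts(spec),
                 oracleSpectrum(seqStr, frags$start0, frags$end0,
                                frags$strand, 4, cls))
    expect_equal(sum(motifFrequencies(spec)), 1, tolerance = 1e-9)
  }
  # two identical fragments -> a frequency-1 spectrum
  two <- asGRanges(data.frame(start0 = c(8, 8), end0 = c(16, 16),
                              strand = "+"))
  sp <- motifSpectrum(two, genome, "EM5", 4)
  f <- motifFrequencies(sp)
  expect_equal(unname(f["ACGT"]), 1)
  expect_equal(sum(f), 1)
})

test_that("expected genome frequencies count both strands", {
  expect_equal(expectedGenomeFrequency(asGenome("AAAA"), 4)[c("AAAA",
                                                              "TTTT")],
               c(AAAA = 0.5, TTTT = 0.5))
  # exhaustive window enumeration oracle on a short genome
  s <- "ACGTACGT"
  fwd <- substring(s, 1:5, 4:8)
  rev <- vapply(fwd, oracleRevComp, character(1))
  dom <- allKmers(4)
  oracle <- table(factor(c(fwd, rev), levels = dom))
  oracle <- setNames(as.numeric(oracle) / sum(oracle), dom)
  expect_equal(expectedGenomeFrequency(asGenome(s), 4), oracle)
  expect_error(expectedGenomeFrequency(asGenome("ACG"), 4), "shorter")
})

test_that("bias correction obeys its algebraic identities", {
  dom <- allKmers(2)
  set.seed(3)
  expected <- setNames(as.numeric(rmultinom(1, 5000, rep(1, 16))), dom)
  expected <- expected / sum(expected)
  plasma <- setNames(as.numeric(rmultinom(1, 5000, seq_len(16))), dom)
  plasma <- plasma / sum(plasma)

  # sonicated == expected motif-wise -> corrected == plasma
  expect_equal(correctFrequencies(plasma, expected, expected), plasma)
  # plasma == sonicated motif-wise -> corrected == expected
  expect_equal(correctFrequencies(plasma, plasma, expected), expected)
  # motif-wise arithmetic: 0.08 / 0.04 * 0.02 = 0.04 before renormalising
  p <- c(X = 0.08, Y = 0.92); s <- c(X = 0.04, Y = 0.96)
  e <- c(X = 0.02, Y = 0.98)
  raw <- p / s * e
  expect_equal(unname(raw["X"]), 0.04)
  expect_equal(correctFrequencies(p, s, e), raw / sum(raw))
  expect_error(correctFrequencies(p, s, c(X = 0.5, Y = 0.4)), "sum to 1")
})

test_that("size profile finds histogram counts and bimodal modes", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(1, c(50, 50, 166)))
  prof <- sizeProfile(gr)
  expect_equal(unname(prof$histogram[c("50", "166")]), c(2, 1))
  expect_warning(sizeProfile(GenomicRanges::GRanges()), "no fragments")
})

test_that("size stratification uses half-open intervals", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(1, c(70, 166, 30, 600)))
  expect_message(strata <- stratifyBySize(gr), "outside all strata")
  expect_equal(GenomicRanges::width(strata[["70-166"]]), 70)
  expect_equal(GenomicRanges::width(strata[["166-601"]]), c(166, 600))
  expect_length(strata[["42-70"]], 0)
  bad <- cbind(lo = c(42, 60), hi = c(70, 166))
  expect_error(stratifyBySize(gr, bad), "overlap")
})

test_that("per-stratum spectra sum count-wise to the pooled spectrum", {
  L <- 5000
  seqStr <- randomGenomeStr(L, seed = 31)
  frags <- randomFragments0(L, 400, seed = 32, minSize = 42,
                            maxSize = 400)
  gr <- asGRanges(frags)
  g <- asGenome(seqStr)
  total <- motifCounts(motifSpectrum(gr, g, "EM5", 4,
                                     sizeRange = c(42, 601)))
  strat <- defaultSizeStrata()
  parts <- lapply(seq_len(nrow(strat)), function(i)
    motifCounts(motifSpectrum(gr, g, "EM5", 4, strat[i, ])))
  expect_equal(Reduce(`+`, parts), total)
})

test_that("spectra are invariant under genome reverse complementation", {
  L <- 1000
  seqStr <- randomGenomeStr(L, seed = 41)
  frags <- randomFragments0(L, 150, seed = 42)
  g <- asGenome(seqStr)
  gRC <- asGenome(oracleRevComp(seqStr))
  fragsRC <- data.frame(start0 = L - frags$end0, end0 = L - frags$start0,
                        strand = ifelse(frags$strand == "+", "-", "+"))
  for (cls in c("PREM", "EM5", "EM3", "POEM")) {
    expect_equal(
      motifCounts(motifSpectrum(asGRanges(frags), g, cls, 4)),
      motifCounts(motifSpectrum(asGRanges(fragsRC), gRC, cls, 4)),
      info = cls)
  }
})

test_that("partition of a contig links PREM to EM3 and POEM to EM5", {
  L <- 3000
  seqStr <- randomGenomeStr(L, seed = 51)
  set.seed(52)
  # cuts at least k apart so every fragment carries full EM5/EM3 motifs
  cuts <- sort(sample(seq(100, L - 100, by = 10), 60))
  bounds <- c(0, cuts, L)
  start0 <- bounds[-length(bounds)]
  end0 <- bounds[-1]
  g <- asGenome(seqStr)
  n <- length(start0)
  mk <- function(idx) asGRanges(data.frame(start0 = start0[idx],
                                           end0 = end0[idx],
                                           strand = "+"))
  # PREM of fragments 2..n equals EM3 of fragments 1..n-1, and POEM of
  # 1..n-1 equals EM5 of 2..n: abutting cuts share their cleavage site
  prem <- motifCounts(motifSpectrum(mk(2:n), g, "PREM", 4))
  em3 <- motifCounts(motifSpectrum(mk(1:(n - 1)), g, "EM3", 4))
  expect_equal(prem, em3)
  poem <- motifCounts(motifSpectrum(mk(1:(n - 1)), g, "POEM", 4))
  em5 <- motifCounts(motifSpectrum(mk(2:n), g, "EM5", 4))
  expect_equal(poem, em5)
})
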