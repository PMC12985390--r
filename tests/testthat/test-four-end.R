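test_that("adapter pool covers all 41 modalities with distance-2 barcodes", {
  pool <- buildAdapterPool()
  expect_equal(nrow(pool), 41)
  expect_equal(sum(pool$kind == "blunt"), 1)
  expect_equal(sort(pool$overhang_len[pool$kind == "five_prime"]), 1:20)
  expect_equal(sort(pool$overhang_len[pool$kind == "three_prime"]), 1:20)
  expect_false(anyDuplicated(pool$barcode) > 0)
  pairs <- utils::combn(pool$barcode, 2)
  dists <- apply(pairs, 2, function(p) {
    sum(strsplit(p[1], "")[[1]] != strsplit(p[2], "")[[1]])
  })
  expect_gte(min(dists), 2)
})

test_that("jagged typing follows duplex geometry", {
  mols <- data.frame(
    chrom = "chr1",
    w_start = c(100, 100, 100), w_end = c(200, 200, 205),
    c_start = c(100, 103, 100), c_end = c(200, 200, 200))
  left <- jaggedType(mols, "left")
  expect_equal(left$type, c("blunt", "five_prime_jagged", "blunt"))
  expect_equal(left$length, c(0, 3, 0))
  right <- jaggedType(mols, "right")
  expect_equal(right$type, c("blunt", "blunt", "three_prime_jagged"))
  expect_equal(right$length, c(0, 0, 5))
  bad <- data.frame(chrom = "chr1", w_start = 100, w_end = 150,
                    c_start = 160, c_end = 200)
  expect_error(jaggedType(bad, "left"), "overlap")
})

test_that("encode/decode round-trips every modality and rejects long overhangs", {
  pool <- buildAdapterPool()
  # all 41 x 41 left/right modality combinations
  mk <- function(kind, len, side) {
    if (side == "left") {
      cs <- 500 + ifelse(kind == "five_prime", len,
                         ifelse(kind == "three_prime", -len, 0))
      c(w_start = 500, c_start = cs)
    } else {
      ce <- 700 - ifelse(kind == "three_prime", len,
                         ifelse(kind == "five_prime", -len, 0))
      c(w_end = 700, c_end = ce)
    }
  }
  grid <- expand.grid(l = seq_len(nrow(pool)), r = seq_len(nrow(pool)))
  mols <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    L <- mk(pool$kind[grid$l[i]], pool$overhang_len[grid$l[i]], "left")
    R <- mk(pool$kind[grid$r[i]], pool$overhang_len[grid$r[i]], "right")
    data.frame(chrom = "chr1", w_start = L[["w_start"]],
               w_end = R[["w_end"]], c_start = L[["c_start"]],
               c_end = R[["c_end"]])
  }))
  enc <- encodeMolecules(mols, pool)
  expect_equal(enc$dropped, 0)
  dec <- decodeReads(enc$records, pool)
  expect_equal(dec$rejected, 0)
  expect_equal(dec$molecules, mols, ignore_attr = TRUE)

  # overhang of 21 is unligatable
  long <- data.frame(chrom = "chr1", w_start = 500, w_end = 700,
                     c_start = 521, c_end = 700)
  expect_equal(encodeMolecules(long, pool)$dropped, 1)
})

test_that("single-substitution barcodes rescue; double collisions reject", {
  pool <- buildAdapterPool()
  mol <- data.frame(chrom = "chr1", w_start = 500, w_end = 700,
                    c_start = 503, c_end = 695)
  rec <- encodeMolecules(mol, pool)$records
  flip <- function(code, i, to) {
    substr(code, i, i) <- to
    code
  }
  # one substitution in the left barcode: rescued to the true adapter
  mut <- rec
  orig <- substr(mut$left_barcode, 2, 2)
  mut$left_barcode <- flip(mut$left_barcode, 2,
                           setdiff(c("A", "C", "G", "T"), orig)[1])
  dec <- decodeReads(mut, pool)
  expect_equal(dec$rejected, 0)
  expect_equal(dec$molecules, mol, ignore_attr = TRUE)
  # a code at distance >= 2 from every pool barcode is rejected
  mut2 <- rec
  repeat {
    cand <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                  collapse = "")
    d <- vapply(pool$barcode, function(b)
      sum(strsplit(b, "")[[1]] != strsplit(cand, "")[[1]]), numeric(1))
    if (min(d) >= 2) break
  }
  mut2$left_barcode <- cand
  expect_equal(decodeReads(mut2, pool)$rejected, 1)
})

test_that("round trip is exact on 10^4 random molecules", {
  set.seed(71)
  n <- 10000
  ws <- sample(100:10000, n, replace = TRUE)
  sz <- sample(40:400, n, replace = TRUE)
  kindL <- sample(c("blunt", "five_prime", "three_prime"), n,
                  replace = TRUE)
  kindR <- sample(c("blunt", "five_prime", "three_prime"), n,
                  replace = TRUE)
  lenL <- ifelse(kindL == "blunt", 0, sample(1:20, n, replace = TRUE))
  lenR <- ifelse(kindR == "blunt", 0, sample(1:20, n, replace = TRUE))
  mols <- data.frame(
    chrom = "chr1", w_start = ws, w_end = ws + sz,
    c_start = ws + ifelse(kindL == "five_prime", lenL, -lenL),
    c_end = ws + sz - ifelse(kindR == "three_prime", lenR, -lenR))
  enc <- encodeMolecules(mols)
  expect_equal(enc$dropped, 0)
  dec <- decodeReads(enc$records)
  expect_equal(dec$rejected, 0)
  expect_equal(dec$molecules, mols, ignore_attr = TRUE)
})

test_that("4-end motifs match manual base pairing and the oracle", {
  g <- asGenome("ACGTACGTACGT")
  blunt <- data.frame(chrom = "chr1", w_start = 0, w_end = 4,
                      c_start = 0, c_end = 4)
  expect_equal(fourEndMotif(blunt, g, c(1, 1, 1, 1)), "A→TT←A")
  expect_equal(fourEndMotif(blunt, g, c(2, 2, 0, 0)), "AC→GT←")
  expect_equal(length(fourEndMotifSpace(c(1, 1, 1, 1))), 256)
  expect_equal(length(fourEndMotifSpace(c(2, 0, 0, 2))), 256)

  # random jagged molecules against the string oracle
  L <- 2000
  seqStr <- randomGenomeStr(L, seed = 72)
  set.seed(73)
  n <- 500
  ws <- sample(50:(L - 300), n, replace = TRUE)
  sz <- sample(60:200, n, replace = TRUE)
  dl <- sample(-5:5, n, replace = TRUE)
  dr <- sample(-5:5, n, replace = TRUE)
  mols <- data.frame(chrom = "chr1", w_start = ws, w_end = ws + sz,
                     c_start = ws + dl, c_end = ws + sz + dr)
  gg <- asGenome(seqStr)
  for (spec in list(c(1, 1, 1, 1), c(2, 2, 0, 0), c(2, 0, 0, 2))) {
    got <- fourEndMotif(mols, gg, spec)
    exp <- vapply(seq_len(n), function(i)
      oracleFourEnd(seqStr, mols$w_start[i], mols$w_end[i],
                    mols$c_start[i], mols$c_end[i], spec), character(1))
    expect_identical(got, exp)
  }
  # spectrum counts equal brute-force tabulation
  spec4 <- fourEndSpectrum(mols, gg, c(1, 1, 1, 1))
  exp <- vapply(seq_len(n), function(i)
    oracleFourEnd(seqStr, mols$w_start[i], mols$w_end[i],
                  mols$c_start[i], mols$c_end[i], c(1, 1, 1, 1)),
    character(1))
  tab <- table(factor(exp, levels = fourEndMotifSpace(c(1, 1, 1, 1))))
  expect_equal(motifCounts(spec4), setNames(as.numeric(tab), names(tab)))
})

test_that("4-end spectra marginalise to single-strand spectra and pair bluntly", {
  L <- 3000
  seqStr <- randomGenomeStr(L, seed = 74)
  g <- asGenome(seqStr)
  set.seed(75)
  n <- 400
  ws <- sample(50:(L - 300), n, replace = TRUE)
  sz <- sample(60:200, n, replace = TRUE)
  mols <- data.frame(chrom = "chr1", w_start = ws, w_end = ws + sz,
                     c_start = ws, c_end = ws + sz)
  # Watson 5' 1-mer marginal == EM5 1-mer spectrum of the Watson strands
  m4 <- motifFrequencies(fourEndSpectrum(mols, g, c(1, 0, 0, 0)))
  names(m4) <- substr(names(m4), 1, 1)
  watson <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(ws + 1, ws + sz),
                                   strand = "+")
  em5 <- motifFrequencies(motifSpectrum(watson, g, "EM5", 1))
  expect_equal(m4[names(em5)], em5)
  # blunt duplexes only populate self-consistent (complementary) pairs
  f <- motifFrequencies(fourEndSpectrum(mols, g, c(1, 1, 1, 1)))
  support <- names(f)[f > 0]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (m in support) {
    ch <- strsplit(m, "")[[1]]   # w5, arrow, w3, c3, arrow, c5
    expect_equal(ch[4], unname(comp[ch[1]]))
    expect_equal(ch[6], unname(comp[ch[3]]))
  }
})

test_that("nuclease pair assignment follows the signature table", {
  # synthetic locus engineered so each side shows a chosen 2-mer pair
  #            GGxxxxxxCT            (Watson)
  # left: Watson 5' GG; Crick 3' read from c_start: revcomp(AG) = CT
  s <- paste0(strrep("T", 30), "GGAGTTTTTTCT", strrep("T", 30))
  g <- asGenome(s)
  mol <- data.frame(chrom = "chr1", w_start = 30, w_end = 42,
                    c_start = 32, c_end = 42)
  expect_equal(assignNucleasePair(mol, g, side = "left"),
               "DNASE1L3-DNASE1L3")
  # 5' CT + 3' CG -> DNASE1-DNASE1 (left side)
  s2 <- paste0(strrep("T", 30), "CTCGTTTTTTTT", strrep("T", 30))
  mol2 <- data.frame(chrom = "chr1", w_start = 30, w_end = 42,
                     c_start = 32, c_end = 42)
  expect_equal(assignNucleasePair(mol2, asGenome(s2), side = "left"),
               "DNASE1-DNASE1")
  # 5' GG + 3' GT -> mixed DFFB-DNASE1L3
  s3 <- paste0(strrep("T", 30), "GGACTTTTTTTT", strrep("T", 30))
  mol3 <- data.frame(chrom = "chr1", w_start = 30, w_end = 42,
                     c_start = 32, c_end = 42)
  expect_equal(assignNucleasePair(mol3, asGenome(s3), side = "left"),
               "DFFB-DNASE1L3")
  # unmatched motifs are unassigned; the label space has 6 categories
  s4 <- paste0(strrep("T", 30), "TTTTTTTTTTTT", strrep("T", 30))
  expect_equal(assignNucleasePair(mol3, asGenome(s4), side = "left"),
               "unassigned")
  expect_length(nucleasePairLabels(), 6)
})

test_that("signature abundance self-normalises on unbiased molecules", {
  g <- asGenome(randomGenomeStr(60000, seed = 76))
  sim <- simulateDsMolecules(g, simConfig(genomeLength = 60000),
                             nMolecules = 1500, seed = 77)
  ab <- signatureSizeAbundance(sim$molecules, g,
                               sizeBins = cbind(lo = 20, hi = 601),
                               seed = 78)
  vals <- ab[1, !is.na(ab[1, ])]
  expect_true(all(vals > 0.5 & vals < 2))
})
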