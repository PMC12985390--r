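TISSUES <- c("buffy_coat", "liver", "colon")

test_that("CpG classification applies the 70/30 rules with precedence", {
  tab <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40, 50, 60),
    buffy_coat = c(80, 10, 20, 85, 50, 40),
    liver = c(75, 25, 60, 40, 50, 80),
    colon = c(90, 15, 55, 45, 50, 80),
    hcc_tumor = c(85, 12, 85, 10, 50, 80)
  )
  lab <- classifyCpGs(tab, TISSUES)
  expect_equal(as.character(lab),
               c("tissue_hyper",        # all > 70
                 "tissue_hypo",         # all < 30
                 "hcc_specific_hyper",  # tumor 85, buffy 20
                 "hcc_specific_hypo",   # tumor 10, buffy 85
                 "unclassified",        # one tissue at 50
                 "unclassified"))       # buffy 40 blocks every rule
  # HCC-specific beats tissue-wide when both apply
  both <- data.frame(chrom = "chr1", pos = 1, buffy_coat = 10,
                     liver = 10, colon = 10, hcc_tumor = 90)
  expect_equal(as.character(classifyCpGs(both, TISSUES)),
               "hcc_specific_hyper")
  expect_error(classifyCpGs(tab[, -3], TISSUES), "missing tissue")
})

test_that("cleavage proportion is ends over depth times 100", {
  # 50 plus-strand fragments cover site 100 (0-based); 5 start there
  start0 <- c(rep(100, 5), 51:95)
  gr <- asGRanges(data.frame(start0 = start0, end0 = start0 + 60,
                             strand = "+"))
  expect_equal(cleavageProportion(gr, "chr1", 100, "5p"), 10)
  # 1 end / depth 97: 96 covering fragments none of which ends at the
  # site, plus one fragment starting exactly there
  start0 <- c(200, 104:199)
  gr2 <- asGRanges(data.frame(start0 = start0, end0 = start0 + 100,
                              strand = "+"))
  expect_equal(cleavageProportion(gr2, "chr1", 200, "5p"), 100 / 97)
  expect_warning(p <- cleavageProportion(gr2, "chr1", 5000, "5p"),
                 "no coverage")
  expect_true(is.na(p))
})

test_that("constructed cutting produces profile peaks at programmed offsets", {
  L <- 4000
  seqStr <- randomGenomeStr(L, seed = 61)
  g <- asGenome(seqStr)
  cpg <- data.frame(chrom = "chr1", pos = seq(500, 3300, by = 200))
  # 5' ends exactly at the C (plus strand), plus uniform background
  anchored <- data.frame(start0 = rep(cpg$pos, each = 4),
                         end0 = rep(cpg$pos, each = 4) + 80,
                         strand = "+")
  set.seed(62)
  bg0 <- sample(0:(L - 120), 400, replace = TRUE)
  background <- data.frame(start0 = bg0, end0 = bg0 + 100, strand = "+")
  gr <- asGRanges(rbind(anchored, background))
  prof5 <- cleavageProfile(gr, cpg, "5p", window = 5)
  v5 <- profileValues(prof5)
  expect_equal(names(which.max(v5)), "0")
  # 3' ends 1 nt before the C: terminal base at pos - 1
  anchored3 <- data.frame(start0 = rep(cpg$pos, each = 4) - 80,
                          end0 = rep(cpg$pos, each = 4),
                          strand = "+")
  gr3 <- asGRanges(rbind(anchored3, background))
  prof3 <- cleavageProfile(gr3, cpg, "3p", window = 5)
  expect_equal(names(which.max(profileValues(prof3))), "-1")
})

test_that("uniform cutting yields a flat profile", {
  L <- 6000
  set.seed(63)
  start0 <- sample(0:(L - 150), 3000, replace = TRUE)
  gr <- asGRanges(data.frame(start0 = start0, end0 = start0 + 120,
                             strand = sample(c("+", "-"), 3000,
                                             replace = TRUE)))
  cpg <- data.frame(chrom = "chr1", pos = seq(300, 5500, by = 40))
  prof <- cleavageProfile(gr, cpg, "5p", window = 5, pooled = TRUE)
  v <- profileValues(prof)
  # all positions within sampling error of the overall mean
  expect_lt(max(abs(v - mean(v))), 0.5)
})

test_that("profiles are invariant under genome-wide reverse complementation", {
  L <- 3000
  set.seed(64)
  start0 <- sample(0:(L - 130), 1500, replace = TRUE)
  frags <- data.frame(start0 = start0, end0 = start0 + 100,
                      strand = sample(c("+", "-"), 1500, replace = TRUE))
  cpg <- data.frame(chrom = "chr1", pos = seq(200, 2700, by = 100))
  # mirrored data: flip coordinates, strands and CpG anchors
  fragsRC <- data.frame(start0 = L - frags$end0, end0 = L - frags$start0,
                        strand = ifelse(frags$strand == "+", "-", "+"))
  cpgRC <- data.frame(chrom = "chr1", pos = L - 2 - cpg$pos)
  for (et in c("5p", "3p")) {
    a <- profileValues(cleavageProfile(asGRanges(frags), cpg, et))
    b <- profileValues(cleavageProfile(asGRanges(fragsRC), cpgRC, et))
    expect_equal(a, b, info = et)
  }
})

test_that("FRAGMA features concatenate 4 categories x 11 positions", {
  L <- 5000
  g <- asGenome(randomGenomeStr(L, seed = 65))
  set.seed(66)
  start0 <- sample(0:(L - 150), 4000, replace = TRUE)
  gr <- asGRanges(data.frame(start0 = start0, end0 = start0 + 120,
                             strand = "+"))
  cpgTab <- data.frame(chrom = "chr1", pos = seq(200, 4500, by = 50))
  labels <- factor(rep(c("tissue_hyper", "tissue_hypo",
                         "hcc_specific_hyper", "hcc_specific_hypo"),
                       length.out = nrow(cpgTab)),
                   levels = cfEnds:::CPG_CLASSES)
  fv <- fragmaFeatures(gr, cpgTab, labels, endType = "3p")
  expect_length(fv, 44)
  fv2 <- fragmaFeatures(gr, cpgTab, labels, endType = "3p")
  expect_identical(fv, fv2)   # deterministic
  # a category with no sites is a hard error naming the category
  lab2 <- labels
  lab2[lab2 == "hcc_specific_hypo"] <- "tissue_hyper"
  expect_error(fragmaFeatures(gr, cpgTab, droplevels(lab2), "3p"),
               "hcc_specific_hypo")
})
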