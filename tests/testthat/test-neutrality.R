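test_that("Tajima's D is negative for star-like data and NA when S = 0", {
  # every variable site a singleton in a different sequence
  seqs <- c("GAAAA", "AGAAA", "AAGAA", "AAAGA", "AAAAG")
  hd <- haplotypeDataset(seqs, pop = rep("p", 5))
  expect_lt(tajimasD(hd), 0)
  hd0 <- haplotypeDataset(rep("AAAA", 5), pop = rep("p", 5))
  expect_true(is.na(tajimasD(hd0)))
  expect_true(is.na(tajimasD(haplotypeDataset(c("AA", "AT", "AA"),
                                              pop = rep("p", 3)))))
})

test_that("Fu's Fs follows the exact Ewens probabilities", {
  # n = 4, 2 haplotypes: compare with integer-Stirling computation
  hd <- haplotypeDataset(c("AAAA", "AAAA", "AATA", "AATA"),
                         pop = rep("p", 4))
  expect_equal(fusFs(hd), slowFuFs(alignmentMatrix(hd)),
               tolerance = 1e-10)
  # many singletons (expansion-like): strongly negative
  set.seed(31)
  seqs <- vapply(1:12, function(i) {
    s <- rep("A", 30); s[i] <- "G"; paste(s, collapse = "")
  }, "")
  hdE <- haplotypeDataset(seqs, pop = rep("p", 12))
  expect_lt(fusFs(hdE), -3)
})

test_that("R2 matches its hand-computed toy and ignores sequence order", {
  hd <- haplotypeDataset(c(s1 = "AAT", s2 = "AAA", s3 = "AAA"),
                         pop = rep("p", 3))
  expect_equal(rozasR2(hd), 0.4714045, tolerance = 1e-6)
  set.seed(41)
  hd2 <- randomAlignment(8, L = 30, S = 5)
  o <- sample(8)
  hd2p <- haplotypeDataset(as.character(hd2@alignment)[o],
                           pop = rep("p", 8))
  expect_equal(rozasR2(hd2), rozasR2(hd2p), tolerance = 1e-12)
})

test_that("neutral coalescent simulations centre Tajima's D near zero", {
  set.seed(51)
  vals <- replicate(2000, {
    cfg <- bathypop:::simNeutralConfig(20, 5)
    if (cfg$S > 0) bathypop:::tajimaDFromSk(20, cfg$S, cfg$pi) else NA
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.15)
})

test_that("coalescent p-values are seeded, sane and conventional", {
  set.seed(61)
  hd <- randomAlignment(15, L = 50, S = 8)
  expect_warning(neutralityPvalues(hd, reps = 500, seed = 9), "1000")
  r1 <- suppressWarnings(neutralityPvalues(hd, reps = 800, seed = 9))
  r2 <- suppressWarnings(neutralityPvalues(hd, reps = 800, seed = 9))
  expect_identical(r1, r2)
  for (p in c(r1$pD, r1$pFs, r1$pR2)) {
    expect_gte(p, 0); expect_lte(p, 1)
  }
  # the per-population table carries the same statistics
  tab <- suppressWarnings(neutralityTable(hd, reps = 500, seed = 3))
  expect_equal(tab$D[1], tajimasD(hd), tolerance = 1e-12)
})

test_that("bottleneck test flags a simulated crash and stays calibrated", {
  # equilibrium-like data straight from the equilibrium simulator: the
  # excess test should not fire systematically
  set.seed(71)
  # build a dataset from 6 equilibrium loci simulated at the gene level
  genes <- lapply(exp(seq(log(1), log(8), length.out = 6)), function(th) {
    d <- list(scenario = 1L, NATL = 500, NMED = 500, NbATL = 500,
              NbMED = 500, t = 1, t1 = 0.5, Nanc = 500,
              muMsatMean = th / 2000, muMsat = th / 2000, muMt = 1e-8)
    s <- simulateScenario(d, nATL = 30, nMED = 1, mtATL = 2, mtMED = 2,
                          seqLen = 10)
    alleleCalls(s$gen)[1:30, 1, ]
  })
  calls <- array(NA_integer_, c(30, 6, 2))
  for (l in 1:6) calls[, l, ] <- genes[[l]]
  gd <- genotypeDataset(calls, pop = rep("p", 30))
  bt <- bottleneckTest(gd, model = "SMM", iterations = 400, seed = 5)
  expect_gte(bt$pExcess, 0.01)
  expect_equal(nrow(bt$perLocus), 6)
  expect_true(all(bt$perLocus$HeqSd > 0))
  # a recent 100-fold crash (25 generations ago) leaves heterozygosity
  # excess relative to the allele-count equilibrium
  set.seed(4)
  crashed <- lapply(1:9, function(i) {
    d <- list(scenario = 4L, NATL = 50, NMED = 50, NbATL = 5000,
              NbMED = 5000, t = 1e6, t1 = 25, Nanc = 5000,
              muMsatMean = 5e-4, muMsat = 5e-4, muMt = 1e-8)
    s <- simulateScenario(d, nATL = 25, nMED = 1, mtATL = 2, mtMED = 2,
                          seqLen = 10)
    alleleCalls(s$gen)[1:25, 1, ]
  })
  calls2 <- array(NA_integer_, c(25, 9, 2))
  for (l in 1:9) calls2[, l, ] <- crashed[[l]]
  gd2 <- genotypeDataset(calls2, pop = rep("p", 25))
  bt2 <- bottleneckTest(gd2, model = "TPM", iterations = 400, seed = 104)
  expect_lt(bt2$pExcess, 0.1)
  expect_gt(mean(bt2$perLocus$stdDiff), 0)
})
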