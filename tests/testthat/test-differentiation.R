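fixedDiffGd <- function(n = 10) {
  # two populations fixed for different alleles at one locus
  calls <- array(c(rep(101L, n), rep(105L, n)), c(2 * n, 1, 2))
  calls[, 1, 2] <- calls[, 1, 1]
  genotypeDataset(calls, pop = rep(c("a", "b"), each = n))
}

test_that("Weir-Cockerham theta hits its limits and the hand oracle", {
  expect_equal(fstWeirCockerham(fixedDiffGd())$theta, 1)
  # one panmictic pool split into two labels: theta near zero, can be < 0
  set.seed(3)
  n <- 200
  a1 <- sample(101:104, n, TRUE); a2 <- sample(101:104, n, TRUE)
  gd <- genotypeDataset(array(c(a1, a2), c(n, 1, 2)),
                        pop = rep(c("x", "y"), each = n / 2))
  expect_lt(abs(fstWeirCockerham(gd)$theta), 0.03)
  # biallelic two-pop worked case against the literal variance components
  g1 <- list(rbind(c(101, 101)), rbind(c(101, 105)), rbind(c(101, 101)),
             rbind(c(101, 105)))
  g2 <- list(rbind(c(105, 105)), rbind(c(101, 105)), rbind(c(105, 105)),
             rbind(c(105, 105)))
  gd2 <- makeGd(list(a = g1, b = g2))
  p1 <- 6 / 8; p2 <- 1 / 8      # freq of allele 101
  h1 <- 2 / 4; h2 <- 1 / 4      # heterozygote fractions
  expect_equal(fstWeirCockerham(gd2)$theta,
               slowWcThetaBiallelic(p1, p2, h1, h2, 4, 4),
               tolerance = 1e-12)
})

test_that("Phi-ST reaches 1 for fixed differences and 0 for identity", {
  hd <- haplotypeDataset(c(rep("AAAA", 4), rep("GAAA", 4)),
                         pop = rep(c("a", "b"), each = 4))
  expect_equal(phiSt(hd)$phiST, 1)
  hd2 <- haplotypeDataset(rep(c("AAAA", "GAAA"), 4),
                          pop = rep(c("a", "b"), each = 4))
  expect_lte(phiSt(hd2)$phiST, 0.01)
  expect_error(phiSt(haplotypeDataset(c("AA", "AA", "AT"),
                                      pop = c("a", "a", "b"))),
               "single sequence")
})

test_that("Phi-ST equals the first-principles AMOVA oracle on toys", {
  set.seed(13)
  for (rep in 1:5) {
    hd <- randomAlignment(12, L = 30, S = 6,
                          pops = c("u1", "u2", "u3"))
    m <- alignmentMatrix(hd)
    d2 <- outer(seq_len(nrow(m)), seq_len(nrow(m)),
                Vectorize(function(i, j) sum(m[i, ] != m[j, ])))
    expect_equal(phiSt(hd)$phiST,
                 slowAmova2(d2, populations(hd))$phiST,
                 tolerance = 1e-10)
  }
})

test_that("Jost's D spans its limits and matches the hand formula", {
  # disjoint haplotype sets, equal sizes: Dest = 1 exactly
  expect_equal(jostDest(rbind(c(40, 0), c(0, 40))), 1)
  expect_equal(jostDest(rbind(c(12, 0), c(0, 4), c(0, 8))), 1)
  # identical frequency vectors: Dest = 0 up to the small-sample
  # correction (the unbiased estimator is slightly negative at finite n
  # and is reported as computed)
  expect_equal(jostDest(rbind(c(1000, 1000), c(1000, 1000))), 0,
               tolerance = 5e-3)
  expect_lte(jostDest(rbind(c(10, 10), c(10, 10))), 0)
  # two-unit two-allele case against the explicit Nei-Chesser evaluation
  cnt <- rbind(c(12, 4), c(8, 16))
  nj <- colSums(cnt); k <- 2
  p <- sweep(cnt, 2, nj, "/")
  ntilde <- k / sum(1 / nj)
  Hs <- (ntilde / (ntilde - 1)) * (1 - mean(colSums(p^2)))
  Ht <- (1 - sum(rowMeans(p)^2)) + Hs / (ntilde * k)
  expect_equal(jostDest(cnt), (k / (k - 1)) * (Ht - Hs) / (1 - Hs),
               tolerance = 1e-12)
  # dataset wrapper: per-locus and multilocus
  gd <- fixedDiffGd()
  expect_equal(jostDestData(gd)$Dest, 1, tolerance = 1e-9)
})

test_that("G-test matches the closed form and vanishes on identity", {
  gd <- makeGd(list(a = list(rbind(c(101, 101)), rbind(c(105, 105))),
                    b = list(rbind(c(101, 101)), rbind(c(105, 105)))))
  res <- gTestAllelic(gd, c("a", "b"), nPerm = 99, seed = 1)
  expect_equal(res$perLocus$G, 0)
  expect_equal(res$perLocus$p, 1)
  # 2x2 table (10,0 / 0,10): G = 2 * 20 * ln 2
  gd2 <- fixedDiffGd(5)
  res2 <- gTestAllelic(gd2, c("a", "b"), nPerm = 99, seed = 1)
  expect_equal(res2$sumG, 40 * log(2), tolerance = 1e-9)
  expect_lt(res2$sumGP, 0.05)
})

test_that("BH-FDR stars follow the step-up procedure and are monotone", {
  fam <- bathypop:::fdrStars(c(0.01, 0.02, 0.5), c(0.05, 0.01, 0.001))
  expect_equal(fam$stars, c("*", "*", ""))
  expect_equal(fam$padj, p.adjust(c(0.01, 0.02, 0.5), "BH"))
  # monotone: significant at alpha stays significant at alpha' > alpha
  set.seed(2)
  p <- runif(30)^2
  for (a in c(0.001, 0.01, 0.05)) {
    sig1 <- p.adjust(p, "BH") < a
    sig2 <- p.adjust(p, "BH") < 0.05
    expect_true(all(!sig1 | sig2))
  }
})

test_that("pairwise matrices flag the generator's basin structure", {
  sim <- generateStudyLikeDataset()
  expect_warning(pairwiseStats(fixedDiffGd(), "fst", nPerm = 50),
                 "100 permutations")
  pm <- pairwiseStats(sim$gen, "fst", nPerm = 200, seed = 91)
  p <- pValues(pm)
  big <- c("MAR1", "MAR3", "ROC")   # localities with decent sample sizes
  for (a in big) for (m in c("MED1", "MED2"))
    expect_lt(p[a, m], 0.05)
  within <- rbind(t(combn(c("MAR1", "MAR2", "MAR3", "ROC"), 2)),
                  c("MED1", "MED2"))
  expect_false(any(p[within] < 0.01))
  # mtDNA Dest between basins is 1 with disjoint haplotype sets
  basins <- poolPops(sim$seqs, basinGrouping(sim$seqs))
  expect_equal(jostDestData(basins)$Dest, 1)
})
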