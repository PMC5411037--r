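test_that("heterozygosity matches hand-computed unbiased values", {
  # monomorphic locus
  gd <- makeGd(list(p = list(rbind(c(101, 101)), rbind(c(101, 101)))))
  h <- heterozygosity(gd)
  expect_equal(h$HO, 0)
  expect_equal(h$HE, 0)
  # two individuals, both heterozygous A/B: HE = (4/3)(1 - 0.5)
  gd2 <- makeGd(list(p = list(rbind(c(101, 105)), rbind(c(101, 105)))))
  h2 <- heterozygosity(gd2)
  expect_equal(h2$HO, 1)
  expect_equal(h2$HE, 2 / 3, tolerance = 1e-12)
  # an unscored cell is absent, not zero
  gd3 <- makeGd(list(a = list(rbind(c(101, 102))),
                     b = list(rbind(c(NA, NA)))))
  h3 <- heterozygosity(gd3)
  expect_true(is.na(h3$HE[h3$pop == "b"]))
})

test_that("HE approaches 1 - sum(p^2) in a large HWE sample", {
  set.seed(7)
  p <- c(0.5, 0.3, 0.2)
  n <- 4000
  a1 <- sample(101:103, n, TRUE, p); a2 <- sample(101:103, n, TRUE, p)
  calls <- array(c(a1, a2), c(n, 1, 2))
  gd <- genotypeDataset(calls, pop = rep("p", n))
  expect_equal(heterozygosity(gd)$HE, 1 - sum(p^2), tolerance = 0.01)
  expect_equal(unname(totalGeneDiversity(gd)), 1 - sum(p^2),
               tolerance = 0.01)
})

test_that("rarefied allelic richness follows the combinatorial formula", {
  # allele counts (9, 1), g = 2: Rs = 1 + (1 - C(9,2)/C(10,2)) = 1.2
  al <- c(rep(101L, 9), 105L)
  calls <- array(c(al[seq(1, 9, 2)], al[seq(2, 10, 2)]), c(5, 1, 2))
  gd <- genotypeDataset(calls, pop = rep("A", 5))
  expect_equal(allelicRichness(gd, g = 2)$perCell$Rs, 1.2)
  # g = N reproduces the observed allele count
  expect_equal(allelicRichness(gd, g = 10)$perCell$Rs, 2)
  # monomorphic cell gives 1 for any g; Rs is non-decreasing in g
  gdm <- makeGd(list(p = list(rbind(c(101, 101)), rbind(c(101, 101)),
                              rbind(c(101, 105)))))
  rs <- vapply(2:6, function(g) allelicRichness(gdm, g)$perCell$Rs, 0)
  expect_true(all(diff(rs) >= -1e-12))
  expect_gte(rs[1], 1); expect_lte(rs[1], 2)
  expect_error(allelicRichness(gd, g = 11), "exceeds")
})

test_that("FIS recovers Hardy-Weinberg and fully inbred extremes", {
  set.seed(11)
  n <- 500
  a1 <- sample(c(101L, 105L), n, TRUE); a2 <- sample(c(101L, 105L), n, TRUE)
  gd <- genotypeDataset(array(c(a1, a2), c(n, 1, 2)), pop = rep("p", n))
  expect_lt(abs(inbreedingFis(gd)$multilocus), 0.02)
  # all homozygous at p = q = 0.5
  hom <- rep(c(101L, 105L), each = 10)
  gd2 <- genotypeDataset(array(c(hom, hom), c(20, 1, 2)),
                         pop = rep("p", 20))
  expect_equal(unname(inbreedingFis(gd2)$multilocus), 1)
})

test_that("FIS agrees with a direct variance-component evaluation", {
  # small worked case: genotypes 101/101, 101/105, 105/105, 101/105, 101/101
  g <- rbind(c(101, 101), c(101, 105), c(105, 105), c(101, 105),
             c(101, 101))
  gd <- genotypeDataset(array(c(g[, 1], g[, 2]), c(5, 1, 2)),
                        pop = rep("p", 5))
  n <- 5
  # direct W&C sums for each allele
  bc <- c(0, 0)
  for (p in c(6 / 10, 4 / 10)) {
    h <- 2 / 5
    b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    bc <- bc + c(b, h / 2)
  }
  expect_equal(unname(inbreedingFis(gd)$multilocus), 1 - bc[2] / sum(bc),
               tolerance = 1e-12)
})

test_that("HWE exact test matches the full pairing enumeration", {
  # monomorphic cell: p = 1 by convention
  gdm <- makeGd(list(p = list(rbind(c(101, 101)), rbind(c(101, 101)))))
  resm <- hweExactTest(gdm)
  expect_equal(resm$p, 1)
  expect_equal(resm$method, "monomorphic")
  # two-allele case: package enumeration vs exhaustive pairing oracle
  cases <- list(list(a1 = c(101, 101, 105), a2 = c(101, 105, 105)),
                list(a1 = c(101, 101, 101, 105), a2 = c(101, 105, 105, 105)),
                list(a1 = c(101, 105, 105), a2 = c(101, 101, 105)))
  for (cs in cases) {
    pkg <- bathypop:::hweCell(cs$a1, cs$a2, 0)
    expect_equal(pkg$method, "enumeration")
    expect_equal(pkg$p, slowHweExact(cs$a1, cs$a2), tolerance = 1e-10)
  }
  # three-allele Monte Carlo within 3 SE of the exhaustive enumeration
  a1 <- c(101, 101, 102, 103); a2 <- c(101, 102, 103, 103)
  exact <- slowHweExact(a1, a2)
  set.seed(5)
  mc <- bathypop:::hweCell(a1, a2, 4000)
  expect_equal(mc$method, "montecarlo")
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p - exact), 3 * se + 1e-4)
})

test_that("haplotype diversity reproduces worked values and properties", {
  expect_equal(round(haplotypeDiversity(c(6, 3, 1)), 3), 0.600)
  expect_equal(round(haplotypeDiversity(c(46, 2, 1)), 3), 0.119)
  expect_equal(haplotypeDiversity(c(30)), 0)
  # permutation invariance
  expect_equal(haplotypeDiversity(c(1, 3, 6)), haplotypeDiversity(c(6, 3, 1)))
  # adding a singleton to a monomorphic sample strictly increases Hd
  expect_gt(haplotypeDiversity(c(10, 1)), haplotypeDiversity(c(10)))
  expect_error(haplotypeDiversity(c(3, 2), n = 6), "sum")
  expect_true(is.na(haplotypeDiversity(c(1))))
})

test_that("nucleotide diversity equals the brute-force pair loop", {
  # identical sequences
  hd0 <- haplotypeDataset(rep("ACGTACGT", 3), pop = rep("p", 3))
  expect_equal(nucleotideDiversity(hd0), 0)
  # two sequences, one difference over 613 sites
  s <- paste(rep("A", 613), collapse = "")
  s2 <- paste0("G", substr(s, 2, 613))
  hd1 <- haplotypeDataset(c(s, s2), pop = c("p", "p"))
  expect_equal(nucleotideDiversity(hd1), 1 / 613, tolerance = 1e-12)
  # random toys, including ambiguity codes, against the quadratic oracle
  set.seed(21)
  for (rep in 1:10) {
    hd <- randomAlignment(sample(4:10, 1), L = 30, S = sample(2:6, 1))
    m <- alignmentMatrix(hd)
    m[sample(length(m), 3)] <- "N"
    hdN <- haplotypeDataset(apply(m, 1, paste, collapse = ""),
                            pop = populations(hd))
    expect_equal(nucleotideDiversity(hdN), slowPi(alignmentMatrix(hdN)),
                 tolerance = 1e-12)
  }
  # pi equals mean pairwise differences / L without ambiguity
  hd2 <- randomAlignment(8, L = 25, S = 4)
  expect_equal(nucleotideDiversity(hd2),
               meanPairwiseDiff(hd2) / 25, tolerance = 1e-12)
})

test_that("segregating sites are counted and classified correctly", {
  hd0 <- haplotypeDataset(rep("ACGT", 2), pop = rep("p", 2))
  expect_equal(segregatingSites(hd0)$S, 0)
  hd1 <- haplotypeDataset(c("AAAA", "AGAA"), pop = rep("p", 2))
  ss <- segregatingSites(hd1)
  expect_equal(ss$S, 1)
  expect_equal(ss$transitions, 1)
  expect_equal(ss$transversions, 0)
  # triallelic site counts in S but not in ts/tv
  hd2 <- haplotypeDataset(c("AAAA", "AGAA", "ATAA"), pop = rep("p", 3))
  expect_warning(ss2 <- segregatingSites(hd2), ">2 states")
  expect_equal(ss2$S, 1)
  expect_equal(ss2$transitions + ss2$transversions, 0)
})
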