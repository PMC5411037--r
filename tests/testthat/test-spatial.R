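test_that("Mantel regression recovers an exact linear relationship", {
  set.seed(5)
  geo <- as.matrix(dist(cbind(runif(6) * 1000, runif(6) * 1000)))
  gen <- 0.001 * geo
  res <- mantelIbd(gen, geo, nPerm = 999, seed = 2)
  expect_equal(res$b, 0.001, tolerance = 1e-10)
  expect_equal(res$a, 0, tolerance = 1e-10)
  expect_lte(res$p, 0.05)
  # constant genetic matrix: slope 0, p = 1
  resc <- mantelIbd(matrix(0.1, 6, 6), geo, nPerm = 99)
  expect_equal(resc$b, 0)
  expect_equal(resc$p, 1)
  # linearized transform applies g/(1-g) before the regression
  gen2 <- 1e-5 * geo
  resl <- mantelIbd(gen2, geo, nPerm = 99, transform = "linearized",
                    seed = 2)
  lt <- lower.tri(gen2)
  ref <- lm((gen2[lt] / (1 - gen2[lt])) ~ geo[lt])
  expect_equal(resl$b, unname(coef(ref)[2]), tolerance = 1e-10)
})

test_that("Mantel permutation p matches exhaustive enumeration on 4 units", {
  set.seed(9)
  geo <- as.matrix(dist(runif(4) * 100))
  gen <- matrix(runif(16), 4, 4); gen <- (gen + t(gen)) / 2
  diag(gen) <- 0
  lt <- lower.tri(gen)
  rObs <- cor(gen[lt], geo[lt])
  allPerms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  allPerms <- allPerms[apply(allPerms, 1, function(x)
    length(unique(x)) == 4), ]
  rAll <- apply(allPerms, 1, function(o) cor(gen[o, o][lt], geo[lt]))
  pExact <- mean(rAll >= rObs - 1e-12)
  res <- mantelIbd(gen, geo, nPerm = 4000, seed = 33)
  expect_lt(abs(res$p - pExact), 0.03)
})

test_that("Mantel correlation agrees with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(12)
  geo <- as.matrix(dist(runif(6) * 50))
  gen <- as.matrix(dist(runif(6)))
  res <- mantelIbd(gen, geo, nPerm = 999, seed = 3)
  veg <- vegan::mantel(as.dist(gen), as.dist(geo), permutations = 999)
  expect_equal(res$r, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(abs(res$p - veg$signif), 0.12)
})

test_that("frequency PCA separates designed basins and sums inertia to 1", {
  sim <- generateStudyLikeDataset()
  pc <- frequencyPca(sim$seqs, nRand = 200, seed = 6)
  expect_equal(sum(pc$inertia), 1, tolerance = 1e-9)
  basin <- c(MAR1 = "ATL", MAR2 = "ATL", MAR3 = "ATL", ROC = "ATL",
             MED1 = "MED", MED2 = "MED")
  pc1 <- pc$scores[, 1]
  atl <- pc1[basin[rownames(pc$scores)] == "ATL"]
  med <- pc1[basin[rownames(pc$scores)] == "MED"]
  expect_true(max(atl) < min(med) || min(atl) > max(med))
  expect_lt(pc$axisP[1], 0.05)
  expect_error(frequencyPca(subsetPops(sim$seqs, c("MED1", "MED2"))),
               "three units")
})

test_that("between-group p-distance matches direct computation", {
  # two sequences differing at 1 of 598 sites: 0.167%
  s <- paste(rep("A", 598), collapse = "")
  s2 <- paste0("G", substr(s, 2, 598))
  hd <- haplotypeDataset(c(s, s2), pop = c("a", "b"))
  g <- sampleGrouping(c("a", "b"), c("g1", "g2"))
  res <- groupPDistance(hd, g, nBoot = 200, seed = 1)
  expect_equal(res$pDistance, 1 / 598, tolerance = 1e-12)
  # SE = 0 when both groups are fixed and monomorphic
  hd2 <- haplotypeDataset(c(s, s, s2, s2), pop = c("a", "a", "b", "b"))
  res2 <- groupPDistance(hd2, g, nBoot = 100, seed = 1)
  expect_gt(res2$se, 0)  # bootstrap over sites still varies the estimate
  hd3 <- haplotypeDataset(c(s, s, s, s), pop = c("a", "a", "b", "b"))
  res3 <- groupPDistance(hd3, g, nBoot = 100, seed = 1)
  expect_equal(res3$se, 0)
})
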