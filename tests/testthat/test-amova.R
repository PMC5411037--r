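test_that("AMOVA indices vanish for populations drawn from one pool", {
  set.seed(17)
  hd <- randomAlignment(36, L = 40, S = 8,
                        pops = rep(c("p1", "p2", "p3", "p4"), 9))
  g <- sampleGrouping(c("p1", "p2", "p3", "p4"),
                      c("g1", "g1", "g2", "g2"))
  res <- amova(hd, g, nPerm = 200, seed = 4)
  phi <- fixationIndices(res)
  expect_lt(abs(phi[["FST"]]), 0.1)
  expect_lt(abs(phi[["FCT"]]), 0.15)
  expect_gt(pValues(res)[["FST"]], 0.05)
  # components sum to the total variance used in the indices
  s2 <- varianceComponents(res)
  expect_equal(phi[["FCT"]], s2[[1]] / sum(s2), tolerance = 1e-12)
  expect_equal(phi[["FST"]], (s2[[1]] + s2[[2]]) / sum(s2),
               tolerance = 1e-12)
})

test_that("two-population AMOVA reproduces Phi-ST exactly", {
  set.seed(23)
  hd <- randomAlignment(16, L = 30, S = 6, pops = c("a", "b"))
  g <- sampleGrouping(c("a", "b"), c("a", "b"))
  res <- amova(hd, g, nPerm = 0)
  expect_equal(fixationIndices(res)[["FST"]], phiSt(hd)$phiST,
               tolerance = 1e-12)
})

test_that("grouping search ranks the true split of identical clusters first", {
  # two internally-identical clusters of populations
  seqs <- c(rep("AAAAAA", 6), rep("GGGAAA", 6))
  pops <- c(rep(c("p1", "p2"), each = 3), rep(c("p3", "p4"), each = 3))
  hd <- haplotypeDataset(seqs, pop = pops)
  locs <- c("p1", "p2", "p3", "p4")
  # enumerate all balanced 2+2 groupings
  cands <- list(
    true = sampleGrouping(locs, c("A", "A", "B", "B")),
    alt1 = sampleGrouping(locs, c("A", "B", "A", "B")),
    alt2 = sampleGrouping(locs, c("A", "B", "B", "A")))
  gs <- groupingSearch(hd, cands)
  expect_equal(gs$ranking$candidate[1], "true")
  expect_equal(max(gs$ranking$FCT), gs$ranking$FCT[1])
})

test_that("nuclear AMOVA matches the sequence path on haploid-coded data", {
  # encode each "sequence" as a homozygous one-locus genotype so the
  # allele non-identity AMOVA must agree with the 0/1 sequence distance
  seqs <- c("A", "A", "G", "G", "G", "T", "T", "A")
  pops <- c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3")
  codes <- c(A = 101L, G = 102L, T = 103L)
  calls <- array(rep(codes[seqs], 2), c(8, 1, 2))
  gd <- genotypeDataset(calls, pop = pops)
  hd <- haplotypeDataset(seqs, pop = pops)
  g <- sampleGrouping(c("p1", "p2", "p3"), c("x", "x", "y"))
  ag <- amova(gd, g, nPerm = 0)
  # each individual contributes two identical gene copies; the genotype
  # AMOVA at the gene level doubles every count, so indices agree with a
  # sequence AMOVA run on the doubled alignment
  hd2 <- haplotypeDataset(rep(seqs, each = 2), pop = rep(pops, each = 2))
  as <- amova(hd2, g, nPerm = 0)
  expect_equal(fixationIndices(ag), fixationIndices(as),
               tolerance = 1e-10)
})

test_that("grouping search on the study mimic recovers the published splits", {
  sim <- generateStudyLikeDataset()
  locs <- popNames(sim$seqs)
  cands <- list(
    northSouth = sampleGrouping(locs, c("N", "S", "S", "N", "M", "M")),
    basins = sampleGrouping(locs, c("A", "A", "A", "A", "M", "M")),
    wrong1 = sampleGrouping(locs, c("A", "A", "B", "B", "M", "M")),
    wrong2 = sampleGrouping(locs, c("N", "M", "N", "N", "M", "M")))
  gsMt <- groupingSearch(sim$seqs, cands)
  expect_equal(gsMt$ranking$candidate[1], "northSouth")
  gsNuc <- groupingSearch(sim$gen, cands)
  expect_equal(gsNuc$ranking$candidate[1], "basins")
})
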