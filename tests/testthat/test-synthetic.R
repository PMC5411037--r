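sim <- generateStudyLikeDataset()

test_that("the default mimic reproduces the study's sampling layout", {
  expect_equal(nInd(sim$gen), 375)
  expect_equal(nLoci(sim$gen), 9)
  expect_equal(nlevels(populations(sim$gen)), 6)
  expect_equal(nSeq(sim$seqs), 193)
  expect_equal(seqLength(sim$seqs), 613)
  # locus polymorphism spans the wide published range
  A <- vapply(seq_len(9), function(l)
    length(unique(na.omit(as.vector(alleleCalls(sim$gen)[, l, ])))), 0)
  expect_lte(min(A), 3)
  expect_gte(max(A), 12)
})

test_that("the mimic's files survive the io round-trip", {
  dir <- tempfile("synth")
  paths <- writeStudyLikeDataset(sim, dir)
  gd <- readGenepop(paths[["genepop"]])
  expect_equal(nInd(gd), 375)
  expect_equal(nLoci(gd), 9)
  expect_equal(nlevels(populations(gd)), 6)
  hd <- readFastaAlignment(paths[["fasta"]], popPattern = "^([A-Z0-9]+)_")
  expect_equal(nSeq(hd), 193)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_true(!is.null(truth$nuclear$realizedFst))
  unlink(dir, recursive = TRUE)
})

test_that("basins share no haplotypes and sit one mutation step apart", {
  basins <- poolPops(sim$seqs, basinGrouping(sim$seqs))
  cc <- collapseHaplotypes(basins)
  expect_equal(sum(cc$counts[, "ATL"] > 0 & cc$counts[, "MED"] > 0), 0)
  net <- medianJoiningNetwork(sim$seqs)
  e <- networkEdges(net)
  atl <- rownames(net@popFreq)[rowSums(net@popFreq[, c("MED1", "MED2")]) == 0 &
                               net@nodes$freq[seq_len(nrow(net@popFreq))] > 0]
  med <- setdiff(rownames(net@popFreq), atl)
  cross <- e[(e$from %in% atl & e$to %in% med) |
             (e$from %in% med & e$to %in% atl), ]
  expect_equal(min(cross$steps), 1)
})

test_that("the truth record matches what the pipeline recovers", {
  expect_lt(abs(sim$truth$nuclear$realizedFst - 0.02) / 0.02, 0.3)
  # per-locality haplotype diversities follow the designed tables
  dt <- diversityTable(seqs = sim$seqs)
  expect_equal(dt$Hd[dt$pop == "MAR1"], 0.000)
  expect_equal(dt$Hd[dt$pop == "MAR2"], 0.600)
  expect_equal(dt$Hd[dt$pop == "ROC"], 0.119)
  expect_equal(dt$Hd[dt$pop == "MED2"], 0.307)
  # dominant-haplotype fractions as recorded
  expect_equal(sim$truth$dominantMed, 49 / 66, tolerance = 1e-9)
})

test_that("the homogeneous-Atlantic variant removes the mtDNA split", {
  cfg <- studyMimicConfig(substructureAtlantic = FALSE, seed = 77)
  sim2 <- generateStudyLikeDataset(cfg)
  atl <- subsetPops(sim2$seqs, c("MAR1", "MAR2", "MAR3", "ROC"))
  ph <- phiSt(atl, nPerm = 100, seed = 1)
  expect_lt(ph$phiST, 0.05)
  expect_gt(ph$p, 0.05)
})
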