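test_that("a mutational chain yields a path with no median vectors", {
  hd <- haplotypeDataset(c(a = "AAAA", b = "AAAT", c = "AATT",
                           a2 = "AAAA"), pop = rep("p", 4))
  net <- medianJoiningNetwork(hd)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2)
  expect_equal(sum(e$steps), 2)
  expect_equal(sum(net@nodes$type == "median"), 0)
  # frequencies conserved: observed nodes sum to the sample size
  expect_equal(sum(net@nodes$freq), 4)
})

test_that("a four-haplotype rectangle resolves to the 4-cycle", {
  hd <- haplotypeDataset(c("AAAA", "AAAT", "AATA", "AATT"),
                         pop = rep("p", 4))
  net <- medianJoiningNetwork(hd, epsilon = 0)
  e <- networkEdges(net)
  expect_equal(nrow(e), 4)
  expect_true(all(e$steps == 1))
  expect_equal(sum(net@nodes$type == "median"), 0)
})

test_that("a star phylogeny with missing centre infers one median vector", {
  # three haplotypes one step from an unsampled central sequence
  hd <- haplotypeDataset(c("GAAA", "AGAA", "AAGA"), pop = rep("p", 3))
  net <- medianJoiningNetwork(hd)
  expect_equal(sum(net@nodes$type == "median"), 1)
  expect_equal(sum(networkEdges(net)$steps), 3)
})

test_that("with epsilon 0 and tree-like data the network is the MST", {
  skip_if_not_installed("ape")
  set.seed(81)
  for (rep in 1:5) {
    hd <- randomAlignment(8, L = 40, S = 10)
    cc <- collapseHaplotypes(hd)
    if (length(cc$sequences) < 3) next
    net <- medianJoiningNetwork(hd)
    m <- do.call(rbind, strsplit(cc$sequences, ""))
    d <- as.matrix(dist(apply(m, 2, function(col)
      as.integer(factor(col))), method = "manhattan"))
    # network length never exceeds the MST length
    mstAdj <- ape::mst(as.dist(d))
    mstLen <- sum(d[which(mstAdj == 1)]) / 2
    obsLen <- sum(networkEdges(net)$steps)
    medians <- sum(net@nodes$type == "median")
    if (medians == 0) expect_lte(obsLen, mstLen + 1e-9)
    # every observed haplotype is a node
    expect_true(all(names(cc$sequences) %in% net@nodes$id))
  }
})

test_that("the designed haplogroups connect through one transition step", {
  hd <- readFastaAlignment(fixtureFasta(),
                           popPattern = "^[^|]+\\|([A-Z]+)")
  net <- medianJoiningNetwork(hd)
  e <- networkEdges(net)
  # map network ids back to haplogroups via node frequencies per pop
  grp <- colnames(net@popFreq)
  atl <- rownames(net@popFreq)[net@popFreq[, "ATL"] > 0]
  med <- rownames(net@popFreq)[net@popFreq[, "MED"] > 0]
  cross <- e[(e$from %in% atl & e$to %in% med) |
             (e$from %in% med & e$to %in% atl), ]
  expect_equal(min(cross$steps), 1)
  expect_match(cross$positions[cross$steps == 1], "^91$")
  # rejects ambiguity codes at variable sites
  m <- alignmentMatrix(hd)
  m[1, 91] <- "N"
  hdN <- haplotypeDataset(apply(m, 1, paste, collapse = ""),
                          pop = populations(hd))
  expect_error(medianJoiningNetwork(hdN), "non-nucleotide")
})
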