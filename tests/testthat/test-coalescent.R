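test_that("prior draws respect bounds, ordering and seeding", {
  spec <- scenarioSpec(4)
  set.seed(101)
  draws <- replicate(2000, drawPriorParameters(spec), simplify = FALSE)
  for (nm in c("NATL", "NMED", "NbATL", "NbMED", "t", "t1", "Nanc")) {
    v <- vapply(draws, `[[`, 0, nm)
    b <- spec@priors[[nm]]
    expect_true(all(v >= b[1] & v <= b[2]))
  }
  expect_true(all(vapply(draws, function(d) d$t1 < d$t, TRUE)))
  # scenario flags: no size change means Nb == N
  d1 <- drawPriorParameters(scenarioSpec(1), seed = 3)
  expect_equal(d1$NbATL, d1$NATL)
  expect_equal(d1$NbMED, d1$NMED)
  d2 <- drawPriorParameters(scenarioSpec(2), seed = 3)
  expect_equal(d2$NbATL, d2$NATL)
  expect_false(d2$NbMED == d2$NMED)
  expect_identical(drawPriorParameters(spec, seed = 11),
                   drawPriorParameters(spec, seed = 11))
  # marginal of t is uniform on its prior (KS)
  tv <- vapply(draws, `[[`, 0, "t")
  expect_gt(ks.test(tv, "punif", 1, 7e4)$p.value, 0.001)
})

test_that("TMRCA of two copies matches coalescent theory within 5 percent", {
  est <- meanTmrca(2, copies = 2000, reps = 5000, seed = 5)
  expect_lt(abs(est - 2000) / 2000, 0.05)
})

test_that("allele-size variance between isolated demes grows like 2 mu t", {
  # huge demes (no within-deme coalescence), instant ancestral merge:
  # the difference between one gene from each deme accumulates
  # Poisson(mu t) +/-1 steps on each side, so Var(diff) = 2 mu t
  mu <- 0.01; t <- 1000
  d <- list(NATL = 1e9, NMED = 1e9, NbATL = 1e9, NbMED = 1e9,
            t = t, t1 = t / 2, Nanc = 0.5, muMsatMean = mu,
            muMsat = mu, muMt = 1e-9, scenario = 1L)
  set.seed(15)
  diffs <- replicate(3000, {
    s <- bathypop:::.cppSimulateScenario(d$NATL, d$NMED, d$NbATL,
      d$NbMED, d$t, d$t1, d$Nanc, d$muMsat, d$muMt, 1L, 1L, 1L, 1L,
      5L, 2, 0L, 0.8, 0.2, TRUE)
    s$msat[1, 1] - s$msat[2, 1]
  })
  expect_lt(abs(var(diffs) - 2 * mu * t) / (2 * mu * t), 0.12)
})

test_that("deep splits with tiny post-split sizes are reciprocally monophyletic", {
  d <- list(NATL = 1e4, NMED = 1e4, NbATL = 50, NbMED = 50,
            t = 6e4, t1 = 100, Nanc = 1e4, muMsatMean = 1e-4,
            muMsat = rep(1e-4, 2), muMt = 5e-8, scenario = 4L)
  set.seed(25)
  shared <- replicate(60, {
    s <- simulateScenario(d, nATL = 5, nMED = 5, mtATL = 12, mtMED = 12,
                          seqLen = 613)
    s$stats[["SHARED"]]
  })
  expect_gt(mean(shared == 0), 0.95)
})

test_that("summary statistics agree between the fast path and the R path", {
  set.seed(35)
  d <- drawPriorParameters(scenarioSpec(4))
  s <- simulateScenario(d, nATL = 25, nMED = 30, mtATL = 20, mtMED = 22)
  rSide <- summaryStatistics(s$gen, s$seqs)
  expect_equal(unname(rSide), unname(s$stats), tolerance = 1e-8)
  # exchangeability: permuting individuals within populations changes
  # nothing
  o <- c(sample(25), 25 + sample(30))
  gen2 <- genotypeDataset(alleleCalls(s$gen)[o, , , drop = FALSE],
                          pop = as.character(populations(s$gen))[o],
                          loci = lociNames(s$gen))
  expect_equal(summaryStatistics(gen2, s$seqs), rSide,
               tolerance = 1e-10)
})

test_that("scenario 1 is nested in scenario 4 when sizes do not change", {
  set.seed(45)
  statUnder <- function(forceNb) {
    replicate(250, {
      d <- drawPriorParameters(scenarioSpec(if (forceNb) 4 else 1))
      if (forceNb) { d$NbATL <- d$NATL; d$NbMED <- d$NMED }
      bathypop:::.cppSimulateScenario(d$NATL, d$NMED, d$NbATL, d$NbMED,
        d$t, d$t1, d$Nanc, d$muMsat, d$muMt, 15L, 15L, 12L, 12L, 200L,
        2, 0L, 0.8, 0.2, FALSE)$stats[3]
    })
  }
  he1 <- statUnder(FALSE)
  he4 <- statUnder(TRUE)
  expect_gt(suppressWarnings(ks.test(he1, he4))$p.value, 0.01)
})
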