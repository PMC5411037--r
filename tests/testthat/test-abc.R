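# A small shared reference table for the ABC unit tests (the acceptance
# suite builds its own at larger scale).
smallRef <- local({
  ref <- NULL
  function() {
    if (is.null(ref))
      ref <<- buildReferenceTable(lapply(1:4, scenarioSpec),
                                  nPerScenario = 1500, seed = 1234)
    ref
  }
})

test_that("scenario probabilities are proper and favour the generating model", {
  ref <- smallRef()
  spec4s <- scenarioSpec(4, priors = list(
    NATL = c(5e5, 2e6), NMED = c(1e5, 5e5), NbATL = c(1, 5e3),
    NbMED = c(1, 5e3), t = c(5e3, 7e4), t1 = c(1, 2e4)))
  set.seed(7)
  pod <- simulateScenario(drawPriorParameters(spec4s))
  mc <- abcModelChoice(ref, pod$stats, retainedFraction = 0.02,
                       nBoot = 20)
  expect_equal(sum(mc$probabilities), 1, tolerance = 1e-6)
  expect_true(all(mc$probabilities >= 0))
  expect_equal(which.max(mc$probabilities), 4L, ignore_attr = TRUE)
  expect_equal(dim(mc$ci), c(2L, 4L))
  expect_true(all(mc$ci[1, ] <= mc$ci[2, ] + 1e-9))
})

test_that("indistinguishable scenarios get equal posterior weight", {
  ref <- smallRef()
  rows <- which(ref@scenario == 1)
  set.seed(9)
  fake <- new("ReferenceTable",
              scenario = sample(rep(1:2, length.out = length(rows))),
              params = ref@params[rows, ], stats = ref@stats[rows, ],
              specs = list(scenarioSpec(1), scenarioSpec(2)),
              design = ref@design)
  pod <- simulateScenario(drawPriorParameters(scenarioSpec(1), seed = 2))
  mc <- abcModelChoice(fake, pod$stats, retainedFraction = 0.2)
  expect_lt(abs(mc$probabilities[1] - 0.5), 0.2)
})

test_that("adjusted posterior draws always stay inside the prior support", {
  ref <- smallRef()
  pod <- simulateScenario(drawPriorParameters(scenarioSpec(4), seed = 4))
  post <- abcParameterPosterior(ref, pod$stats, scenario = 4,
                                nRetain = 400)
  spec <- scenarioSpec(4)
  for (pm in colnames(post@draws)) {
    b <- spec@priors[[pm]]
    expect_true(all(post@draws[, pm] > b[1] & post@draws[, pm] < b[2]))
  }
  s <- post@summary
  expect_true(all(s$q025 <= s$median & s$median <= s$q975))
  expect_true(all(s$mode > vapply(rownames(s),
    function(pm) spec@priors[[pm]][1], 0)))
})

test_that("uninformative statistics return the prior as posterior", {
  # reference table whose statistics are pure noise: rejection sampling
  # cannot update the uniform prior on t
  set.seed(19)
  n <- 4000
  spec <- scenarioSpec(1)
  params <- matrix(runif(n * 9), n, 9,
                   dimnames = list(NULL, c("NATL", "NMED", "NbATL",
                     "NbMED", "t", "t1", "Nanc", "muMsatMean", "muMt")))
  params[, "t"] <- runif(n, 1, 7e4)
  stats <- matrix(rnorm(n * 18), n, 18,
                  dimnames = list(NULL, summaryStatNames()))
  fake <- new("ReferenceTable", scenario = rep(1L, n), params = params,
              stats = stats, specs = list(spec), design = list())
  obs <- setNames(rnorm(18), summaryStatNames())
  post <- abcParameterPosterior(fake, obs, scenario = 1, nRetain = 2000,
                                parameters = "t", method = "rejection")
  expect_gt(ks.test(post@draws[, "t"], "punif", 1, 7e4)$p.value, 0.01)
})

test_that("rejection and regression posteriors agree on high-signal pods", {
  ref <- smallRef()
  pod <- simulateScenario(drawPriorParameters(scenarioSpec(4), seed = 21))
  pr <- abcParameterPosterior(ref, pod$stats, scenario = 4,
                              nRetain = 150, parameters = "t",
                              method = "rejection")
  pl <- abcParameterPosterior(ref, pod$stats, scenario = 4,
                              nRetain = 150, parameters = "t",
                              method = "loclinear")
  span <- diff(range(pr@draws[, "t"]))
  expect_lt(abs(pr@summary["t", "median"] - pl@summary["t", "median"]),
            span)
  # the adjusted posterior is no wider than the rejection one
  expect_lte(pl@summary["t", "q975"] - pl@summary["t", "q025"],
             1.5 * (pr@summary["t", "q975"] - pr@summary["t", "q025"]))
})

test_that("confidence errors are consistent with the confusion matrix", {
  ref <- smallRef()
  conf <- abcConfidence(ref, focalScenario = 4, nPods = 8,
                        method = "rejection", seed = 99)
  cm <- conf$confusion
  expect_equal(sum(cm), 32)
  expect_equal(conf$typeI, 1 - cm["4", "4"] / sum(cm["4", ]))
  expect_equal(conf$typeII,
               sum(cm[c("1", "2", "3"), "4"]) /
                 sum(cm[c("1", "2", "3"), ]))
  expect_gte(conf$typeI, 0); expect_lte(conf$typeI, 1)
  conf2 <- abcConfidence(ref, focalScenario = 4, nPods = 8,
                         method = "rejection", seed = 99)
  expect_identical(conf$confusion, conf2$confusion)
})

test_that("the posterior-predictive check flags gross misfit only", {
  ref <- smallRef()
  pod <- simulateScenario(drawPriorParameters(scenarioSpec(4), seed = 8))
  chk <- abcModelCheck(ref, pod$stats, scenario = 4, nSim = 60,
                       nRetain = 500, seed = 3)
  expect_true(all(chk$ppp >= 0 & chk$ppp <= 1, na.rm = TRUE))
  expect_equal(length(chk$pcaObs), 2)
  # grossly misspecified observation: impossible heterozygosity pattern
  bad <- pod$stats
  bad[c("ATL_TAJD", "MED_TAJD")] <- 15
  chkBad <- abcModelCheck(ref, bad, scenario = 4, nSim = 60,
                          nRetain = 500, seed = 3)
  expect_true(all(chkBad$ppp[c("ATL_TAJD", "MED_TAJD")] > 0.99))
})

test_that("generation-time conversion reproduces the published arithmetic", {
  expect_equal(generationsToYears(6690), 60210)
  expect_equal(generationsToYears(c(2210, 45100)), c(19890, 405900))
  expect_equal(generationsToYears(100, generationTime = 5), 500)
})
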