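#' Heterozygosity excess/deficiency bottleneck test
#'
#' For each polymorphic locus, simulates the coalescent at mutation-drift
#' equilibrium under the chosen microsatellite model, with theta
#' calibrated by bisection so the expected allele count matches the
#' observed one, and keeps replicates whose simulated allele count equals
#' the observed count. The observed unbiased expected heterozygosity is
#' compared with the simulated equilibrium distribution; a one-tailed
#' Wilcoxon signed-rank test across loci on the standardized differences
#' tests for heterozygosity excess (recent bottleneck) and deficiency
#' (expansion).
#'
#' @param x a GenotypeDataset.
#' @param unit locality (or pooled group) label to test; NULL pools
#'   everything.
#' @param model "TPM" (default, as commonly configured: 70-90 percent
#'   single-step mutations) or "SMM".
#' @param pStep TPM probability of a single-step mutation.
#' @param varMultiStep TPM variance of the multi-step size distribution.
#' @param iterations equilibrium replicates per locus.
#' @param seed optional integer seed.
#' @return list with \code{perLocus} (data.frame: locus, k, n (genes),
#'   HeObs, HeqMean, HeqSd, stdDiff), \code{pExcess}, \code{pDeficiency},
#'   \code{model}.
#' @export
bottleneckTest <- function(x, unit = NULL, model = c("TPM", "SMM"),
                           pStep = 0.8, varMultiStep = 20,
                           iterations = 1000, seed = NULL) {
  model <- match.arg(model)
  maybeSeed(seed)
  if (!is.null(unit)) x <- subsetPops(x, unit)
  geomQ <- geomParamFromVar(varMultiStep)
  modelInt <- if (model == "SMM") 0L else 1L
  rows <- list()
  for (l in seq_len(nLoci(x))) {
    a1 <- x@calls[, l, 1]; a2 <- x@calls[, l, 2]
    g <- c(a1, a2); g <- g[!is.na(g)]
    n <- length(g)
    if (n < 10L) next
    k <- length(unique(g))
    if (k < 2L) next   # monomorphic loci are skipped
    p <- tabulate(match(g, unique(g))) / n
    HeObs <- n / (n - 1) * (1 - sum(p^2))
    theta <- calibrateThetaForK(n, k, modelInt, pStep, geomQ)
    sims <- .cppSimEqMsat(n, theta, iterations, modelInt, pStep, geomQ)
    match0 <- sims[, 1] == k
    if (sum(match0) < 20) match0 <- abs(sims[, 1] - k) <= 1
    if (sum(match0) < 2) next
    Heq <- sims[match0, 2]
    rows[[length(rows) + 1L]] <- data.frame(
      locus = x@loci[l], k = k, n = n, HeObs = HeObs,
      HeqMean = mean(Heq), HeqSd = sd(Heq),
      stdDiff = (HeObs - mean(Heq)) / sd(Heq))
  }
  if (length(rows) < 4L)
    stop("need at least four polymorphic loci for the Wilcoxon test")
  perLocus <- do.call(rbind, rows)
  pEx <- wilcox.test(perLocus$stdDiff, alternative = "greater",
                     mu = 0, exact = TRUE)$p.value
  pDef <- wilcox.test(perLocus$stdDiff, alternative = "less",
                      mu = 0, exact = TRUE)$p.value
  list(perLocus = perLocus, pExcess = pEx, pDeficiency = pDef,
       model = model)
}

# Bisection on log(theta) so that the simulated mean allele count matches
# the observed k (the usual equilibrium-calibration approach).
calibrateThetaForK <- function(n, k, modelInt, pStep, geomQ,
                               nCal = 200, iter = 10) {
  lo <- log(0.005); hi <- log(500)
  meanK <- function(lt)
    mean(.cppSimEqMsat(n, exp(lt), nCal, modelInt, pStep, geomQ)[, 1])
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (meanK(mid) < k) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}
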