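#' Expected FST after t generations of drift
#'
#' Pure-drift expectation 1 - (1 - 1/(2Ne))^t for subpopulations of
#' effective size Ne diverging from common base frequencies.
#'
#' @param Ne diploid effective size.
#' @param t generations of drift.
#' @return expected FST.
#' @export
expectedFstAfterDrift <- function(Ne, t) 1 - (1 - 1 / (2 * Ne))^t

#' Drift generations needed for a target FST
#'
#' Inverts \code{\link{expectedFstAfterDrift}}:
#' t = ln(1 - FST) / ln(1 - 1/(2Ne)), rounded to the nearest generation.
#'
#' @param targetFst desired FST.
#' @param Ne diploid effective size (3000 in the study design).
#' @return integer generations.
#' @export
driftGenerationsForFst <- function(targetFst, Ne = 3000) {
  as.integer(round(log(1 - targetFst) / log(1 - 1 / (2 * Ne))))
}

#' Describe a drift-based power design
#'
#' Captures everything a power run needs: per-locus base allele
#' frequencies, the drift parameters (Ne, t) that set the true level of
#' divergence, and the per-locality sample sizes of the design being
#' evaluated.
#'
#' @param baseFreqs list (one element per locus) of allele frequency
#'   vectors; see \code{\link{baseFrequencies}} to extract them from data.
#' @param sampleSizes named integer vector of diploid sample sizes per
#'   locality.
#' @param Ne diploid effective size during drift.
#' @param t generations of drift (use
#'   \code{\link{driftGenerationsForFst}} to hit a target FST).
#' @param alpha significance level.
#' @param reps replicates.
#' @return list of class "powerDesign".
#' @export
powerDesign <- function(baseFreqs, sampleSizes, Ne = 3000, t = 0,
                        alpha = 0.05, reps = 1000) {
  stopifnot(t >= 0, all(sampleSizes >= 1))
  for (f in baseFreqs)
    if (abs(sum(f) - 1) > 1e-8) stop("base frequencies must sum to 1")
  structure(list(baseFreqs = baseFreqs, sampleSizes = sampleSizes,
                 Ne = Ne, t = t, alpha = alpha, reps = reps),
            class = "powerDesign")
}

#' Base allele frequencies from a dataset
#'
#' Pooled sample frequencies per locus, the natural input for a power
#' design mirroring an empirical study.
#'
#' @param x a GenotypeDataset.
#' @param minCount drop alleles rarer than this pooled count.
#' @return list of frequency vectors, one per locus.
#' @export
baseFrequencies <- function(x, minCount = 1) {
  cnts <- lociAlleleCounts(x)
  lapply(cnts, function(m) {
    tot <- rowSums(m)
    tot <- tot[tot >= minCount]
    tot / sum(tot)
  })
}

#' Drift-based power analysis of a sampling design
#'
#' Each replicate drifts the base allele frequencies independently in
#' every locality for t generations (multinomial resampling of 2Ne gene
#' copies per generation), samples the design's gene counts from the
#' drifted frequencies, and tests for global allele-frequency
#' heterogeneity across localities. The per-locus null distribution is
#' the exact conditional one (random tables with fixed margins); the
#' default global test ("gsum") refers the summed per-locus G statistic
#' to its conditional null, which keeps the test size exact, while
#' combining the discrete per-locus p-values by Fisher's method
#' ("fisher") is also available but markedly conservative. Power is the
#' fraction of replicates with p < alpha; with t = 0 the true FST is zero
#' and power estimates the test's size.
#'
#' @param design a \code{\link{powerDesign}}.
#' @param test "gsum" (default) or "fisher".
#' @param B conditional-null tables per locus and replicate.
#' @param seed optional integer seed.
#' @return list with \code{power}, \code{se} (binomial), \code{pValues},
#'   \code{meanFst} (realized drift FST across replicates),
#'   \code{expectedFst}.
#' @export
powsimPower <- function(design, test = c("gsum", "fisher"), B = 200,
                        seed = NULL) {
  test <- match.arg(test)
  maybeSeed(seed)
  L <- length(design$baseFreqs)
  nPop <- length(design$sampleSizes)
  genes <- 2 * design$sampleSizes
  pvals <- numeric(design$reps)
  fstNum <- fstDen <- 0
  for (rep in seq_len(design$reps)) {
    gObs <- numeric(L)
    gSims <- matrix(0, B, L)
    pLoc <- numeric(L)
    for (l in seq_len(L)) {
      p0 <- design$baseFreqs[[l]]
      cnts <- matrix(0L, nPop, length(p0))
      for (s in seq_len(nPop)) {
        p <- p0
        tt <- design$t
        while (tt > 0) {
          p <- as.vector(rmultinom(1, 2 * design$Ne, p)) / (2 * design$Ne)
          tt <- tt - 1
        }
        if (design$t > 0) {
          fstNum <- fstNum + sum((p - p0)^2)
          fstDen <- fstDen + sum(p0 * (1 - p0))
        }
        cnts[s, ] <- as.vector(rmultinom(1, genes[s], p))
      }
      keep <- colSums(cnts) > 0
      cnts <- cnts[, keep, drop = FALSE]
      if (ncol(cnts) < 2L) { gSims[, l] <- 0; pLoc[l] <- 1; next }
      gObs[l] <- gFromTable(cnts)
      tabs <- stats::r2dtable(B, rowSums(cnts), colSums(cnts))
      gSims[, l] <- vapply(tabs, gFromTable, 0)
      pLoc[l] <- (1 + sum(gSims[, l] >= gObs[l] - 1e-12)) / (1 + B)
    }
    if (test == "fisher") {
      X <- -2 * sum(log(pLoc))
      pvals[rep] <- pchisq(X, df = 2 * L, lower.tail = FALSE)
    } else {
      pvals[rep] <- (1 + sum(rowSums(gSims) >= sum(gObs) - 1e-12)) /
        (1 + B)
    }
  }
  pow <- mean(pvals < design$alpha)
  meanFst <- if (design$t > 0) fstNum / fstDen else 0
  list(power = pow,
       se = sqrt(pow * (1 - pow) / design$reps),
       pValues = pvals,
       meanFst = meanFst,
       expectedFst = expectedFstAfterDrift(design$Ne, design$t))
}

gFromTable <- function(tab) {
  o <- as.vector(as.matrix(tab))
  e <- as.vector(outer(rowSums(tab), colSums(tab)) / sum(tab))
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}
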