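#' Construct a divergence scenario with priors
#'
#' Builds a \linkS4class{ScenarioSpec} for the four-scenario family of
#' two-population divergence models (see the class documentation). The
#' default prior bounds are the intervals used for the Atlantic versus
#' Mediterranean analysis: NATL 10-2e6, NMED 10-5e5, t 1-7e4 generations,
#' t1 1-2e4 (t1 < t), NbATL and NbMED 1-4e4, mean microsatellite rate
#' 1e-6 to 5e-4 per generation, mtDNA rate 1e-9 to 8e-8 per site per
#' generation. The ancestral size Nanc has no stated prior; by default it
#' shares the NATL prior and is exposed as an independent option.
#'
#' @param scenario integer 1..4.
#' @param priors optional named list overriding any of NATL, NMED, NbATL,
#'   NbMED, t, t1, Nanc (each c(min, max)).
#' @param muMsatPrior c(min, max) mean microsatellite mutation rate.
#' @param muMtPrior c(min, max) mtDNA substitution rate.
#' @param logUniform draw sizes/times log-uniformly instead of uniformly.
#' @return a ScenarioSpec.
#' @export
scenarioSpec <- function(scenario, priors = list(),
                         muMsatPrior = c(1e-6, 5e-4),
                         muMtPrior = c(1e-9, 8e-8),
                         logUniform = FALSE) {
  def <- list(NATL = c(10, 2e6), NMED = c(10, 5e5),
              NbATL = c(1, 4e4), NbMED = c(1, 4e4),
              t = c(1, 7e4), t1 = c(1, 2e4), Nanc = c(10, 2e6))
  def[names(priors)] <- priors
  new("ScenarioSpec", scenario = as.integer(scenario), priors = def,
      muMsatPrior = muMsatPrior, muMtPrior = muMtPrior,
      logUniform = logUniform)
}

#' Draw one parameter vector from a scenario's priors
#'
#' Uniform (or log-uniform) draws on the prior bounds; the constraint
#' t1 < t is enforced by redrawing t1 conditionally on the drawn t, which
#' leaves the marginal prior of t unchanged. Scenarios without a size
#' change in a population set that population's post-split size equal to
#' its present size. Per-locus microsatellite rates are drawn around the
#' mean rate from a Gamma distribution with shape 2 (clamped to
#' [1e-8, 1e-2]).
#'
#' @param spec a ScenarioSpec.
#' @param L number of microsatellite loci.
#' @param seed optional integer seed.
#' @return named list (a parameter draw): NATL, NMED, NbATL, NbMED, t,
#'   t1, Nanc, muMsatMean, muMsat (length L), muMt, scenario.
#' @export
drawPriorParameters <- function(spec, L = 9, seed = NULL) {
  maybeSeed(seed)
  dr <- function(b) {
    if (spec@logUniform) exp(runif(1, log(b[1]), log(b[2])))
    else runif(1, b[1], b[2])
  }
  p <- spec@priors
  t <- dr(p$t)
  b1 <- c(p$t1[1], min(p$t1[2], t))
  t1 <- if (b1[2] <= b1[1]) t / 2 else {
    if (spec@logUniform) exp(runif(1, log(b1[1]), log(b1[2])))
    else runif(1, b1[1], b1[2])
  }
  NATL <- dr(p$NATL); NMED <- dr(p$NMED)
  NbATL <- if (spec@scenario %in% c(3, 4)) dr(p$NbATL) else NATL
  NbMED <- if (spec@scenario %in% c(2, 4)) dr(p$NbMED) else NMED
  muMean <- dr(spec@muMsatPrior)
  muL <- pmin(pmax(rgamma(L, shape = 2, scale = muMean / 2), 1e-8), 1e-2)
  list(scenario = spec@scenario, NATL = NATL, NMED = NMED,
       NbATL = NbATL, NbMED = NbMED, t = t, t1 = t1, Nanc = dr(p$Nanc),
       muMsatMean = muMean, muMsat = muL, muMt = dr(spec@muMtPrior))
}

#' Simulate one dataset under a divergence scenario
#'
#' Backward-time coalescent: the two demes evolve at their present sizes
#' until t1 generations ago, at the post-split sizes from t1 back to the
#' split at t, and merge into an ancestral population of size Nanc.
#' Microsatellites mutate by +/-1 repeat steps (strict SMM by default; TPM
#' optional) at the drawn per-locus rates, allele codes reflected into
#' [50, 300]; mtDNA evolves under K2P (default ts:tv ratio 2) on a haploid
#' genealogy whose effective sizes are the nuclear sizes divided by 4.
#'
#' @param draw a parameter draw from \code{\link{drawPriorParameters}}.
#' @param nATL,nMED diploid sample sizes (microsatellites).
#' @param mtATL,mtMED mtDNA sample sizes (sequences).
#' @param seqLen mtDNA sequence length in bp.
#' @param tsRatio transition:transversion ratio of the K2P model.
#' @param msatModel "SMM" or "TPM".
#' @param pStep TPM probability of a single-step mutation.
#' @param varMultiStep TPM variance of multi-step sizes (geometric).
#' @param seed optional integer seed.
#' @return list with \code{gen} (GenotypeDataset, localities ATL/MED),
#'   \code{seqs} (HaplotypeDataset), \code{stats} (the summary vector as
#'   computed by the fast simulation path) and \code{draw}.
#' @export
simulateScenario <- function(draw, nATL = 85, nMED = 97, mtATL = 48,
                             mtMED = 66, seqLen = 613, tsRatio = 2,
                             msatModel = c("SMM", "TPM"), pStep = 0.8,
                             varMultiStep = 20, seed = NULL) {
  msatModel <- match.arg(msatModel)
  maybeSeed(seed)
  geomQ <- geomParamFromVar(varMultiStep)
  res <- .cppSimulateScenario(draw$NATL, draw$NMED, draw$NbATL,
    draw$NbMED, draw$t, draw$t1, draw$Nanc, draw$muMsat, draw$muMt,
    as.integer(nATL), as.integer(nMED), as.integer(mtATL),
    as.integer(mtMED), as.integer(seqLen), tsRatio,
    if (msatModel == "SMM") 0L else 1L, pStep, geomQ, TRUE)
  L <- length(draw$muMsat)
  n <- nATL + nMED
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (l in seq_len(L)) {
    calls[, l, 1] <- res$msat[, 2 * l - 1]
    calls[, l, 2] <- res$msat[, 2 * l]
  }
  gen <- genotypeDataset(calls,
                         pop = rep(c("ATL", "MED"), c(nATL, nMED)))
  bases <- c("A", "C", "G", "T")
  seqChar <- apply(res$mt, 1, function(r)
    paste(bases[r + 1L], collapse = ""))
  seqs <- haplotypeDataset(setNames(seqChar,
            paste0(rep(c("ATL", "MED"), c(mtATL, mtMED)), "_",
                   seq_len(mtATL + mtMED))),
            pop = rep(c("ATL", "MED"), c(mtATL, mtMED)))
  names(res$stats) <- summaryStatNames()
  list(gen = gen, seqs = seqs, stats = res$stats, draw = draw)
}

geomParamFromVar <- function(v) {
  # geometric on {1,2,...}: var = (1-q)/q^2; solve for q
  (-1 + sqrt(1 + 4 * v)) / (2 * v)
}

#' Names and order of the ABC summary-statistic vector
#'
#' Per population: mean allele number (A), mean unbiased expected
#' heterozygosity (HE), mean allele-size variance (VAR), haplotype number
#' (HN), haplotype diversity (HD), mean pairwise sequence differences
#' (PI), Tajima's D (TAJD); between populations: Weir-Cockerham FST
#' (microsatellites), Phi-ST (mtDNA), shared-allele distance (DAS) and
#' number of shared haplotypes (SHARED).
#'
#' @return character vector of length 18.
#' @export
summaryStatNames <- function() {
  c("ATL_A", "MED_A", "ATL_HE", "MED_HE", "ATL_VAR", "MED_VAR",
    "ATL_HN", "MED_HN", "ATL_HD", "MED_HD", "ATL_PI", "MED_PI",
    "ATL_TAJD", "MED_TAJD", "FST", "PHIST", "DAS", "SHARED")
}

#' Summary statistics of a two-population dataset
#'
#' Computes the fixed, ordered summary vector (see
#' \code{\link{summaryStatNames}}) for observed or simulated data, using
#' the same definitions as the fast simulation path; missing genotype
#' calls are excluded per locus. Undefined components (e.g. Tajima's D
#' with no segregating sites) are NA and are masked during ABC
#' standardization.
#'
#' @param gen a GenotypeDataset with exactly two populations.
#' @param seqs a HaplotypeDataset with the same two populations.
#' @return named numeric vector of length 18 (order: ATL-like population
#'   first, i.e. the first factor level).
#' @export
summaryStatistics <- function(gen, seqs) {
  if (nlevels(gen@pop) != 2L || nlevels(seqs@pop) != 2L)
    stop("summary statistics are defined for exactly two populations")
  pops <- popNames(gen)
  out <- setNames(rep(NA_real_, 18), summaryStatNames())
  cnts <- lociAlleleCounts(gen)
  for (q in 1:2) {
    p <- pops[q]
    A <- He <- Va <- numeric(0)
    for (l in seq_len(nLoci(gen))) {
      a1 <- gen@calls[gen@pop == p, l, 1]; a2 <- gen@calls[gen@pop == p, l, 2]
      g <- c(a1, a2); g <- g[!is.na(g)]
      if (length(g) < 2) next
      A <- c(A, length(unique(g)))
      pr <- tabulate(match(g, unique(g))) / length(g)
      He <- c(He, length(g) / (length(g) - 1) * (1 - sum(pr^2)))
      Va <- c(Va, var(g))
    }
    out[q] <- mean(A); out[2 + q] <- mean(He); out[4 + q] <- mean(Va)
    sub <- subsetPops(seqs, p)
    cc <- collapseHaplotypes(sub)
    out[6 + q] <- nrow(cc$counts)
    out[8 + q] <- haplotypeDiversity(rowSums(cc$counts))
    out[10 + q] <- meanPairwiseDiff(sub)
    out[12 + q] <- tajimasD(sub)
  }
  out["FST"] <- fstWeirCockerham(gen)$theta
  out["PHIST"] <- phiSt(seqs)$phiST
  das <- vapply(cnts, function(m) {
    tot <- colSums(m)
    if (any(tot == 0)) return(NA_real_)
    1 - sum(pmin(m[, 1] / tot[1], m[, 2] / tot[2]))
  }, 0)
  out["DAS"] <- mean(das, na.rm = TRUE)
  ccAll <- collapseHaplotypes(seqs)
  out["SHARED"] <- sum(ccAll$counts[, 1] > 0 & ccAll$counts[, 2] > 0)
  out
}

#' Mean time to the most recent common ancestor of a single deme
#'
#' Simulation helper exposing the genealogy engine for calibration against
#' coalescent theory (a sample of two gene copies from a population of G
#' copies has E[TMRCA] = G generations).
#'
#' @param n sample size (gene copies).
#' @param copies population size in gene copies.
#' @param reps replicates.
#' @param seed optional integer seed.
#' @return mean TMRCA in generations.
#' @export
meanTmrca <- function(n, copies, reps = 1000, seed = NULL) {
  maybeSeed(seed)
  .cppMeanTmrca(as.integer(n), copies, as.integer(reps))
}
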