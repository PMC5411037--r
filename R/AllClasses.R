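#' @import methods
#' @importFrom stats pchisq pnorm quantile rbinom rgamma rmultinom rnorm
#'   runif sd var density setNames lm coef p.adjust ks.test wilcox.test
#'   prcomp rpois dist weighted.mean median predict complete.cases cor
#'   residuals rexp r2dtable
#' @importFrom utils head combn
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   width uniqueLetters
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Diploid multilocus genotype dataset
#'
#' Container for co-dominant diploid genotypes (microsatellite allele codes)
#' with locality labels. Allele calls are stored as an integer array of
#' dimension individuals x loci x 2; a missing call has \code{NA} in both
#' slots of the pair.
#'
#' @slot ids character, one id per individual.
#' @slot pop factor, locality label per individual.
#' @slot loci character, locus names.
#' @slot calls integer array \code{n x L x 2} of allele codes (1-999),
#'   \code{NA} for missing.
#' @export
setClass("GenotypeDataset",
  representation(ids = "character", pop = "factor", loci = "character",
                 calls = "array"),
  validity = function(object) {
    d <- dim(object@calls)
    if (length(d) != 3L || d[3] != 2L)
      return("calls must be an n x L x 2 array")
    if (d[1] < 1L || d[2] < 1L)
      return("need at least one individual and one locus")
    if (length(object@ids) != d[1]) return("ids length != n individuals")
    if (length(object@pop) != d[1]) return("pop length != n individuals")
    if (length(object@loci) != d[2]) return("loci length != n loci")
    half <- is.na(object@calls[, , 1, drop = FALSE]) !=
            is.na(object@calls[, , 2, drop = FALSE])
    if (any(half)) return("half-missing calls are not allowed")
    cv <- object@calls[!is.na(object@calls)]
    if (length(cv) && (any(cv < 1) || any(cv > 999)))
      return("allele codes must lie in 1..999")
    TRUE
  })

#' Aligned haplotype sequence dataset
#'
#' Equal-length nucleotide sequences (one per sampled individual) with a
#' locality label each. The alignment is held as a
#' \code{\link[Biostrings]{DNAStringSet}}; A/C/G/T/N/- are accepted and
#' ambiguous positions are excluded pairwise in distance computations.
#'
#' @slot alignment \code{DNAStringSet} of equal-width sequences.
#' @slot pop factor, locality label per sequence.
#' @export
setClass("HaplotypeDataset",
  representation(alignment = "DNAStringSet", pop = "factor"),
  validity = function(object) {
    if (length(object@alignment) < 1L) return("empty alignment")
    w <- Biostrings::width(object@alignment)
    if (length(unique(w)) != 1L) return("sequences must have equal length")
    if (length(object@pop) != length(object@alignment))
      return("pop length != number of sequences")
    letters <- Biostrings::uniqueLetters(object@alignment)
    if (!all(letters %in% c("A", "C", "G", "T", "N", "-")))
      return("alphabet restricted to A/C/G/T/N/-")
    TRUE
  })

#' Pairwise differentiation matrix with significance
#'
#' Lower-triangular pairwise statistic (theta, Phi-ST or Jost's D) between
#' sampling units, with permutation p-values and Benjamini-Hochberg FDR
#' decisions at a set of alpha levels.
#'
#' @slot labels unit names, in order.
#' @slot stat numeric matrix of pairwise values (symmetric storage,
#'   diagonal \code{NA}).
#' @slot pValues numeric matrix of raw permutation p-values.
#' @slot signifCodes character matrix: "" or "*", "**", "***" per the
#'   largest alpha level at which the BH-adjusted decision is significant.
#' @slot statName one of "fst", "phist", "dest".
#' @slot nPerm permutations used.
#' @slot alphaLevels alpha levels for the FDR star codes.
#' @export
setClass("PairwiseStatMatrix",
  representation(labels = "character", stat = "matrix", pValues = "matrix",
                 signifCodes = "matrix", statName = "character",
                 nPerm = "numeric", alphaLevels = "numeric"),
  validity = function(object) {
    k <- length(object@labels)
    for (m in list(object@stat, object@pValues, object@signifCodes))
      if (!all(dim(m) == c(k, k))) return("matrix dimensions != labels")
    s <- object@stat[lower.tri(object@stat)]
    if (any(s[!is.na(s)] < -1 | s[!is.na(s)] > 1))
      return("stat values must lie in [-1, 1]")
    TRUE
  })

#' Hierarchical AMOVA result
#'
#' Variance components and fixation indices from a (two- or three-level)
#' analysis of molecular variance on pairwise distances, with permutation
#' p-values per level. Negative components are reported as computed.
#'
#' @slot df degrees of freedom per stratum.
#' @slot ss sums of squared deviations per stratum.
#' @slot sigma2 variance components (amongGroups, amongPopsWithinGroups,
#'   withinPops; two-level fits drop the group stratum).
#' @slot phi fixation indices (FCT, FSC, FST, or FST only for two levels).
#' @slot pValues permutation p-values per index.
#' @slot grouping named character mapping locality -> group.
#' @slot nPerm permutations used.
#' @export
setClass("AmovaResult",
  representation(df = "numeric", ss = "numeric", sigma2 = "numeric",
                 phi = "numeric", pValues = "numeric",
                 grouping = "character", nPerm = "numeric"))

#' Median-joining haplotype network
#'
#' Nodes are observed haplotypes plus inferred median vectors; edges carry
#' the number of mutational steps and the variable-alignment positions at
#' which the incident haplotypes differ.
#'
#' @slot nodes data.frame with columns id, type ("observed"/"median"),
#'   freq (total observed frequency; 0 for medians).
#' @slot edges data.frame with columns from, to, steps, positions
#'   (comma-separated 1-based alignment positions).
#' @slot popFreq matrix haplotype x locality of observed frequencies.
#' @slot haplotypes character matrix of states at variable sites
#'   (rownames = node ids).
#' @slot variableSites integer, 1-based alignment positions of the
#'   variable sites.
#' @export
setClass("HaploNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 popFreq = "matrix", haplotypes = "matrix",
                 variableSites = "integer"))

#' Two-population divergence scenario with priors
#'
#' Describes one of four divergence scenarios between an Atlantic-like and a
#' Mediterranean-like population: an ancestral population of size
#' \code{Nanc} splits \code{t} generations ago into two populations that
#' keep sizes \code{NbATL}/\code{NbMED} until \code{t1} generations ago and
#' then switch to the present sizes \code{NATL}/\code{NMED}. Scenario 1 has
#' no size change (post-split sizes equal present sizes); scenario 2 changes
#' only the MED size, scenario 3 only the ATL size, scenario 4 both.
#' Sizes are diploid effective sizes; the mitochondrial genealogy uses a
#' quarter of the nuclear effective size (maternal haploid inheritance).
#'
#' @slot scenario integer in 1..4.
#' @slot priors named list of c(min, max) uniform prior bounds for NATL,
#'   NMED, NbATL, NbMED, t, t1 (generations; t1 < t enforced by redraw) and
#'   Nanc.
#' @slot muMsatPrior c(min, max) for the mean microsatellite mutation rate
#'   per generation (stepwise mutation model).
#' @slot muMtPrior c(min, max) for the mtDNA substitution rate per site per
#'   generation (K2P model).
#' @slot logUniform logical: draw size and time parameters log-uniformly.
#' @export
setClass("ScenarioSpec",
  representation(scenario = "integer", priors = "list",
                 muMsatPrior = "numeric", muMtPrior = "numeric",
                 logUniform = "logical"),
  validity = function(object) {
    if (!object@scenario %in% 1:4) return("scenario must be 1..4")
    need <- c("NATL", "NMED", "NbATL", "NbMED", "t", "t1", "Nanc")
    if (!all(need %in% names(object@priors)))
      return(paste("priors must name", paste(need, collapse = ", ")))
    for (nm in need) {
      b <- object@priors[[nm]]
      if (length(b) != 2L || b[1] <= 0 || b[2] < b[1])
        return(paste("bad prior bounds for", nm))
    }
    TRUE
  })

#' ABC reference table
#'
#' Simulated records (scenario id, parameter draw, summary-statistic
#' vector) used for rejection/regression ABC. Statistics are standardized
#' by the reference-table mean and standard deviation before distances are
#' computed.
#'
#' @slot scenario integer vector of scenario ids per row.
#' @slot params numeric matrix of drawn parameters per row.
#' @slot stats numeric matrix of summary statistics per row.
#' @slot specs list of the ScenarioSpec objects the rows were drawn from.
#' @slot design list of the sampling design used (sample sizes, locus
#'   count, sequence length).
#' @export
setClass("ReferenceTable",
  representation(scenario = "integer", params = "matrix", stats = "matrix",
                 specs = "list", design = "list"),
  validity = function(object) {
    n <- length(object@scenario)
    if (nrow(object@params) != n || nrow(object@stats) != n)
      return("row counts of params/stats must match scenario vector")
    TRUE
  })

#' ABC posterior summary
#'
#' Per-parameter posterior location and interval estimates after local
#' regression adjustment on the logit scale, plus the weighted adjusted
#' draws themselves.
#'
#' @slot summary data.frame with one row per parameter: mean, median, mode,
#'   q025, q975.
#' @slot draws matrix of regression-adjusted parameter draws.
#' @slot weights Epanechnikov kernel weights per retained draw.
#' @slot scenario scenario id the posterior conditions on.
#' @slot method "loclinear" or "rejection".
#' @export
setClass("PosteriorSummary",
  representation(summary = "data.frame", draws = "matrix",
                 weights = "numeric", scenario = "integer",
                 method = "character"))
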