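# Weir-Cockerham variance components for one locus, vectorized over
# alleles. a1/a2: allele vectors of scored individuals, popf: factor.
wcComponentsLocus <- function(a1, a2, popf) {
  popf <- droplevels(popf)
  r <- nlevels(popf)
  if (r < 2L) return(c(a = 0, b = 0, c = 0))
  alleles <- unique(c(a1, a2))
  K <- length(alleles)
  if (K < 2L) return(c(a = 0, b = 0, c = 0))
  pi <- as.integer(popf)
  ni <- tabulate(pi, r)
  if (any(ni == 0)) {
    keep <- ni > 0
    return(wcComponentsLocus(a1[keep[pi]], a2[keep[pi]],
                             factor(pi[keep[pi]])))
  }
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  # allele counts per pop x allele
  cnt <- matrix(tabulate((i1 - 1L) * r + pi, r * K) +
                tabulate((i2 - 1L) * r + pi, r * K), nrow = r)
  het <- i1 != i2
  hcnt <- matrix(tabulate((i1[het] - 1L) * r + pi[het], r * K) +
                 tabulate((i2[het] - 1L) * r + pi[het], r * K), nrow = r)
  p <- cnt / (2 * ni)
  h <- hcnt / ni
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  A <- sum((nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1)))
  B <- sum((nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
     (2 * nbar - 1) / (4 * nbar) * hbar))
  C <- sum(hbar / 2)
  c(a = A, b = B, c = C)
}

#' Weir-Cockerham theta (FST)
#'
#' Multilocus theta from the Weir-Cockerham (1984) a/(a+b+c) variance
#' components, summing components over alleles and loci. Loci monomorphic
#' across the included units contribute zero components and so drop out of
#' the ratio. Negative estimates are reported as computed.
#'
#' @param x a GenotypeDataset.
#' @param units optional subset of locality labels (default: all).
#' @return list with \code{theta} (multilocus), \code{perLocus} (named
#'   vector), \code{components} (summed a, b, c).
#' @export
fstWeirCockerham <- function(x, units = NULL) {
  if (!is.null(units)) x <- subsetPops(x, units)
  if (nlevels(x@pop) < 2L) stop("need at least two units")
  tot <- c(a = 0, b = 0, c = 0)
  perLocus <- setNames(rep(NA_real_, nLoci(x)), x@loci)
  for (l in seq_len(nLoci(x))) {
    a1 <- x@calls[, l, 1]; a2 <- x@calls[, l, 2]
    ok <- !is.na(a1)
    cmp <- wcComponentsLocus(a1[ok], a2[ok], droplevels(x@pop[ok]))
    denom <- sum(cmp)
    perLocus[l] <- if (abs(denom) > 0) cmp["a"] / denom else NA_real_
    tot <- tot + cmp
  }
  theta <- if (abs(sum(tot)) > 0) unname(tot["a"] / sum(tot)) else NA_real_
  list(theta = theta, perLocus = perLocus, components = tot)
}

#' Phi-ST from pairwise sequence differences
#'
#' Two-level AMOVA on the matrix of pairwise nucleotide differences:
#' Phi-ST = sigma2_among / (sigma2_among + sigma2_within). The permutation
#' p-value shuffles sequences among units.
#'
#' @param x a HaplotypeDataset.
#' @param units optional subset of locality labels.
#' @param nPerm permutations for the p-value (0 to skip).
#' @param seed optional integer seed.
#' @return list with \code{phiST}, \code{sigma2}, \code{p} (NA when
#'   nPerm = 0).
#' @export
phiSt <- function(x, units = NULL, nPerm = 0, seed = NULL) {
  if (!is.null(units)) x <- subsetPops(x, units)
  if (nlevels(x@pop) < 2L) stop("need at least two units")
  ones <- names(which(table(x@pop) < 2))
  if (length(ones))
    stop("unit(s) with a single sequence: ", paste(ones, collapse = ", "))
  d2 <- pairwiseDiffs(alignmentMatrix(x))$diff
  res <- amovaDistTwoLevel(d2, x@pop)
  p <- NA_real_
  if (nPerm > 0) {
    maybeSeed(seed)
    sims <- replicate(nPerm, {
      amovaDistTwoLevel(d2, sample(x@pop))$phiST
    })
    p <- permPValue(res$phiST, sims, "ge")
  }
  c(res, list(p = p))
}

# Two-level AMOVA from a squared-distance matrix and unit factor.
amovaDistTwoLevel <- function(d2, pop) {
  pop <- droplevels(pop)
  N <- nrow(d2); P <- nlevels(pop)
  lt <- lower.tri(d2)
  ssT <- sum(d2[lt]) / N
  ssW <- 0
  np <- as.vector(table(pop))
  for (p in levels(pop)) {
    idx <- which(pop == p)
    ssW <- ssW + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  ssA <- ssT - ssW
  s2w <- ssW / (N - P)
  nprime <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (ssA / (P - 1) - s2w) / nprime
  phi <- if (s2a + s2w != 0) s2a / (s2a + s2w) else NA_real_
  list(phiST = phi,
       sigma2 = c(among = s2a, within = s2w),
       ss = c(among = ssA, within = ssW, total = ssT),
       df = c(among = P - 1, within = N - P))
}

#' Jost's differentiation estimator D
#'
#' Unbiased Dest = (k/(k-1)) (H'T - H'S) / (1 - H'S) from a matrix of
#' allele (or haplotype) counts per unit, using the Nei-Chesser
#' small-sample corrections with the harmonic mean number of gene copies:
#' H'S = (n~/(n~-1)) (1 - mean_j sum_a p_aj^2), H'T = (1 - sum_a pbar_a^2)
#' + H'S/(n~ k). Two units sharing no alleles give Dest = 1.
#'
#' @param counts matrix of allele counts, alleles x units (gene copies).
#' @return Dest; NA (flagged by warning) when H'S = 1 exactly.
#' @export
jostDest <- function(counts) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  if (k < 2L) stop("need at least two units")
  nj <- colSums(counts)
  if (any(nj == 0)) stop("unit with zero gene copies")
  p <- sweep(counts, 2, nj, "/")
  ntilde <- k / sum(1 / nj)
  Hs <- (ntilde / (ntilde - 1)) * (1 - mean(colSums(p^2)))
  pbar <- rowMeans(p)
  Ht <- (1 - sum(pbar^2)) + Hs / (ntilde * k)
  if (Hs >= 1) {
    warning("H'S = 1: Jost's D undefined")
    return(NA_real_)
  }
  (k / (k - 1)) * (Ht - Hs) / (1 - Hs)
}

#' Jost's D for a dataset
#'
#' Computes Dest per locus for a GenotypeDataset (arithmetic mean across
#' loci as the multilocus default, harmonic mean also reported) or a single
#' Dest from haplotype counts for a HaplotypeDataset.
#'
#' @param x a GenotypeDataset or HaplotypeDataset.
#' @param units optional subset of locality labels.
#' @return list with \code{Dest} (default multilocus value),
#'   \code{perLocus} (GenotypeDataset only) and \code{harmonic}.
#' @export
jostDestData <- function(x, units = NULL) {
  if (!is.null(units)) x <- subsetPops(x, units)
  if (is(x, "HaplotypeDataset")) {
    cc <- collapseHaplotypes(x)
    d <- jostDest(cc$counts)
    return(list(Dest = d, perLocus = NULL, harmonic = d))
  }
  cnts <- lociAlleleCounts(x)
  per <- vapply(cnts, function(m) {
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2L || nrow(m) < 2L) return(NA_real_)
    jostDest(m)
  }, 0)
  names(per) <- x@loci
  v <- per[!is.na(per)]
  harm <- if (all(v > 0)) length(v) / sum(1 / v) else NA_real_
  list(Dest = mean(v), perLocus = per, harmonic = harm)
}

#' G-test for allele frequency differences between two units
#'
#' Per-locus G = 2 sum o log(o/e) on the 2 x alleles contingency table of
#' allele counts (zero-margin alleles dropped), with p-values from
#' permutation of individuals between the units; loci are combined by
#' Fisher's method for a global test, and the permutation p of the summed
#' G statistic is reported alongside.
#'
#' @param x a GenotypeDataset.
#' @param units character vector of exactly two locality labels.
#' @param nPerm permutations.
#' @param seed optional integer seed.
#' @return list with \code{perLocus} (data.frame locus, G, p),
#'   \code{fisherP}, \code{sumG}, \code{sumGP}.
#' @export
gTestAllelic <- function(x, units, nPerm = 1000, seed = NULL) {
  stopifnot(length(units) == 2L)
  x <- subsetPops(x, units)
  maybeSeed(seed)
  obs <- gStatsAllLoci(x@calls, x@pop)
  sims <- matrix(0, nPerm, nLoci(x))
  for (b in seq_len(nPerm))
    sims[b, ] <- gStatsAllLoci(x@calls, sample(x@pop))
  pLoc <- vapply(seq_len(nLoci(x)), function(l)
    permPValue(obs[l], sims[, l], "ge"), 0)
  fisherX <- -2 * sum(log(pLoc))
  fisherP <- pchisq(fisherX, df = 2 * length(pLoc), lower.tail = FALSE)
  sumGP <- permPValue(sum(obs), rowSums(sims), "ge")
  list(perLocus = data.frame(locus = x@loci, G = obs, p = pLoc),
       fisherP = fisherP, sumG = sum(obs), sumGP = sumGP)
}

gStatsAllLoci <- function(calls, popf) {
  L <- dim(calls)[2]
  vapply(seq_len(L), function(l) {
    a1 <- calls[, l, 1]; a2 <- calls[, l, 2]
    ok <- !is.na(a1)
    gStatCounts(c(a1[ok], a2[ok]), rep(popf[ok], 2L))
  }, 0)
}

gStatCounts <- function(genes, labels) {
  tab <- table(labels, genes)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.vector(tab); e <- as.vector(e)
  2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
}

#' Pairwise differentiation matrix with permutation tests and FDR
#'
#' Computes the chosen statistic for every pair of sampling units, a
#' permutation p-value per pair (labels shuffled between the two units),
#' and Benjamini-Hochberg FDR decisions over the whole family of pairwise
#' tests at each alpha level (star codes as in the usual table layout).
#'
#' @param x a GenotypeDataset (stat "fst" or "dest") or HaplotypeDataset
#'   (stat "phist" or "dest").
#' @param stat one of "fst", "phist", "dest".
#' @param nPerm permutations per pair (warning below 100).
#' @param alphaLevels alpha levels for the star codes.
#' @param seed optional integer seed.
#' @return a \linkS4class{PairwiseStatMatrix}.
#' @export
pairwiseStats <- function(x, stat = c("fst", "phist", "dest"),
                          nPerm = 1000, alphaLevels = c(0.05, 0.01, 0.001),
                          seed = NULL) {
  stat <- match.arg(stat)
  if (nPerm < 100) warning("fewer than 100 permutations")
  maybeSeed(seed)
  pops <- levels(x@pop)
  k <- length(pops)
  if (k < 2L) stop("need at least two units")
  statM <- pM <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pr <- pairStatPerm(x, stat, c(pops[i], pops[j]), nPerm)
    statM[i, j] <- statM[j, i] <- pr$value
    pM[i, j] <- pM[j, i] <- pr$p
  }
  lt <- lower.tri(pM)
  fam <- fdrStars(pM[lt], alphaLevels)
  stars <- matrix("", k, k, dimnames = list(pops, pops))
  stars[lt] <- fam$stars
  stars[upper.tri(stars)] <- t(stars)[upper.tri(stars)]
  new("PairwiseStatMatrix", labels = pops, stat = statM, pValues = pM,
      signifCodes = stars, statName = stat, nPerm = nPerm,
      alphaLevels = alphaLevels)
}

pairStatPerm <- function(x, stat, units, nPerm) {
  sub <- subsetPops(x, units)
  if (stat == "phist") {
    d2 <- pairwiseDiffs(alignmentMatrix(sub))$diff
    f <- function(popf) amovaDistTwoLevel(d2, popf)$phiST
  } else if (stat == "fst") {
    f <- function(popf) {
      tot <- c(0, 0, 0)
      for (l in seq_len(nLoci(sub))) {
        a1 <- sub@calls[, l, 1]; a2 <- sub@calls[, l, 2]
        ok <- !is.na(a1)
        tot <- tot + wcComponentsLocus(a1[ok], a2[ok],
                                       droplevels(popf[ok]))
      }
      if (abs(sum(tot)) > 0) tot[1] / sum(tot) else NA_real_
    }
  } else {
    if (is(sub, "HaplotypeDataset")) {
      cc <- collapseHaplotypes(sub)
      hap <- cc$assignment
      f <- function(popf) {
        m <- table(hap, popf)
        jostDest(matrix(as.integer(m), nrow(m)))
      }
    } else {
      f <- function(popf) {
        tmp <- genotypeDataset(sub@calls, pop = as.character(popf),
                               ids = sub@ids, loci = sub@loci)
        jostDestData(tmp)$Dest
      }
    }
  }
  obs <- f(sub@pop)
  if (nPerm > 0) {
    sims <- replicate(nPerm, f(sample(sub@pop)))
    p <- permPValue(obs, sims, "ge")
  } else p <- NA_real_
  list(value = obs, p = p)
}
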