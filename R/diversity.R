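#' Observed and unbiased expected heterozygosity
#'
#' For each population x locus cell with at least one scored individual,
#' computes the observed heterozygosity HO (fraction of heterozygous
#' individuals among scored) and Nei's unbiased expected heterozygosity
#' HE = (2n/(2n-1)) (1 - sum p_k^2) from the sample allele frequencies of
#' the n scored diploids. Cells with no scored individuals are NA (absent,
#' not zero).
#'
#' @param x a GenotypeDataset.
#' @param by "population" for per-locality rows, "total" for a single row
#'   over the pooled sample.
#' @return data.frame with columns pop, locus, n (scored diploids), HO, HE.
#' @seealso \code{\link{totalGeneDiversity}} for the pooled-frequency HT.
#' @export
heterozygosity <- function(x, by = c("population", "total")) {
  by <- match.arg(by)
  if (by == "total")
    x <- genotypeDataset(x@calls, pop = rep("total", nInd(x)),
                         ids = x@ids, loci = x@loci)
  pops <- levels(x@pop)
  out <- expand.grid(pop = pops, locus = x@loci, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$n <- NA_integer_; out$HO <- NA_real_; out$HE <- NA_real_
  for (r in seq_len(nrow(out))) {
    l <- match(out$locus[r], x@loci)
    sel <- x@pop == out$pop[r]
    a1 <- x@calls[sel, l, 1]; a2 <- x@calls[sel, l, 2]
    ok <- !is.na(a1)
    n <- sum(ok)
    out$n[r] <- n
    if (n == 0L) next
    out$HO[r] <- mean(a1[ok] != a2[ok])
    p <- tabulate(match(c(a1[ok], a2[ok]), unique(c(a1[ok], a2[ok])))) /
         (2 * n)
    out$HE[r] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }
  out
}

#' Total gene diversity (HT) per locus
#'
#' Nei's gene diversity computed on the allele frequencies of the pooled
#' sample (pooling weights populations by their sample sizes).
#'
#' @param x a GenotypeDataset.
#' @param unbiased apply the (2n/(2n-1)) small-sample correction.
#' @return named numeric vector, one HT per locus.
#' @export
totalGeneDiversity <- function(x, unbiased = TRUE) {
  out <- numeric(nLoci(x))
  for (l in seq_len(nLoci(x))) {
    a <- c(x@calls[, l, 1], x@calls[, l, 2])
    a <- a[!is.na(a)]
    n2 <- length(a)
    if (n2 < 2L) { out[l] <- NA_real_; next }
    p <- tabulate(match(a, unique(a))) / n2
    h <- 1 - sum(p^2)
    out[l] <- if (unbiased) n2 / (n2 - 1) * h else h
  }
  setNames(out, x@loci)
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a random subsample of \code{g} gene
#' copies: Rs = sum_a [1 - C(N - N_a, g) / C(N, g)] with N scored genes and
#' N_a copies of allele a. With \code{g = N} this is the observed allele
#' count; a monomorphic cell gives Rs = 1.
#'
#' @param x a GenotypeDataset.
#' @param g rarefaction size in gene copies (2 x diploid individuals). The
#'   default uses the smallest number of scored genes over all
#'   population x locus cells.
#' @return list with \code{perCell} (data.frame pop, locus, N, A, Rs),
#'   \code{perPop} (mean Rs over loci per population) and \code{g}.
#' @export
allelicRichness <- function(x, g = NULL) {
  pops <- levels(x@pop)
  counts <- lociAlleleCounts(x)
  Ns <- 2 * scoredCounts(x)
  if (is.null(g)) g <- min(Ns[Ns > 0])
  bad <- which(Ns < g, arr.ind = TRUE)
  if (length(bad))
    stop("rarefaction size g = ", g, " exceeds scored genes in cell (",
         pops[bad[1, 1]], ", ", x@loci[bad[1, 2]], ")")
  perCell <- expand.grid(pop = pops, locus = x@loci,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  perCell$N <- NA_real_; perCell$A <- NA_integer_; perCell$Rs <- NA_real_
  for (r in seq_len(nrow(perCell))) {
    l <- match(perCell$locus[r], x@loci)
    na <- counts[[l]][, perCell$pop[r]]
    na <- na[na > 0]
    N <- sum(na)
    perCell$N[r] <- N
    perCell$A[r] <- length(na)
    perCell$Rs[r] <-
      sum(1 - exp(lchoose(N - na, g) - lchoose(N, g)))
  }
  perPop <- tapply(perCell$Rs, perCell$pop, mean)[pops]
  list(perCell = perCell, perPop = perPop, g = g)
}

#' Weir-Cockerham inbreeding coefficient (FIS)
#'
#' Within-population f from the Weir-Cockerham variance components: per
#' allele, b = (n/(n-1)) [p(1-p) - (2n-1)/(4n) h] and c = h/2 with h the
#' frequency of heterozygotes carrying the allele; f = 1 - sum(c)/sum(b+c)
#' with components summed over alleles (per locus) or over alleles and loci
#' (multilocus), so loci are weighted exactly as in the multilocus
#' estimator. Populations where every included locus is monomorphic return
#' NA (undefined, flagged).
#'
#' @param x a GenotypeDataset.
#' @param loci optional subset of locus names (e.g. to drop loci with
#'   suspected null alleles).
#' @return list with \code{perLocus} (matrix pop x locus) and
#'   \code{multilocus} (named vector per population).
#' @export
inbreedingFis <- function(x, loci = NULL) {
  if (!is.null(loci)) {
    keep <- match(loci, x@loci)
    if (anyNA(keep)) stop("unknown loci requested")
    x <- genotypeDataset(x@calls[, keep, , drop = FALSE], pop = x@pop,
                         ids = x@ids, loci = x@loci[keep])
  }
  pops <- levels(x@pop)
  perLocus <- matrix(NA_real_, length(pops), nLoci(x),
                     dimnames = list(pops, x@loci))
  multi <- setNames(numeric(length(pops)), pops)
  for (p in pops) {
    sel <- x@pop == p
    sb <- sc <- 0
    for (l in seq_len(nLoci(x))) {
      a1 <- x@calls[sel, l, 1]; a2 <- x@calls[sel, l, 2]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n < 2L) next
      a1 <- a1[ok]; a2 <- a2[ok]
      alleles <- unique(c(a1, a2))
      if (length(alleles) < 2L) { perLocus[p, l] <- NA; next }
      bl <- cl <- 0
      for (al in alleles) {
        pfreq <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
        h <- mean((a1 == al) != (a2 == al))
        b <- (n / (n - 1)) *
          (pfreq * (1 - pfreq) - (2 * n - 1) / (4 * n) * h)
        bl <- bl + b; cl <- cl + h / 2
      }
      perLocus[p, l] <- if (bl + cl > 0) 1 - cl / (bl + cl) else NA
      sb <- sb + bl; sc <- sc + cl
    }
    multi[p] <- if (sb + sc > 0) 1 - sc / (sb + sc) else NA
  }
  list(perLocus = perLocus, multilocus = multi)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided conditional probability test: the p-value is the total
#' probability, given the observed allele counts, of all genotype tables at
#' most as probable as the observed one (Levene's conditional
#' distribution). For two alleles the table space is enumerated completely;
#' for more alleles a seeded Monte Carlo sample of random gene pairings is
#' used. A monomorphic cell returns p = 1 (flagged in the \code{method}
#' column).
#'
#' @param x a GenotypeDataset.
#' @param B Monte Carlo draws when enumeration is not used.
#' @param seed optional integer seed for the Monte Carlo path.
#' @return data.frame pop, locus, p, method ("enumeration", "montecarlo"
#'   or "monomorphic").
#' @export
hweExactTest <- function(x, B = 1e5, seed = NULL) {
  maybeSeed(seed)
  pops <- levels(x@pop)
  out <- expand.grid(pop = pops, locus = x@loci, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$p <- NA_real_; out$method <- NA_character_
  for (r in seq_len(nrow(out))) {
    l <- match(out$locus[r], x@loci)
    sel <- x@pop == out$pop[r]
    a1 <- x@calls[sel, l, 1]; a2 <- x@calls[sel, l, 2]
    ok <- !is.na(a1)
    res <- hweCell(a1[ok], a2[ok], B)
    out$p[r] <- res$p; out$method[r] <- res$method
  }
  out
}

hweCell <- function(a1, a2, B) {
  n <- length(a1)
  if (n == 0L) return(list(p = NA_real_, method = "empty"))
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) return(list(p = 1, method = "monomorphic"))
  m <- tabulate(match(c(a1, a2), alleles), nbins = k)
  if (k == 2L) {
    # enumerate over the heterozygote count (fixed parity with m[1])
    n1 <- m[1]
    hets <- seq(n1 %% 2, min(n1, m[2]), by = 2)
    logp <- vapply(hets, function(h) {
      n11 <- (n1 - h) / 2; n22 <- (m[2] - h) / 2
      lfactorial(n) + sum(lfactorial(m)) + h * log(2) -
        lfactorial(2 * n) - lfactorial(n11) - lfactorial(n22) -
        lfactorial(h)
    }, 0)
    hobs <- sum(a1 != a2)
    pobs <- logp[match(hobs, hets)]
    p <- sum(exp(logp[logp <= pobs + 1e-9]))
    return(list(p = min(1, p), method = "enumeration"))
  }
  # Monte Carlo: re-pair the gene pool at random
  genoId <- function(x1, x2) {
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    (lo - 1L) * k + hi
  }
  logProbFromIds <- function(ids) {
    cnt <- tabulate(ids, nbins = k * k)
    nz <- which(cnt > 0L)
    het <- ((nz - 1L) %/% k + 1L) != ((nz - 1L) %% k + 1L)
    H <- sum(cnt[nz][het])
    lfactorial(n) + sum(lfactorial(m)) + H * log(2) -
      lfactorial(2 * n) - sum(lfactorial(cnt[nz]))
  }
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lpObs <- logProbFromIds(genoId(i1, i2))
  pool <- c(i1, i2)
  hits <- 0L
  for (b in seq_len(B)) {
    s <- sample(pool)
    lp <- logProbFromIds(genoId(s[seq_len(n)], s[n + seq_len(n)]))
    if (lp <= lpObs + 1e-9) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + B), method = "montecarlo")
}

#' Unbiased haplotype diversity
#'
#' Hd = (n/(n-1)) (1 - sum (c_i/n)^2) for haplotype counts c_i summing to
#' n. Full precision is returned; round to three decimals at the reporting
#' layer.
#'
#' @param counts haplotype count vector.
#' @param n sample size; must equal \code{sum(counts)}.
#' @return Hd in [0, 1]; NA when n < 2 (undefined).
#' @examples
#' round(haplotypeDiversity(c(6, 3, 1)), 3)   # 0.600
#' round(haplotypeDiversity(c(46, 2, 1)), 3)  # 0.119
#' @export
haplotypeDiversity <- function(counts, n = sum(counts)) {
  if (!isTRUE(all.equal(sum(counts), n)))
    stop("counts must sum to n")
  if (n < 2) return(NA_real_)
  unbiasedDiversity(counts)
}

#' Nucleotide diversity per site
#'
#' Mean over all C(n,2) sequence pairs of the proportion of differing
#' sites, with pairwise deletion of ambiguous positions (N or -).
#'
#' @param x a HaplotypeDataset (or subset).
#' @return pi per site; NA when undefined.
#' @export
nucleotideDiversity <- function(x) {
  n <- nSeq(x)
  if (n < 2L) return(NA_real_)
  m <- alignmentMatrix(x)
  pd <- pairwiseDiffs(m)
  lt <- lower.tri(pd$diff)
  comp <- pd$comp[lt]
  if (all(comp == 0)) return(NA_real_)
  mean((pd$diff[lt] / comp)[comp > 0])
}

#' Mean number of pairwise sequence differences
#'
#' @param x a HaplotypeDataset.
#' @return mean count of differing sites over all sequence pairs.
#' @export
meanPairwiseDiff <- function(x) {
  if (nSeq(x) < 2L) return(NA_real_)
  pd <- pairwiseDiffs(alignmentMatrix(x))
  mean(pd$diff[lower.tri(pd$diff)])
}

#' Segregating sites, transition/transversion counts and haplotype number
#'
#' Counts variable alignment columns (ignoring N and -), classifies
#' biallelic variable sites as transitions (A<->G, C<->T) or transversions,
#' and reports the number of distinct haplotypes. Sites with three or more
#' states are counted in S but excluded from the ts/tv classification with
#' a warning.
#'
#' @param x a HaplotypeDataset.
#' @return list with S, transitions, transversions, nHaplotypes,
#'   variableSites (1-based positions).
#' @export
segregatingSites <- function(x) {
  m <- alignmentMatrix(x)
  ts <- tv <- 0L; multi <- 0L
  varSites <- integer(0)
  for (j in seq_len(ncol(m))) {
    st <- unique(m[, j])
    st <- st[!st %in% AMBIG]
    if (length(st) < 2L) next
    varSites <- c(varSites, j)
    if (length(st) == 2L) {
      pair <- paste(sort(st), collapse = "")
      if (pair %in% c("AG", "CT")) ts <- ts + 1L else tv <- tv + 1L
    } else multi <- multi + 1L
  }
  if (multi > 0L)
    warning(multi, " site(s) with >2 states excluded from ts/tv counts")
  list(S = length(varSites), transitions = ts, transversions = tv,
       nHaplotypes = length(unique(as.character(x@alignment))),
       variableSites = varSites)
}

#' Assemble a per-locality diversity table
#'
#' One row per locality combining the microsatellite summaries (mean HO,
#' HE, multilocus FIS, mean allele count A, mean rarefied richness Rs) and
#' the mitochondrial summaries (sample size, haplotype number Hn, unique
#' haplotypes, haplotype diversity Hd, nucleotide diversity pi). Values are
#' rounded only here, at the reporting layer.
#'
#' @param gen a GenotypeDataset (or NULL to skip the nuclear block).
#' @param seqs a HaplotypeDataset (or NULL to skip the mtDNA block).
#' @param rarefactionGenes rarefaction size g passed to
#'   \code{\link{allelicRichness}}.
#' @param digits rounding for reported values.
#' @return data.frame, one row per locality.
#' @export
diversityTable <- function(gen = NULL, seqs = NULL,
                           rarefactionGenes = NULL, digits = 3) {
  stopifnot(!is.null(gen) || !is.null(seqs))
  pops <- union(if (!is.null(gen)) popNames(gen) else character(0),
                if (!is.null(seqs)) popNames(seqs) else character(0))
  out <- data.frame(pop = pops, stringsAsFactors = FALSE)
  if (!is.null(gen)) {
    het <- heterozygosity(gen)
    fis <- inbreedingFis(gen)$multilocus
    rich <- allelicRichness(gen, g = rarefactionGenes)
    agg <- function(v, f) tapply(v, f, mean, na.rm = TRUE)
    out$N_msat <- as.integer(table(populations(gen))[pops])
    out$HO <- round(agg(het$HO, het$pop)[pops], 2)
    out$HE <- round(agg(het$HE, het$pop)[pops], 2)
    out$FIS <- round(fis[pops], digits)
    cnts <- lociAlleleCounts(gen)
    A <- sapply(pops, function(p)
      mean(vapply(cnts, function(m) sum(m[, p] > 0), 0)))
    out$A <- round(A, 1)
    out$Rs <- round(rich$perPop[pops], 1)
  }
  if (!is.null(seqs)) {
    out$N_mt <- as.integer(table(populations(seqs))[pops])
    hn <- hd <- pi <- rep(NA_real_, length(pops))
    for (i in seq_along(pops)) {
      if (is.na(out$N_mt[i]) || out$N_mt[i] == 0) next
      sub <- subsetPops(seqs, pops[i])
      cc <- collapseHaplotypes(sub)
      hn[i] <- nrow(cc$counts)
      hd[i] <- haplotypeDiversity(rowSums(cc$counts))
      pi[i] <- nucleotideDiversity(sub)
    }
    out$Hn <- hn
    out$Hd <- round(hd, digits)
    out$pi <- round(pi, 4)
  }
  out
}
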