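#' Isolation-by-distance Mantel test
#'
#' Least-squares regression of genetic distance on geographic distance over
#' the lower triangle of the matrices, with a Mantel permutation test
#' (units permuted jointly in rows and columns of the genetic matrix; the
#' test statistic is the Pearson correlation, upper tail for positive
#' isolation by distance). The genetic matrix can optionally be linearized
#' as g/(1-g) before regression.
#'
#' @param gen genetic distance matrix or a \linkS4class{PairwiseStatMatrix}.
#' @param geo geographic distance matrix (same unit order; positive
#'   off-diagonal).
#' @param nPerm permutations.
#' @param transform "raw" or "linearized" (g/(1-g)).
#' @param seed optional integer seed.
#' @return list with \code{a} (intercept), \code{b} (slope), \code{r}
#'   (Mantel correlation), \code{p}.
#' @export
mantelIbd <- function(gen, geo, nPerm = 10000,
                      transform = c("raw", "linearized"), seed = NULL) {
  transform <- match.arg(transform)
  if (is(gen, "PairwiseStatMatrix")) gen <- statMatrix(gen)
  gen <- as.matrix(gen); geo <- as.matrix(geo)
  if (!all(dim(gen) == dim(geo))) stop("matrix dimensions differ")
  if (!is.null(rownames(gen)) && !is.null(rownames(geo)) &&
      !identical(rownames(gen), rownames(geo)))
    stop("unit labels of gen and geo do not match")
  if (any(geo[lower.tri(geo)] <= 0))
    stop("geographic distances must be positive off-diagonal")
  if (transform == "linearized") gen <- gen / (1 - gen)
  maybeSeed(seed)
  lt <- lower.tri(gen)
  gv <- gen[lt]; dv <- geo[lt]
  if (sd(gv) == 0) {
    return(list(a = mean(gv), b = 0, r = 0, p = 1))
  }
  fit <- lm(gv ~ dv)
  r <- unname(cor(gv, dv))
  n <- nrow(gen)
  sims <- replicate(nPerm, {
    o <- sample(n)
    cor(gen[o, o][lt], dv)
  })
  list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]), r = r,
       p = permPValue(r, sims, "ge"))
}

# unit x allele (or haplotype) relative frequency table
frequencyTable <- function(x) {
  if (is(x, "HaplotypeDataset")) {
    cc <- collapseHaplotypes(x)
    f <- t(cc$counts)
    f / rowSums(f)
  } else {
    cnts <- lociAlleleCounts(x)
    blocks <- lapply(seq_along(cnts), function(l) {
      m <- t(cnts[[l]])
      tot <- rowSums(m)
      tot[tot == 0] <- 1
      colnames(m) <- paste(x@loci[l], colnames(m), sep = ".")
      m / tot
    })
    do.call(cbind, blocks)
  }
}

#' PCA on allele or haplotype frequencies
#'
#' Centered principal component analysis of the unit x frequency table.
#' Axis significance is assessed by permuting individuals (or sequences)
#' among units and recomputing the eigenvalue of each axis; the p-value is
#' the fraction of randomizations whose k-th eigenvalue is at least the
#' observed one.
#'
#' @param x a GenotypeDataset or HaplotypeDataset with >= 3 units.
#' @param nRand randomizations for axis p-values (0 to skip).
#' @param nAxes axes to report.
#' @param seed optional integer seed.
#' @return list with \code{scores} (unit x axis), \code{inertia}
#'   (variance fraction per axis, summing to 1 over all axes),
#'   \code{axisP}.
#' @export
frequencyPca <- function(x, nRand = 1000, nAxes = 2, seed = NULL) {
  if (nlevels(x@pop) < 3L) stop("need at least three units")
  maybeSeed(seed)
  doPca <- function(obj) {
    f <- frequencyTable(obj)
    pc <- prcomp(f, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    list(scores = pc$x, frac = ev / sum(ev), ev = ev)
  }
  obs <- doPca(x)
  nAxes <- min(nAxes, ncol(obs$scores))
  axisP <- rep(NA_real_, nAxes)
  if (nRand > 0) {
    sims <- replicate(nRand, {
      shuffled <- if (is(x, "HaplotypeDataset"))
        haplotypeDataset(x@alignment, sample(as.character(x@pop)))
      else genotypeDataset(x@calls, sample(as.character(x@pop)),
                           ids = x@ids, loci = x@loci)
      doPca(shuffled)$ev[seq_len(nAxes)]
    })
    sims <- matrix(sims, nrow = nAxes)
    for (k in seq_len(nAxes))
      axisP[k] <- permPValue(obs$ev[k], sims[k, ], "ge")
  }
  list(scores = obs$scores[, seq_len(nAxes), drop = FALSE],
       inertia = obs$frac, axisP = axisP)
}

#' Mean between-group p-distance with bootstrap SE
#'
#' Average proportion of differing sites over inter-group sequence pairs
#' (pairwise deletion of ambiguous positions), with a standard error from
#' bootstrap resampling of alignment sites. By default each distinct
#' haplotype enters the average once ("haplotypes"); with
#' weights = "sequences" every sampled sequence enters, so common
#' haplotypes dominate the average.
#'
#' @param x a HaplotypeDataset.
#' @param grouping named character locality -> group; exactly two groups.
#' @param nBoot bootstrap replicates over sites.
#' @param weights "haplotypes" or "sequences".
#' @param seed optional integer seed.
#' @return list with \code{pDistance}, \code{se}, \code{nPairs}.
#' @export
groupPDistance <- function(x, grouping, nBoot = 10000,
                           weights = c("haplotypes", "sequences"),
                           seed = NULL) {
  weights <- match.arg(weights)
  grouping <- validateGrouping(x, grouping)
  if (length(unique(grouping)) != 2L) stop("exactly two groups required")
  maybeSeed(seed)
  grp <- unname(grouping[as.character(x@pop)])
  m <- alignmentMatrix(x)
  if (weights == "haplotypes") {
    key <- paste(apply(m, 1, paste, collapse = ""), grp)
    keep <- !duplicated(key)
    m <- m[keep, , drop = FALSE]; grp <- grp[keep]
  }
  gl <- unique(grp)
  i1 <- which(grp == gl[1]); i2 <- which(grp == gl[2])
  # per inter-group pair x site: 1 = differ, 0 = match, NA = not comparable
  Lc <- ncol(m)
  pairMat <- matrix(NA_real_, length(i1) * length(i2), Lc)
  r <- 0L
  dropped <- 0L
  for (i in i1) for (j in i2) {
    r <- r + 1L
    ok <- !(m[i, ] %in% AMBIG) & !(m[j, ] %in% AMBIG)
    if (!any(ok)) { dropped <- dropped + 1L; next }
    v <- rep(NA_real_, Lc)
    v[ok] <- as.numeric(m[i, ok] != m[j, ok])
    pairMat[r, ] <- v
  }
  if (dropped > 0L)
    warning(dropped, " pair(s) with no comparable sites dropped")
  pairMat <- pairMat[rowSums(!is.na(pairMat)) > 0, , drop = FALSE]
  meanP <- function(cols)
    mean(rowMeans(pairMat[, cols, drop = FALSE], na.rm = TRUE))
  obs <- meanP(seq_len(Lc))
  se <- NA_real_
  if (nBoot > 0) {
    reps <- replicate(nBoot, meanP(sample.int(Lc, Lc, replace = TRUE)))
    se <- sd(reps, na.rm = TRUE)
  }
  list(pDistance = obs, se = se, nPairs = nrow(pairMat))
}
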