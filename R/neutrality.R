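#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)) with k the mean number of
#' pairwise differences, S the number of segregating sites and the standard
#' a1, a2, b1, b2, c1, c2, e1, e2 constants for sample size n.
#'
#' @param x a HaplotypeDataset (population subset).
#' @return D; NA when n < 4 or S = 0 (undefined, not zero).
#' @export
tajimasD <- function(x) {
  n <- nSeq(x)
  if (n < 4L) return(NA_real_)
  S <- segregatingSites(x)$S
  if (S == 0L) return(NA_real_)
  k <- meanPairwiseDiff(x)
  tajimaDFromSk(n, S, k)
}

tajimaDFromSk <- function(n, S, k) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log |s(n, k)| table (unsigned Stirling numbers of the first kind),
# computed in log space so n beyond ~60 does not overflow.
logStirlingFirst <- function(n) {
  L <- rep(-Inf, n)
  L[1] <- 0
  if (n == 1L) return(L)
  for (m in 2:n) {
    Lnew <- rep(-Inf, n)
    for (k in seq_len(m)) {
      terms <- c(if (k > 1) L[k - 1] else -Inf,
                 log(m - 1) + L[k])
      mx <- max(terms)
      Lnew[k] <- if (is.finite(mx)) mx + log(sum(exp(terms - mx))) else -Inf
    }
    L <- Lnew
  }
  L
}

# P(K = k | theta, n) under the Ewens sampling formula, log scale.
logEwensK <- function(n, theta, logStirling = logStirlingFirst(n)) {
  k <- seq_len(n)
  logStirling + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's Fs
#'
#' S' = P(K >= k_obs | theta = theta_pi) under the Ewens sampling formula
#' (computed from unsigned Stirling numbers of the first kind in log
#' space), with theta_pi the mean number of pairwise differences;
#' Fs = ln(S'/(1 - S')). Strongly negative values indicate an excess of
#' haplotypes relative to neutrality, as after a population expansion.
#'
#' @param x a HaplotypeDataset.
#' @return Fs; NA when the sample has a single haplotype or theta_pi = 0.
#' @export
fusFs <- function(x) {
  n <- nSeq(x)
  if (n < 3L) return(NA_real_)
  kObs <- length(unique(as.character(x@alignment)))
  theta <- meanPairwiseDiff(x)
  fuFsFromK(n, kObs, theta)
}

fuFsFromK <- function(n, kObs, theta, logStirling = logStirlingFirst(n)) {
  if (kObs <= 1L || !is.finite(theta) || theta <= 0) return(NA_real_)
  lp <- logEwensK(n, theta, logStirling)
  sPrime <- sum(exp(lp[kObs:n]))
  sPrime <- min(max(sPrime, .Machine$double.xmin), 1 - 1e-15)
  log(sPrime / (1 - sPrime))
}

#' Ramos-Onsins and Rozas' R2
#'
#' R2 = sqrt( mean_i (U_i - k/2)^2 ) / S with U_i the number of singleton
#' mutations carried by sequence i, k the mean number of pairwise
#' differences and S the number of segregating sites. Small values are
#' expected after population growth.
#'
#' @param x a HaplotypeDataset.
#' @return R2; NA when n < 3 or S = 0.
#' @export
rozasR2 <- function(x) {
  n <- nSeq(x)
  if (n < 3L) return(NA_real_)
  m <- alignmentMatrix(x)
  S <- 0L
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    use <- !(col %in% AMBIG)
    st <- unique(col[use])
    if (length(st) < 2L) next
    S <- S + 1L
    cnt <- table(col[use])
    for (s in names(cnt)[cnt == 1L]) {
      idx <- which(col == s & use)
      U[idx] <- U[idx] + 1
    }
  }
  if (S == 0L) return(NA_real_)
  k <- meanPairwiseDiff(x)
  sqrt(mean((U - k / 2)^2)) / S
}

# One neutral coalescent replicate conditioned on n and theta: returns
# c(S, pi, nHap). Branch lengths in coalescent units; mutations dropped on
# branches as Poisson(theta/2 * total length), infinite sites.
simNeutralConfig <- function(n, theta) {
  tipsets <- as.list(seq_len(n))
  lens <- numeric(n)
  branches <- list(); blens <- numeric(0)
  k <- n
  while (k > 1L) {
    dt <- rexp(1, k * (k - 1) / 2)
    lens <- lens + dt
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    branches <- c(branches, tipsets[i], tipsets[j])
    blens <- c(blens, lens[i], lens[j])
    tipsets[[i]] <- c(tipsets[[i]], tipsets[[j]])
    lens[i] <- 0
    tipsets[[j]] <- NULL
    lens <- lens[-j]
    k <- k - 1L
  }
  Ltot <- sum(blens)
  S <- rpois(1, theta / 2 * Ltot)
  if (S == 0L)
    return(list(S = 0L, pi = 0, nHap = 1L, U = numeric(n)))
  hit <- sample.int(length(blens), S, replace = TRUE, prob = blens)
  cs <- lengths(branches)[hit]
  pi <- sum(cs * (n - cs)) / choose(n, 2)
  key <- rep("", n)
  U <- numeric(n)
  for (b in hit) {
    ts <- branches[[b]]
    key[ts] <- paste0(key[ts], ",", b)
    if (length(ts) == 1L) U[ts] <- U[ts] + 1
    if (length(ts) == n - 1L) U[-ts] <- U[-ts] + 1
  }
  list(S = S, pi = pi, nHap = length(unique(key)), U = U)
}

#' Coalescent p-values for the neutrality statistics
#'
#' Simulates the standard neutral coalescent conditioned on the sample size
#' and theta = theta_pi (the observed mean number of pairwise differences)
#' and reports lower-tail p-values -- the conventional one-tailed usage for
#' detecting population expansion: p = fraction of simulated statistics at
#' most the observed one. Fu's Fs is conventionally called significant at
#' p < 0.02.
#'
#' @param x a HaplotypeDataset.
#' @param reps coalescent replicates (warning below 1000).
#' @param seed optional integer seed.
#' @return list with observed \code{D}, \code{Fs}, \code{R2} and p-values
#'   \code{pD}, \code{pFs}, \code{pR2}.
#' @export
neutralityPvalues <- function(x, reps = 10000, seed = NULL) {
  if (reps < 1000) warning("fewer than 1000 coalescent replicates")
  maybeSeed(seed)
  n <- nSeq(x)
  theta <- meanPairwiseDiff(x)
  obsD <- tajimasD(x); obsFs <- fusFs(x); obsR2 <- rozasR2(x)
  if (!is.finite(theta) || theta <= 0)
    stop("theta_pi = 0: neutrality statistics undefined")
  lst <- logStirlingFirst(n)
  simD <- simFs <- simR2 <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    cfg <- simNeutralConfig(n, theta)
    if (cfg$S > 0) {
      simD[r] <- tajimaDFromSk(n, cfg$S, cfg$pi)
      simR2[r] <- sqrt(mean((cfg$U - cfg$pi / 2)^2)) / cfg$S
    }
    simFs[r] <- fuFsFromK(n, cfg$nHap, cfg$pi, lst)
  }
  pv <- function(obs, sims) {
    sims <- sims[is.finite(sims)]
    if (!is.finite(obs) || !length(sims)) return(NA_real_)
    mean(sims <= obs)
  }
  list(D = obsD, Fs = obsFs, R2 = obsR2,
       pD = pv(obsD, simD), pFs = pv(obsFs, simFs),
       pR2 = pv(obsR2, simR2))
}

#' Neutrality summary per population
#'
#' Convenience wrapper running \code{\link{neutralityPvalues}} for each
#' locality (or pooled group) with enough data.
#'
#' @param x a HaplotypeDataset.
#' @param reps coalescent replicates per population.
#' @param seed optional integer seed.
#' @return data.frame with one row per population: n, S, D, pD, Fs, pFs,
#'   R2, pR2 (NA where a statistic is undefined).
#' @export
neutralityTable <- function(x, reps = 10000, seed = NULL) {
  maybeSeed(seed)
  pops <- popNames(x)
  rows <- lapply(pops, function(p) {
    sub <- subsetPops(x, p)
    n <- nSeq(sub)
    S <- if (n >= 2) segregatingSites(sub)$S else NA_integer_
    base <- data.frame(pop = p, n = n, S = S, D = NA_real_, pD = NA_real_,
                       Fs = NA_real_, pFs = NA_real_, R2 = NA_real_,
                       pR2 = NA_real_)
    if (!is.na(S) && S > 0 && n >= 4) {
      res <- neutralityPvalues(sub, reps = reps)
      base$D <- res$D; base$pD <- res$pD
      base$Fs <- res$Fs; base$pFs <- res$pFs
      base$R2 <- res$R2; base$pR2 <- res$pR2
    }
    base
  })
  do.call(rbind, rows)
}
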