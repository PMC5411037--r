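# Independent slow-path oracles and small fixture builders used across the
# test files. These deliberately avoid the package's internal code paths.

# Build a GenotypeDataset from a list pop -> list of c(a1, a2) per locus
# per individual: genotypes[[pop]][[ind]] is an L x 2 matrix.
makeGd <- function(genotypes, loci = NULL) {
  pops <- names(genotypes)
  rows <- list(); popv <- character(0)
  for (p in pops) for (ind in genotypes[[p]]) {
    rows[[length(rows) + 1L]] <- ind
    popv <- c(popv, p)
  }
  L <- nrow(rows[[1]])
  calls <- array(NA_integer_, c(length(rows), L, 2))
  for (i in seq_along(rows)) calls[i, , ] <- rows[[i]]
  genotypeDataset(calls, pop = popv, loci = loci)
}

# Random equal-length alignment: S biallelic sites, random carrier sets.
randomAlignment <- function(n, L = 40, S = 5, pops = "a") {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(base, each = n), nrow = n)
  sites <- sample(L, S)
  subs <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in sites) {
    carriers <- sample(n, sample(n - 1, 1))
    m[carriers, s] <- subs[[base[s]]]
  }
  seqs <- apply(m, 1, paste, collapse = "")
  haplotypeDataset(setNames(seqs, paste0("s", seq_len(n))),
                   pop = rep(pops, length.out = n))
}

# Brute-force nucleotide diversity: explicit double loop with pairwise
# deletion of N/- positions.
slowPi <- function(charMat) {
  n <- nrow(charMat)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- charMat[i, ]; b <- charMat[j, ]
    ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
    if (!any(ok)) next
    vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(vals)
}

slowMeanDiff <- function(charMat) {
  n <- nrow(charMat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(charMat[i, ] != charMat[j, ])
  tot / choose(n, 2)
}

# Tajima's D written out from its defining quantities.
slowTajimaD <- function(charMat) {
  n <- nrow(charMat)
  S <- sum(apply(charMat, 2, function(c) length(unique(c)) > 1))
  if (S == 0 || n < 4) return(NA_real_)
  k <- slowMeanDiff(charMat)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Exact unsigned Stirling numbers of the first kind via integer polynomial
# expansion of the rising factorial x(x+1)...(x+n-1); n <= 15 is exact in
# doubles here.
stirlingRow <- function(n) {
  coefs <- c(0, 1)  # polynomial x
  if (n >= 2) for (m in 1:(n - 1)) {
    # multiply by (x + m)
    shifted <- c(0, coefs)            # * x
    scaled <- c(coefs * m, 0)         # * m
    coefs <- shifted + scaled
  }
  coefs[2:(n + 1)]                    # |s(n, 1..n)|
}

# Fu's Fs via the Ewens sampling formula computed from the exact Stirling
# row.
slowFuFs <- function(charMat) {
  n <- nrow(charMat)
  k <- length(unique(apply(charMat, 1, paste, collapse = "")))
  theta <- slowMeanDiff(charMat)
  if (k <= 1 || theta <= 0) return(NA_real_)
  st <- stirlingRow(n)
  probs <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sPrime <- sum(probs[k:n])
  log(sPrime / (1 - sPrime))
}

# R2 by direct singleton counting.
slowR2 <- function(charMat) {
  n <- nrow(charMat)
  S <- 0; U <- numeric(n)
  for (j in seq_len(ncol(charMat))) {
    cnt <- table(charMat[, j])
    if (length(cnt) < 2) next
    S <- S + 1
    for (st in names(cnt)[cnt == 1])
      U[charMat[, j] == st] <- U[charMat[, j] == st] + 1
  }
  if (S == 0) return(NA_real_)
  k <- slowMeanDiff(charMat)
  sqrt(mean((U - k / 2)^2)) / S
}

# Two-level AMOVA oracle: sums of squares and expected-mean-square
# algebra written out directly on a squared-distance matrix.
slowAmova2 <- function(d2, pop) {
  pop <- as.character(pop)
  N <- nrow(d2); pops <- unique(pop); P <- length(pops)
  sstot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sstot <- sstot + d2[i, j]
  sstot <- sstot / N
  ssw <- 0
  np <- integer(P)
  for (q in seq_along(pops)) {
    idx <- which(pop == pops[q]); np[q] <- length(idx)
    s <- 0
    if (length(idx) > 1)
      for (i in idx) for (j in idx) if (i < j) s <- s + d2[i, j]
    ssw <- ssw + s / length(idx)
  }
  msw <- ssw / (N - P)
  msa <- (sstot - ssw) / (P - 1)
  n0 <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (msa - msw) / n0
  list(phiST = s2a / (s2a + msw), s2a = s2a, s2w = msw)
}

# Weir-Cockerham variance components written out literally for a single
# biallelic locus and two populations (scalar arithmetic).
slowWcThetaBiallelic <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2; acc <- c(0, 0, 0)
  for (al in 1:2) {
    pA <- if (al == 1) c(p1, p2) else c(1 - p1, 1 - p2)
    hA <- c(h1, h2)
    ni <- c(n1, n2)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pA) / (r * nbar)
    s2 <- sum(ni * (pA - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hA) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    acc <- acc + c(a, b, cc)
  }
  acc[1] / sum(acc)
}

# All perfect matchings of a gene vector (tiny sizes only): returns the
# exact conditional distribution of genotype tables given allele counts.
allPairings <- function(genes) {
  if (length(genes) == 0) return(list(list()))
  out <- list()
  first <- genes[1]
  rest <- genes[-1]
  for (i in seq_along(rest)) {
    pair <- sort(c(first, rest[i]))
    sub <- allPairings(rest[-i])
    for (s in sub) out[[length(out) + 1L]] <- c(list(pair), s)
  }
  out
}

# Exact two-sided HWE probability-test p-value by enumerating every
# pairing of the gene pool.
slowHweExact <- function(a1, a2) {
  genes <- c(a1, a2)
  matchings <- allPairings(genes)
  key <- function(pairs)
    paste(sort(vapply(pairs, paste, "", collapse = "/")), collapse = ";")
  obsKey <- key(lapply(seq_along(a1),
                       function(i) sort(c(a1[i], a2[i]))))
  keys <- vapply(matchings, key, "")
  tab <- table(keys)
  probs <- tab / length(matchings)
  pObs <- probs[[obsKey]]
  sum(probs[probs <= pObs + 1e-12])
}

# Fixture path helper
fixtureFasta <- function()
  system.file("extdata", "synthetic_coi_haplotypes.fasta",
              package = "bathypop")

basinGrouping <- function(x)
  sampleGrouping(popNames(x),
                 ifelse(grepl("^MED", popNames(x)), "MED", "ATL"))
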