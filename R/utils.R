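# Internal helpers shared across modules.

# Allele counts per population for one locus: matrix allele-code x pop.
lociAlleleCounts <- function(x) {
  pops <- levels(x@pop)
  lapply(seq_len(nLoci(x)), function(l) {
    a <- rbind(x@calls[, l, 1], x@calls[, l, 2])
    codes <- sort(unique(as.vector(a[!is.na(a)])))
    m <- sapply(pops, function(p) {
      v <- as.vector(a[, x@pop == p])
      tabulate(match(v[!is.na(v)], codes), nbins = length(codes))
    })
    m <- matrix(m, nrow = length(codes),
                dimnames = list(codes, pops))
    m
  })
}

# Scored diploid count per pop x locus.
scoredCounts <- function(x) {
  ok <- !is.na(x@calls[, , 1, drop = FALSE])
  dim(ok) <- dim(ok)[1:2]
  m <- t(sapply(levels(x@pop), function(p)
    colSums(ok[x@pop == p, , drop = FALSE])))
  matrix(m, nrow = nlevels(x@pop),
         dimnames = list(levels(x@pop), x@loci))
}

# Character matrix of an alignment restricted to unambiguous columns kept
# as-is; ambiguity handled by callers.
AMBIG <- c("N", "-")

# Pairwise difference counts with pairwise deletion. Returns list with
# matrices `diff` (sites differing) and `comp` (sites comparable).
pairwiseDiffs <- function(m) {
  n <- nrow(m)
  # restrict to candidate columns: any mismatch or ambiguity
  keep <- which(apply(m, 2, function(col) {
    u <- unique(col)
    length(u) > 1L || any(u %in% AMBIG)
  }))
  Lc <- ncol(m)
  d <- matrix(0, n, n); comp <- matrix(Lc, n, n)
  if (length(keep)) {
    sub <- m[, keep, drop = FALSE]
    ok <- !(sub == "N" | sub == "-")
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nd <- sum(sub[i, both] != sub[j, both])
      nc <- Lc - length(keep) + sum(both)
      d[i, j] <- d[j, i] <- nd
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  diag(comp) <- Lc
  list(diff = d, comp = comp)
}

# Unbiased haplotype/gene diversity from a count vector.
unbiasedDiversity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  (n / (n - 1)) * (1 - sum((counts / n)^2))
}

# BH-FDR star codes over a family of p-values at several alpha levels.
fdrStars <- function(p, alphaLevels = c(0.05, 0.01, 0.001)) {
  padj <- p.adjust(p, method = "BH")
  stars <- character(length(p))
  als <- sort(alphaLevels, decreasing = TRUE)
  for (k in seq_along(als))
    stars[!is.na(padj) & padj < als[k]] <- strrep("*", k)
  list(padj = padj, stars = stars)
}

# Permutation p-value with the observed value counted once.
permPValue <- function(obs, sims, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  hits <- if (tail == "ge") sum(sims >= obs) else sum(sims <= obs)
  (1 + hits) / (1 + length(sims))
}

maybeSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
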