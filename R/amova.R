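# Three-level AMOVA machinery. Entities are sequences (mtDNA, squared
# distance = pairwise difference count) or gene copies (microsatellites,
# allele non-identity distance, closed-form sums of squares from counts).

amova3FromDist <- function(d2, pop, group) {
  pop <- droplevels(pop)
  N <- nrow(d2); P <- nlevels(pop)
  grp <- factor(group[as.character(pop)])
  G <- nlevels(grp)
  lt <- function(m) m[lower.tri(m)]
  ssT <- sum(lt(d2)) / N
  ssWP <- 0; ssWG <- 0
  for (p in levels(pop)) {
    idx <- which(pop == p)
    ssWP <- ssWP + sum(lt(d2[idx, idx, drop = FALSE])) / length(idx)
  }
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ssWG <- ssWG + sum(lt(d2[idx, idx, drop = FALSE])) / length(idx)
  }
  np <- as.vector(table(pop))
  Ng <- as.vector(table(grp))
  popGroup <- tapply(as.character(grp), pop, `[`, 1)
  sumNp2overNg <- sum(vapply(levels(grp), function(g) {
    sum(np[popGroup == g]^2) / sum(np[popGroup == g])
  }, 0))
  ss <- c(amongGroups = ssT - ssWG, amongPops = ssWG - ssWP,
          within = ssWP)
  df <- c(amongGroups = G - 1, amongPops = P - G, within = N - P)
  s2c <- ss["within"] / df["within"]
  n1 <- (N - sumNp2overNg) / (P - G)
  s2b <- (ss["amongPops"] / df["amongPops"] - s2c) / n1
  n2 <- (sumNp2overNg - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  s2a <- (ss["amongGroups"] / df["amongGroups"] - s2c - n2 * s2b) / n3
  sigma2 <- setNames(as.numeric(c(s2a, s2b, s2c)),
                     c("amongGroups", "amongPopsWithinGroups",
                       "withinPops"))
  tot <- sum(sigma2)
  phi <- c(FCT = sigma2[[1]] / tot,
           FSC = sigma2[[2]] / (sigma2[[2]] + sigma2[[3]]),
           FST = (sigma2[[1]] + sigma2[[2]]) / tot)
  list(df = df, ss = ss, sigma2 = sigma2, phi = phi)
}

# SSD building blocks for 0/1 gene distances from allele counts:
# sum over pairs within a set of n genes with counts c_a, divided by n.
ssdFromCounts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  (n^2 - sum(cnt^2)) / (2 * n)
}

amova3FromGenotypes <- function(calls, pop, group) {
  pop <- droplevels(pop)
  L <- dim(calls)[2]
  sigma2 <- c(0, 0, 0); dfs <- c(0, 0, 0); sss <- c(0, 0, 0)
  for (l in seq_len(L)) {
    a <- rbind(calls[, l, 1], calls[, l, 2])
    ok <- !is.na(a[1, ])
    genes <- c(a[1, ok], a[2, ok])
    gpop <- droplevels(rep(pop[ok], 2L))
    ggrp <- factor(unname(group[as.character(gpop)]))
    P <- nlevels(gpop); G <- nlevels(ggrp)
    codes <- unique(genes)
    N <- length(genes)
    cntTot <- tabulate(match(genes, codes), length(codes))
    ssT <- ssdFromCounts(cntTot)
    ssWP <- sum(vapply(levels(gpop), function(p)
      ssdFromCounts(tabulate(match(genes[gpop == p], codes),
                             length(codes))), 0))
    ssWG <- sum(vapply(levels(ggrp), function(g)
      ssdFromCounts(tabulate(match(genes[ggrp == g], codes),
                             length(codes))), 0))
    np <- as.vector(table(gpop)); Ng <- as.vector(table(ggrp))
    popGroup <- tapply(as.character(ggrp), gpop, `[`, 1)
    sumNp2overNg <- sum(vapply(levels(ggrp), function(g) {
      sum(np[popGroup == g]^2) / sum(np[popGroup == g])
    }, 0))
    ss <- c(ssT - ssWG, ssWG - ssWP, ssWP)
    df <- c(G - 1, P - G, N - P)
    if (df[1] <= 0 || df[3] <= 0) next
    s2c <- ss[3] / df[3]
    if (df[2] > 0) {
      n1 <- (N - sumNp2overNg) / df[2]
      s2b <- (ss[2] / df[2] - s2c) / n1
    } else s2b <- 0
    n2 <- (sumNp2overNg - sum(np^2) / N) / df[1]
    n3 <- (N - sum(Ng^2) / N) / df[1]
    s2a <- (ss[1] / df[1] - s2c - n2 * s2b) / n3
    sigma2 <- sigma2 + c(s2a, s2b, s2c)
    dfs <- dfs + df; sss <- sss + ss
  }
  names(sigma2) <- c("amongGroups", "amongPopsWithinGroups", "withinPops")
  names(dfs) <- names(sss) <- names(sigma2)
  tot <- sum(sigma2)
  phi <- c(FCT = sigma2[[1]] / tot,
           FSC = sigma2[[2]] / (sigma2[[2]] + sigma2[[3]]),
           FST = (sigma2[[1]] + sigma2[[2]]) / tot)
  list(df = dfs, ss = sss, sigma2 = sigma2, phi = phi)
}

amova2FromGenotypes <- function(calls, pop) {
  pop <- droplevels(pop)
  L <- dim(calls)[2]
  sigma2 <- c(0, 0); dfs <- c(0, 0); sss <- c(0, 0)
  for (l in seq_len(L)) {
    a <- rbind(calls[, l, 1], calls[, l, 2])
    ok <- !is.na(a[1, ])
    genes <- c(a[1, ok], a[2, ok])
    gpop <- droplevels(rep(pop[ok], 2L))
    P <- nlevels(gpop); N <- length(genes)
    if (P < 2L || N <= P) next
    codes <- unique(genes)
    ssT <- ssdFromCounts(tabulate(match(genes, codes), length(codes)))
    ssWP <- sum(vapply(levels(gpop), function(p)
      ssdFromCounts(tabulate(match(genes[gpop == p], codes),
                             length(codes))), 0))
    np <- as.vector(table(gpop))
    s2w <- ssWP / (N - P)
    nprime <- (N - sum(np^2) / N) / (P - 1)
    s2a <- ((ssT - ssWP) / (P - 1) - s2w) / nprime
    sigma2 <- sigma2 + c(s2a, s2w)
    dfs <- dfs + c(P - 1, N - P); sss <- sss + c(ssT - ssWP, ssWP)
  }
  names(sigma2) <- names(dfs) <- names(sss) <- c("amongPops", "withinPops")
  list(df = dfs, ss = sss, sigma2 = sigma2,
       phi = c(FST = sigma2[[1]] / sum(sigma2)))
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions genetic variance among groups of localities, among localities
#' within groups, and within localities, from pairwise distances: squared
#' distance = number of nucleotide differences for sequence data, allele
#' non-identity at the gene-copy level for microsatellites (components
#' summed over loci). Components are reported even when negative.
#' Permutation p-values: localities are permuted among groups for F_CT;
#' individuals among localities within their group for F_SC; individuals
#' among all localities for F_ST.
#'
#' @param x a GenotypeDataset or HaplotypeDataset.
#' @param grouping named character locality -> group (see
#'   \code{\link{sampleGrouping}}); with one group per locality a two-level
#'   analysis among localities is returned (F_ST only).
#' @param nPerm permutations per index (0 to skip tests).
#' @param seed optional integer seed.
#' @return an \linkS4class{AmovaResult}.
#' @export
amova <- function(x, grouping, nPerm = 1000, seed = NULL) {
  grouping <- validateGrouping(x, grouping)
  pop <- x@pop
  G <- length(unique(grouping))
  P <- nlevels(pop)
  if (G < 2L) stop("need at least two groups")
  singletons <- names(table(grouping))[table(grouping) == 1]
  if (length(singletons) && G < P)
    message("group(s) with a single locality: ",
            paste(singletons, collapse = ", "))
  maybeSeed(seed)
  isSeq <- is(x, "HaplotypeDataset")
  if (isSeq) {
    d2 <- pairwiseDiffs(alignmentMatrix(x))$diff
    evalFull <- function(popf, grp) amova3FromDist(d2, popf, grp)
  } else {
    evalFull <- function(popf, grp) amova3FromGenotypes(x@calls, popf, grp)
  }
  if (G == P) {
    # two-level analysis among localities
    if (isSeq) {
      res <- amovaDistTwoLevel(d2, pop)
      phi <- c(FST = res$phiST)
      sigma2 <- c(amongPops = res$sigma2[["among"]],
                  withinPops = res$sigma2[["within"]])
      df <- res$df; ss <- res$ss[c("among", "within")]
      stat <- function(popf) amovaDistTwoLevel(d2, popf)$phiST
    } else {
      res <- amova2FromGenotypes(x@calls, pop)
      phi <- res$phi
      sigma2 <- res$sigma2
      df <- res$df; ss <- res$ss
      stat <- function(popf)
        amova2FromGenotypes(x@calls, popf)$phi[["FST"]]
    }
    p <- NA_real_
    if (nPerm > 0) {
      sims <- replicate(nPerm, stat(sample(pop)))
      p <- permPValue(phi[["FST"]], sims, "ge")
    }
    return(new("AmovaResult", df = df, ss = ss, sigma2 = sigma2,
               phi = phi, pValues = c(FST = p), grouping = grouping,
               nPerm = nPerm))
  }
  res <- evalFull(pop, grouping)
  pv <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
  if (nPerm > 0) {
    # F_CT: permute localities among groups
    simsCT <- replicate(nPerm, {
      g2 <- setNames(sample(unname(grouping)), names(grouping))
      evalFull(pop, g2)$phi[["FCT"]]
    })
    pv["FCT"] <- permPValue(res$phi[["FCT"]], simsCT, "ge")
    # F_SC: permute individuals among localities within their group
    grpOfInd <- unname(grouping[as.character(pop)])
    simsSC <- replicate(nPerm, {
      popf <- pop
      for (g in unique(grpOfInd)) {
        idx <- which(grpOfInd == g)
        popf[idx] <- sample(pop[idx])
      }
      evalFull(popf, grouping)$phi[["FSC"]]
    })
    pv["FSC"] <- permPValue(res$phi[["FSC"]], simsSC, "ge")
    # F_ST: permute individuals among all localities
    simsST <- replicate(nPerm, evalFull(sample(pop), grouping)$phi[["FST"]])
    pv["FST"] <- permPValue(res$phi[["FST"]], simsST, "ge")
  }
  new("AmovaResult", df = res$df, ss = res$ss, sigma2 = res$sigma2,
      phi = res$phi, pValues = pv, grouping = grouping, nPerm = nPerm)
}

#' Search over candidate groupings by AMOVA
#'
#' Runs the hierarchical AMOVA for every candidate locality grouping and
#' ranks them by F_CT (descending) with F_SC (ascending) as tie-break --
#' the optimal grouping maximizes the among-group variance fraction.
#'
#' @param x a GenotypeDataset or HaplotypeDataset.
#' @param candidates named list of groupings (named character vectors).
#' @param nPerm permutations per candidate (0 for a ranking-only search).
#' @param seed optional integer seed.
#' @return list with \code{ranking} (data.frame candidate, FCT, FSC, FST,
#'   ordered best first) and \code{results} (AmovaResult per candidate).
#' @export
groupingSearch <- function(x, candidates, nPerm = 0, seed = NULL) {
  if (length(candidates) < 2L) stop("need at least two candidates")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("grouping", seq_along(candidates))
  maybeSeed(seed)
  results <- lapply(candidates, function(g) amova(x, g, nPerm = nPerm))
  tab <- data.frame(
    candidate = names(candidates),
    FCT = vapply(results, function(r)
      if ("FCT" %in% names(r@phi)) r@phi[["FCT"]] else NA_real_, 0),
    FSC = vapply(results, function(r)
      if ("FSC" %in% names(r@phi)) r@phi[["FSC"]] else NA_real_, 0),
    FST = vapply(results, function(r) r@phi[["FST"]], 0),
    row.names = NULL)
  ord <- order(-tab$FCT, tab$FSC)
  list(ranking = tab[ord, ], results = results)
}
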