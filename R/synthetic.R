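#' Configuration for the study-like synthetic dataset
#'
#' Describes a six-locality, two-basin sampling layout mirroring the
#' Atlantic-Mediterranean study design: four Atlantic localities (three
#' Mid-Atlantic Ridge sections and Rockall) and two Mediterranean ones,
#' with the published genotyped and sequenced sample sizes as defaults.
#' The mitochondrial side is an explicit haplotype-frequency design (two
#' haplogroups separated by one transition step at \code{splitPosition},
#' one dominant haplotype per basin, per-locality counts chosen to
#' reproduce the published per-locality haplotype diversities); the
#' nuclear side is simulated with the two-population coalescent and
#' calibrated to the target between-basin FST.
#'
#' @param localities locality names.
#' @param basin basin label per locality ("ATL"/"MED").
#' @param nGenotyped diploid microsatellite sample sizes per locality.
#' @param nSequenced mtDNA sample sizes per locality.
#' @param nLoci number of microsatellite loci.
#' @param targetFst target between-basin multilocus FST (nuclear).
#' @param fstTolerance relative tolerance for the calibration (0.3 =
#'   within 30 percent of target).
#' @param seqLen mtDNA sequence length (bp).
#' @param splitPosition alignment position of the basin-splitting
#'   transition (1-based).
#' @param substructureAtlantic keep the within-Atlantic mtDNA
#'   substructure (northern MAR1/ROC versus southern MAR2/MAR3); when
#'   FALSE all Atlantic localities share one composition with the
#'   dominant haplotype at \code{dominantAtl}.
#' @param dominantAtl,dominantMed dominant-haplotype fractions used when
#'   \code{substructureAtlantic = FALSE} (and for the MED side always
#'   approximately realized by the default tables).
#' @param missingRate fraction of genotype calls set missing.
#' @param seed integer seed for the whole generation.
#' @return list of class "studyMimicConfig".
#' @export
studyMimicConfig <- function(localities = c("MAR1", "MAR2", "MAR3",
                                            "ROC", "MED1", "MED2"),
                             basin = c("ATL", "ATL", "ATL", "ATL",
                                       "MED", "MED"),
                             nGenotyped = c(61, 13, 72, 132, 78, 19),
                             nSequenced = c(30, 10, 38, 49, 48, 18),
                             nLoci = 9, targetFst = 0.02,
                             fstTolerance = 0.3, seqLen = 613,
                             splitPosition = 91,
                             substructureAtlantic = TRUE,
                             dominantAtl = 0.82, dominantMed = 0.74,
                             missingRate = 0.01, seed = 20170501) {
  stopifnot(length(basin) == length(localities),
            length(nGenotyped) == length(localities),
            length(nSequenced) == length(localities),
            all(nGenotyped > 0), dominantAtl > 0, dominantAtl < 1,
            dominantMed > 0, dominantMed < 1)
  structure(list(localities = localities,
                 basin = setNames(basin, localities),
                 nGenotyped = setNames(nGenotyped, localities),
                 nSequenced = setNames(nSequenced, localities),
                 nLoci = nLoci, targetFst = targetFst,
                 fstTolerance = fstTolerance, seqLen = seqLen,
                 splitPosition = splitPosition,
                 substructureAtlantic = substructureAtlantic,
                 dominantAtl = dominantAtl, dominantMed = dominantMed,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "studyMimicConfig")
}

# Ten-haplotype design over 11 variable sites: the Atlantic haplogroup
# (H1-H6, H2 dominant) and the Mediterranean one (H7-H10, H8 dominant)
# differ by exactly one transition (A<->G) at the split position; the
# remaining ten mutations are private derivations (8 transitions, 2
# transversions), nested so the unweighted inter-group mean distance is
# 3.25 steps (~0.53 percent of 613 bp).
studyHaplotypeDesign <- function(seqLen = 613, splitPosition = 91,
                                 seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), seqLen, replace = TRUE)
  sitePool <- setdiff(round(seq(20, seqLen - 20, length.out = 30)),
                      splitPosition)
  sites <- sitePool[seq(1, 28, by = 3)][1:10]
  base[splitPosition] <- "A"
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- c(A = "C", G = "T", C = "A", T = "G")
  mut <- function(s, pos, kind) {
    s[pos] <- if (kind == "ts") ts[[s[pos]]] else tv[[s[pos]]]
    s
  }
  H2 <- base
  H8 <- mut(H2, splitPosition, "ts")
  H3 <- mut(H2, sites[1], "ts")
  H6 <- mut(H2, sites[2], "ts")
  H1 <- mut(mut(H2, sites[3], "ts"), sites[4], "ts")
  H4 <- mut(H1, sites[5], "ts")
  H5 <- mut(mut(H2, sites[6], "ts"), sites[7], "tv")
  H7 <- mut(H8, sites[8], "ts")
  H9 <- mut(H8, sites[9], "ts")
  H10 <- mut(H8, sites[10], "tv")
  seqs <- vapply(list(H1 = H1, H2 = H2, H3 = H3, H4 = H4, H5 = H5,
                      H6 = H6, H7 = H7, H8 = H8, H9 = H9, H10 = H10),
                 paste, "", collapse = "")
  list(sequences = seqs,
       groups = setNames(rep(c("ATL", "MED"), c(6, 4)), names(seqs)))
}

# Default per-locality haplotype counts (substructured Atlantic):
# reproduce the published per-locality (Hn, Hd) pattern.
studyHaplotypeCounts <- function() {
  m <- matrix(0L, 10, 6,
              dimnames = list(paste0("H", 1:10),
                              c("MAR1", "MAR2", "MAR3", "ROC",
                                "MED1", "MED2")))
  m["H2", "MAR1"] <- 30
  m[c("H1", "H2", "H5"), "MAR2"] <- c(6, 3, 1)
  m[c("H1", "H2", "H4"), "MAR3"] <- c(22, 14, 2)
  m[c("H2", "H3", "H6"), "ROC"] <- c(46, 2, 1)
  m[c("H8", "H7", "H9"), "MED1"] <- c(34, 13, 1)
  m[c("H8", "H7", "H10"), "MED2"] <- c(15, 2, 1)
  m
}

roundCounts <- function(fracs, n) {
  cnt <- floor(fracs * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(fracs * n - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  cnt
}

#' Generate a study-like synthetic dataset with known truth
#'
#' Produces a six-locality GenotypeDataset and HaplotypeDataset that mimic
#' the study's observed structure: strong between-basin mitochondrial
#' differentiation with no shared haplotypes and a single-step
#' inter-basin connection, within-Atlantic mtDNA substructure (optional),
#' weak but real between-basin nuclear differentiation (coalescent
#' calibrated to the target FST within the stated tolerance) and
#' near-zero within-basin nuclear structure (localities are random
#' partitions of their basin's panmictic sample). The truth record stores
#' every generating parameter.
#'
#' @param config a \code{\link{studyMimicConfig}}.
#' @return list with \code{gen}, \code{seqs}, \code{truth}.
#' @export
generateStudyLikeDataset <- function(config = studyMimicConfig()) {
  set.seed(config$seed)
  locs <- config$localities
  basin <- config$basin
  # ---- mtDNA: explicit haplotype design --------------------------------
  des <- studyHaplotypeDesign(config$seqLen, config$splitPosition,
                              seed = config$seed)
  if (config$substructureAtlantic) {
    cnts <- studyHaplotypeCounts()[, locs, drop = FALSE]
    # rescale to requested sample sizes if they differ from the defaults
    for (j in seq_along(locs)) {
      n <- config$nSequenced[j]
      if (sum(cnts[, j]) != n)
        cnts[, j] <- roundCounts(cnts[, j] / sum(cnts[, j]), n)
    }
  } else {
    fa <- c(H1 = (1 - config$dominantAtl) * 0.55,
            H2 = config$dominantAtl,
            H3 = (1 - config$dominantAtl) * 0.25,
            H5 = (1 - config$dominantAtl) * 0.12,
            H6 = (1 - config$dominantAtl) * 0.08)
    fm <- c(H7 = (1 - config$dominantMed) * 0.75,
            H8 = config$dominantMed,
            H9 = (1 - config$dominantMed) * 0.15,
            H10 = (1 - config$dominantMed) * 0.10)
    cnts <- matrix(0L, 10, length(locs),
                   dimnames = list(paste0("H", 1:10), locs))
    for (j in seq_along(locs)) {
      f <- if (basin[j] == "ATL") fa else fm
      cnts[names(f), j] <- roundCounts(f / sum(f), config$nSequenced[j])
    }
  }
  seqv <- character(0); seqpop <- character(0)
  for (j in seq_along(locs)) for (h in rownames(cnts)) {
    k <- cnts[h, j]
    if (k > 0) {
      seqv <- c(seqv, rep(des$sequences[h], k))
      seqpop <- c(seqpop, rep(locs[j], k))
    }
  }
  names(seqv) <- paste0(seqpop, "_", seq_along(seqv))
  ord <- order(match(seqpop, locs))
  seqs <- haplotypeDataset(seqv[ord], pop = seqpop[ord])
  # ---- nuclear: calibrated two-population coalescent -------------------
  N <- 5000
  nATL <- sum(config$nGenotyped[basin == "ATL"])
  nMED <- sum(config$nGenotyped[basin == "MED"])
  thetaTargets <- exp(seq(log(0.08), log(100),
                          length.out = config$nLoci))
  muL <- thetaTargets / (4 * N)
  t <- -2 * N * log(1 - config$targetFst)
  realized <- NA_real_
  for (try in 1:6) {
    draw <- list(scenario = 1L, NATL = N, NMED = N, NbATL = N,
                 NbMED = N, t = t, t1 = t / 2, Nanc = N,
                 muMsatMean = mean(muL), muMsat = muL, muMt = 2e-8)
    sim <- simulateScenario(draw, nATL = nATL, nMED = nMED, mtATL = 5,
                            mtMED = 5, seqLen = 20)
    realized <- fstWeirCockerham(sim$gen)$theta
    if (is.finite(realized) &&
        abs(realized - config$targetFst) <=
          config$fstTolerance * config$targetFst) break
    if (!is.finite(realized) || realized <= 0) { t <- t * 2; next }
    t <- t * config$targetFst / realized
  }
  if (!is.finite(realized) ||
      abs(realized - config$targetFst) >
        config$fstTolerance * config$targetFst)
    stop("could not calibrate nuclear FST to ", config$targetFst,
         "; consider larger samples or a larger targetFst")
  # partition basin samples into localities (panmictic within basin)
  calls <- alleleCalls(sim$gen)
  popLabels <- character(nATL + nMED)
  atlLocs <- locs[basin == "ATL"]; medLocs <- locs[basin == "MED"]
  popLabels[seq_len(nATL)] <-
    sample(rep(atlLocs, config$nGenotyped[atlLocs]))
  popLabels[nATL + seq_len(nMED)] <-
    sample(rep(medLocs, config$nGenotyped[medLocs]))
  if (config$missingRate > 0) {
    nCell <- dim(calls)[1] * dim(calls)[2]
    miss <- which(runif(nCell) < config$missingRate)
    for (m in miss) {
      i <- ((m - 1) %% dim(calls)[1]) + 1
      l <- ((m - 1) %/% dim(calls)[1]) + 1
      calls[i, l, ] <- NA_integer_
    }
  }
  ordId <- order(match(popLabels, locs))
  gen <- genotypeDataset(calls[ordId, , , drop = FALSE],
                         pop = popLabels[ordId],
                         loci = paste0("loc", seq_len(config$nLoci)))
  truth <- list(config = config, hapCounts = cnts,
                hapGroups = des$groups,
                hapSequences = des$sequences,
                nuclear = list(N = N, t = t, mu = muL,
                               realizedFst = realized),
                dominantAtl = sum(cnts["H2", basin == "ATL"]) /
                  sum(cnts[, basin == "ATL"]),
                dominantMed = sum(cnts["H8", basin == "MED"]) /
                  sum(cnts[, basin == "MED"]))
  list(gen = gen, seqs = seqs, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the genepop genotype file, the FASTA alignment and a JSON truth
#' record into a directory.
#'
#' @param sim output of \code{\link{generateStudyLikeDataset}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeStudyLikeDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "genotypes.genepop.txt")
  fa <- file.path(dir, "haplotypes.fasta")
  tj <- file.path(dir, "truth.json")
  writeGenepop(sim$gen, gp, title = "synthetic study-like genotypes")
  writeFastaAlignment(sim$seqs, fa)
  truth <- sim$truth
  truth$hapCounts <- as.data.frame(truth$hapCounts)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(genepop = gp, fasta = fa, truth = tj))
}
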