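#' Constructors for the core data containers
#'
#' \code{genotypeDataset} builds a \linkS4class{GenotypeDataset} from an
#' allele-call array; \code{haplotypeDataset} builds a
#' \linkS4class{HaplotypeDataset} from sequences and locality labels.
#'
#' @param calls integer array n x L x 2 of allele codes, NA for missing.
#' @param pop locality label per individual/sequence (coerced to factor;
#'   level order follows first appearance).
#' @param ids individual ids (defaults to ind1..indN).
#' @param loci locus names (defaults to L1..LL).
#' @return A validated S4 object.
#' @examples
#' calls <- array(c(101L, 101L, 103L, 105L), dim = c(2, 1, 2))
#' gd <- genotypeDataset(calls, pop = c("A", "A"))
#' nInd(gd)
#' @export
genotypeDataset <- function(calls, pop, ids = NULL, loci = NULL) {
  storage.mode(calls) <- "integer"
  n <- dim(calls)[1]; L <- dim(calls)[2]
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  pop <- factor(pop, levels = unique(as.character(pop)))
  new("GenotypeDataset", ids = as.character(ids), pop = pop,
      loci = as.character(loci), calls = calls)
}

#' @rdname genotypeDataset
#' @param sequences a \code{DNAStringSet} or named character vector of
#'   equal-length sequences (lowercase normalized to uppercase).
#' @export
haplotypeDataset <- function(sequences, pop) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  pop <- factor(pop, levels = unique(as.character(pop)))
  new("HaplotypeDataset", alignment = sequences, pop = pop)
}

#' Accessors for bathypop containers
#'
#' Dimension, label and content accessors for the S4 containers; use these
#' instead of direct slot access.
#'
#' @param x a bathypop S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nInd", "GenotypeDataset", function(x) dim(x@calls)[1])
#' @rdname accessors
#' @export
setMethod("nLoci", "GenotypeDataset", function(x) dim(x@calls)[2])
#' @rdname accessors
#' @export
setMethod("lociNames", "GenotypeDataset", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("populations", "GenotypeDataset", function(x) x@pop)
#' @rdname accessors
#' @export
setMethod("popNames", "GenotypeDataset", function(x) levels(x@pop))
#' @rdname accessors
#' @export
setMethod("populations", "HaplotypeDataset", function(x) x@pop)
#' @rdname accessors
#' @export
setMethod("popNames", "HaplotypeDataset", function(x) levels(x@pop))
#' @rdname accessors
#' @export
setMethod("nSeq", "HaplotypeDataset", function(x) length(x@alignment))
#' @rdname accessors
#' @export
setMethod("seqLength", "HaplotypeDataset",
          function(x) Biostrings::width(x@alignment)[1])
#' @rdname accessors
#' @export
setMethod("statMatrix", "PairwiseStatMatrix", function(x) x@stat)
#' @rdname accessors
#' @export
setMethod("pValues", "PairwiseStatMatrix", function(x) x@pValues)
#' @rdname accessors
#' @export
setMethod("fixationIndices", "AmovaResult", function(x) x@phi)
#' @rdname accessors
#' @export
setMethod("varianceComponents", "AmovaResult", function(x) x@sigma2)
#' @rdname accessors
#' @export
setMethod("pValues", "AmovaResult", function(x) x@pValues)

#' Extract allele calls
#'
#' Returns the raw n x L x 2 integer call array of a GenotypeDataset.
#' @param x a GenotypeDataset.
#' @return integer array.
#' @export
alleleCalls <- function(x) x@calls

#' Alignment as a character matrix
#'
#' One row per sequence, one column per site, uppercase letters.
#' @param x a HaplotypeDataset.
#' @return character matrix.
#' @export
alignmentMatrix <- function(x) {
  m <- as.matrix(x@alignment)
  rownames(m) <- names(x@alignment)
  m
}

#' Subset a dataset to one or more localities
#'
#' @param x a GenotypeDataset or HaplotypeDataset.
#' @param pops locality labels to keep.
#' @return object of the same class.
#' @export
subsetPops <- function(x, pops) {
  keep <- as.character(x@pop) %in% pops
  if (!any(keep)) stop("no individuals in the requested localities")
  if (is(x, "GenotypeDataset")) {
    genotypeDataset(x@calls[keep, , , drop = FALSE],
                    pop = as.character(x@pop)[keep],
                    ids = x@ids[keep], loci = x@loci)
  } else {
    haplotypeDataset(x@alignment[keep], pop = as.character(x@pop)[keep])
  }
}

#' Pool localities into groups
#'
#' Relabels individuals by the group of their locality, e.g. to merge
#' basin-level samples before diversity or neutrality analyses.
#' @param x a GenotypeDataset or HaplotypeDataset.
#' @param grouping named character: locality -> group.
#' @return object of the same class with group labels as populations.
#' @export
poolPops <- function(x, grouping) {
  grouping <- validateGrouping(x, grouping)
  newpop <- unname(grouping[as.character(x@pop)])
  if (is(x, "GenotypeDataset")) {
    genotypeDataset(x@calls, pop = newpop, ids = x@ids, loci = x@loci)
  } else {
    haplotypeDataset(x@alignment, pop = newpop)
  }
}

#' Build a locality-to-group mapping
#'
#' @param localities character vector of locality labels.
#' @param groups character vector (same length) of group labels.
#' @return named character vector usable wherever a grouping is expected.
#' @export
sampleGrouping <- function(localities, groups) {
  if (length(localities) != length(groups))
    stop("localities and groups must have the same length")
  if (anyDuplicated(localities))
    stop("each locality must appear exactly once")
  setNames(as.character(groups), as.character(localities))
}

validateGrouping <- function(x, grouping) {
  pops <- levels(x@pop)
  if (is.null(names(grouping)))
    stop("grouping must be a named character vector (locality -> group)")
  miss <- setdiff(pops, names(grouping))
  if (length(miss))
    stop("grouping misses localities: ", paste(miss, collapse = ", "))
  grouping[pops]
}

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nInd(object), "diploid individuals,",
      nLoci(object), "loci,", nlevels(object@pop), "localities\n")
  tab <- table(object@pop)
  cat("  localities:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(object@calls[, , 1]))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})

setMethod("show", "HaplotypeDataset", function(object) {
  cat("HaplotypeDataset:", nSeq(object), "sequences of",
      seqLength(object), "bp,", nlevels(object@pop), "localities\n")
  tab <- table(object@pop)
  cat("  localities:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PairwiseStatMatrix", function(object) {
  cat("PairwiseStatMatrix (", object@statName, "), ",
      length(object@labels), " units, ", object@nPerm,
      " permutations\n", sep = "")
  m <- round(object@stat, 4)
  m[upper.tri(m, diag = TRUE)] <- NA
  disp <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  lt <- lower.tri(m)
  disp[lt] <- paste0(format(m[lt]), object@signifCodes[lt])
  print(as.data.frame(disp), right = TRUE)
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", length(object@sigma2), "-level), ", object@nPerm,
      " permutations\n", sep = "")
  print(data.frame(df = object@df, SS = round(object@ss, 3),
                   row.names = names(object@df)))
  cat("variance components:\n")
  print(round(object@sigma2, 5))
  cat("fixation indices:\n")
  out <- rbind(value = round(object@phi, 4),
               p = round(object@pValues[names(object@phi)], 4))
  print(out)
})

setMethod("show", "HaploNetwork", function(object) {
  nm <- sum(object@nodes$type == "median")
  cat("Median-joining network:", nrow(object@nodes), "nodes (", nm,
      "median vectors ),", nrow(object@edges), "edges, total length",
      sum(object@edges$steps), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  chg <- c("no size change", "MED size change", "ATL size change",
           "ATL+MED size change")[object@scenario]
  cat("ScenarioSpec", object@scenario, "-", chg, "\n")
  for (nm in names(object@priors))
    cat(sprintf("  %-6s U(%g, %g)\n", nm, object@priors[[nm]][1],
                object@priors[[nm]][2]))
  cat(sprintf("  msat mean rate U(%g, %g); mtDNA rate U(%g, %g)\n",
              object@muMsatPrior[1], object@muMsatPrior[2],
              object@muMtPrior[1], object@muMtPrior[2]))
})

setMethod("show", "ReferenceTable", function(object) {
  cat("ABC ReferenceTable:", length(object@scenario), "rows,",
      ncol(object@stats), "summary statistics\n")
  print(table(scenario = object@scenario))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("ABC posterior (scenario ", object@scenario, ", ", object@method,
      ", ", nrow(object@draws), " retained draws)\n", sep = "")
  print(signif(as.matrix(object@summary), 3))
})
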