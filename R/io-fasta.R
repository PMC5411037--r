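#' Read an aligned FASTA file into a HaplotypeDataset
#'
#' Records must be of equal length (an alignment). Locality labels are
#' taken from a regular expression applied to the record names (first
#' capture group) or from an explicit id -> locality side table; with
#' neither, all sequences get the label \code{"all"}. Lowercase input is
#' normalized to uppercase.
#'
#' @param file path to a FASTA file, or a character vector of FASTA lines.
#' @param popPattern regex with one capture group extracting the locality
#'   from each record name, e.g. \code{"^([A-Z0-9]+)_"}.
#' @param popMap named character vector mapping record names to localities
#'   (overrides \code{popPattern}).
#' @return a \linkS4class{HaplotypeDataset}.
#' @export
readFastaAlignment <- function(file, popPattern = NULL, popMap = NULL) {
  if (length(file) > 1L || grepl("\n", file[1], fixed = TRUE) ||
      startsWith(trimws(file[1]), ">")) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), tmp)
    file <- tmp
  }
  seqs <- Biostrings::readDNAStringSet(file)
  if (!length(seqs)) stop("FASTA format error: no records")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  nm <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- nm
  if (!is.null(popMap)) {
    miss <- setdiff(nm, names(popMap))
    if (length(miss))
      stop("popMap misses ids: ", paste(head(miss, 5), collapse = ", "))
    pop <- unname(popMap[nm])
  } else if (!is.null(popPattern)) {
    m <- regmatches(nm, regexec(popPattern, nm))
    if (any(lengths(m) < 2L))
      stop("popPattern does not match all record names")
    pop <- vapply(m, `[`, "", 2L)
  } else {
    pop <- rep("all", length(seqs))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  haplotypeDataset(seqs, pop = pop)
}

#' Write a HaplotypeDataset as FASTA
#'
#' @param x a HaplotypeDataset.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeFastaAlignment <- function(x, file) {
  seqs <- x@alignment
  if (is.null(names(seqs)))
    names(seqs) <- paste(x@pop, seq_along(seqs), sep = "_")
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Collapse an alignment to its distinct haplotypes
#'
#' Identical sequences (exact string identity) are merged; haplotypes are
#' labelled H1, H2, ... in order of decreasing total frequency (ties by
#' first appearance).
#'
#' @param x a HaplotypeDataset.
#' @return list with \code{sequences} (named character vector of distinct
#'   haplotypes), \code{counts} (matrix haplotype x locality),
#'   \code{assignment} (haplotype id per input sequence).
#' @export
collapseHaplotypes <- function(x) {
  s <- as.character(x@alignment)
  first <- !duplicated(s)
  uniq <- s[first]
  tot <- as.vector(table(factor(s, levels = uniq)))
  ord <- order(-tot, seq_along(uniq))
  uniq <- uniq[ord]
  ids <- paste0("H", seq_along(uniq))
  names(uniq) <- ids
  assignment <- ids[match(s, uniq)]
  counts <- table(factor(assignment, levels = ids), x@pop)
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, levels(x@pop)))
  list(sequences = uniq, counts = counts, assignment = assignment)
}

#' Read a run configuration file
#'
#' YAML file naming the input files and analysis settings: \code{genepop},
#' \code{fasta}, a \code{groups} mapping (locality -> region), \code{seed}
#' and optional replicate counts. Unknown keys are kept as-is.
#'
#' @param file path to a YAML config.
#' @return named list; \code{groups} is converted to a named character
#'   vector usable as a grouping.
#' @export
readRunConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$groups)) cfg$groups <- unlist(cfg$groups)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}
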