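#' Read a genepop (3-digit) genotype file
#'
#' Parses the widely used genepop dialect: a title line, one locus name per
#' line (or several comma-separated per line), and "POP"-separated blocks of
#' individual lines of the form \code{id , 101105 092092 ...} with 6-digit
#' diploid codes. Following the genepop convention the locality label of a
#' block is taken from the id of its last individual. A \code{000} half-code
#' anywhere in a call marks the whole call missing.
#'
#' @param file path to a genepop file, or a character vector holding its
#'   lines (a single string with embedded newlines is also accepted).
#' @return a \linkS4class{GenotypeDataset}; populations appear in file
#'   order.
#' @examples
#' txt <- c("toy", "locA", "locB", "POP",
#'          "north , 101105 202202", "north , 101101 202204",
#'          "POP", "south , 105105 204204")
#' gd <- readGenepop(txt)
#' popNames(gd)
#' @export
readGenepop <- function(file) {
  lines <- asLines(file)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 4L) stop("genepop format error: file too short")
  popIdx <- grep("^\\s*[Pp][Oo][Pp]\\s*$", lines)
  if (!length(popIdx))
    stop("genepop format error: no POP keyword found")
  headerLines <- lines[2:(popIdx[1] - 1L)]
  loci <- unlist(strsplit(headerLines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("genepop format error: no locus names")
  L <- length(loci)

  ids <- character(0); pops <- character(0)
  rows <- list()
  blockEnds <- c(popIdx[-1] - 1L, length(lines))
  for (b in seq_along(popIdx)) {
    from <- popIdx[b] + 1L; to <- blockEnds[b]
    if (from > to) stop("genepop format error: empty POP block ", b)
    blockIds <- character(0)
    blockRows <- list()
    for (ln in from:to) {
      line <- lines[ln]
      if (!nzchar(trimws(line))) next
      commaAt <- regexpr(",", line, fixed = TRUE)
      if (commaAt < 0)
        stop("genepop parse error at line ", ln, ": missing ',' separator")
      id <- trimws(substr(line, 1L, commaAt - 1L))
      geno <- strsplit(trimws(substr(line, commaAt + 1L, nchar(line))),
                       "\\s+")[[1]]
      if (length(geno) != L)
        stop("genepop parse error at line ", ln, ": ", length(geno),
             " genotypes for ", L, " loci")
      if (!all(grepl("^[0-9]{6}$", geno)))
        stop("genepop parse error at line ", ln,
             ": expected 6-digit diploid codes")
      a1 <- as.integer(substr(geno, 1L, 3L))
      a2 <- as.integer(substr(geno, 4L, 6L))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      blockIds <- c(blockIds, id)
      blockRows[[length(blockRows) + 1L]] <- cbind(a1, a2)
    }
    if (!length(blockIds))
      stop("genepop format error: empty POP block ", b)
    popLabel <- blockIds[length(blockIds)]
    ids <- c(ids, blockIds)
    pops <- c(pops, rep(popLabel, length(blockIds)))
    rows <- c(rows, blockRows)
  }
  n <- length(rows)
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) calls[i, , ] <- rows[[i]]
  ids <- make.unique(paste(pops, seq_along(ids), sep = "_"), sep = ".")
  genotypeDataset(calls, pop = pops, ids = ids, loci = loci)
}

#' Write a genepop (3-digit) genotype file
#'
#' Emits the 3-digit dialect re-readable by \code{\link{readGenepop}}. The
#' locality label is written as the id of every individual in its block so
#' that the genepop last-individual convention recovers it on re-reading;
#' missing calls are encoded \code{000000}. Population order is preserved.
#'
#' @param x a GenotypeDataset.
#' @param file optional path; when NULL the lines are returned invisibly
#'   visible (a character vector).
#' @param title title line (first line of the file).
#' @return invisibly, the character vector of lines.
#' @export
writeGenepop <- function(x, file = NULL, title = "bathypop genotypes") {
  cv <- x@calls[!is.na(x@calls)]
  if (length(cv) && any(cv > 999))
    stop("genepop encoding error: allele code > 999")
  lines <- c(title, x@loci)
  for (p in levels(x@pop)) {
    lines <- c(lines, "POP")
    idx <- which(x@pop == p)
    for (i in idx) {
      a1 <- x@calls[i, , 1]; a2 <- x@calls[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      geno <- sprintf("%03d%03d", a1, a2)
      lines <- c(lines, paste(p, ",", paste(geno, collapse = " ")))
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

asLines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) &&
      file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
}
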