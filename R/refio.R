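#' @useDynLib qgmapper, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Total length of a genome
#' @param x a \linkS4class{Genome}.
#' @return Numeric count of symbols across all records.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname totalLength
#' @export
setMethod("totalLength", "Genome", function(x) x@totalLength)

#' Per-record global start offsets
#' @param x a \linkS4class{Genome}.
#' @return Named numeric vector of 0-based record starts in the concatenated
#'   coordinate space.
#' @export
setGeneric("seqOffsets", function(x) standardGeneric("seqOffsets"))

#' @rdname seqOffsets
#' @export
setMethod("seqOffsets", "Genome", function(x) {
  stats::setNames(x@offsets, names(x@seqs))
})

#' Record lengths
#' @param x a \linkS4class{Genome}.
#' @return Named numeric vector of record lengths.
#' @export
setGeneric("recordLengths", function(x) standardGeneric("recordLengths"))

#' @rdname recordLengths
#' @export
setMethod("recordLengths", "Genome", function(x) {
  stats::setNames(as.numeric(nchar(x@seqs)), names(x@seqs))
})

#' Record sequences
#' @param x a \linkS4class{Genome}.
#' @return Named character vector of record sequences.
#' @export
setGeneric("recordSeqs", function(x) standardGeneric("recordSeqs"))

#' @rdname recordSeqs
#' @export
setMethod("recordSeqs", "Genome", function(x) x@seqs)

#' @export
setMethod("names", "Genome", function(x) names(x@seqs))

#' @export
setMethod("length", "Genome", function(x) length(x@seqs))

#' Map global positions to (record, local) pairs
#'
#' Every 0-based global position maps to exactly one record and 0-based local
#' position.
#'
#' @param genome a \linkS4class{Genome}.
#' @param pos numeric vector of 0-based global positions.
#' @return data.frame with columns \code{record} (name) and \code{local}.
#' @export
globalToLocal <- function(genome, pos) {
  stopifnot(is(genome, "Genome"))
  if (any(pos < 0 | pos >= genome@totalLength))
    stop("global position out of range")
  idx <- findInterval(pos, genome@offsets)
  data.frame(record = names(genome@seqs)[idx],
             local = pos - genome@offsets[idx],
             stringsAsFactors = FALSE)
}

#' Map (record, local) pairs to global positions
#'
#' @param genome a \linkS4class{Genome}.
#' @param record character vector of record names.
#' @param local numeric vector of 0-based local positions.
#' @return Numeric vector of 0-based global positions.
#' @export
localToGlobal <- function(genome, record, local) {
  stopifnot(is(genome, "Genome"))
  idx <- match(record, names(genome@seqs))
  if (anyNA(idx)) stop("unknown record name: ", record[which(is.na(idx))[1]])
  if (any(local < 0 | local >= nchar(genome@seqs)[idx]))
    stop("local position out of range")
  unname(genome@offsets[idx] + local)
}

#' Load a reference genome from FASTA
#'
#' Records are kept in file order; lower-case input is upper-cased; gzip
#' compression is detected transparently. Symbols outside \code{A,C,G,T,N}
#' are rejected.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return A \linkS4class{Genome}.
#' @export
loadFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("malformed FASTA in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  seqs <- stats::setNames(toupper(as.character(ss)),
                          sub("\\s.*$", "", names(ss)))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("record '%s' in '%s' contains invalid symbol '%s' at position %d",
                 names(seqs)[i], path, substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  Genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a \linkS4class{Genome}.
#' @param path output file.
#' @param width line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(genome, path, width = 70L) {
  stopifnot(is(genome, "Genome"))
  ss <- Biostrings::DNAStringSet(genome@seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Load reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character (\code{>} vs
#' \code{@}); gzip input is transparent. FASTQ qualities are retained so they
#' can be echoed into SAM output.
#'
#' @param path reads file.
#' @return data.frame with columns \code{id}, \code{seq} and \code{qual}
#'   (\code{NA} for FASTA input).
#' @export
loadReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) stop("empty reads file: ", path)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect reads format of '", path,
                   "': first character is neither '>' nor '@'")
  if (fmt == "fastq") {
    con <- gzfile(path, "rt")
    lns <- readLines(con)
    close(con)
    while (length(lns) > 0 && !nzchar(lns[length(lns)]))
      lns <- lns[-length(lns)]
    if (length(lns) %% 4 != 0)
      stop("malformed FASTQ in '", path, "': truncated record at line ",
           4 * (length(lns) %/% 4) + 1)
    i1 <- seq(1, length(lns), by = 4)
    if (any(!startsWith(lns[i1], "@")) || any(!startsWith(lns[i1 + 2], "+")))
      stop("malformed FASTQ in '", path, "': record separators out of phase")
    if (any(nchar(lns[i1 + 1]) != nchar(lns[i1 + 3]))) {
      j <- which(nchar(lns[i1 + 1]) != nchar(lns[i1 + 3]))[1]
      stop(sprintf("FASTQ record '%s' has sequence length %d but quality length %d",
                   sub("^@", "", sub("\\s.*$", "", lns[i1[j]])),
                   nchar(lns[i1[j] + 1]), nchar(lns[i1[j] + 3])))
    }
  }
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt, with.qualities = (fmt == "fastq")),
    error = function(e) stop("malformed ", toupper(fmt), " in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("no reads in file: ", path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  qual <- rep(NA_character_, length(ss))
  if (fmt == "fastq") {
    qual <- tryCatch(as.character(S4Vectors::mcols(ss)$qualities),
                     error = function(e)
                       stop("malformed FASTQ in '", path, "': ",
                            conditionMessage(e), call. = FALSE))
    if (any(nchar(qual) != nchar(seqs))) {
      i <- which(nchar(qual) != nchar(seqs))[1]
      stop(sprintf("FASTQ record '%s' has sequence length %d but quality length %d",
                   ids[i], nchar(seqs)[i], nchar(qual)[i]))
    }
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("read '%s' contains invalid symbol '%s'",
                 ids[i], substr(seqs[i], bad[i], bad[i])))
  }
  if (any(nchar(seqs) < 1)) stop("reads must have length >= 1")
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Reverse complement
#'
#' \code{A<->T}, \code{C<->G}, \code{N->N}, order reversed; an involution.
#'
#' @param x character vector of sequences over \code{A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("AACN")   # "NGTT"
#' @export
revComp <- function(x) {
  if (length(x) == 0) return(character(0))
  if (any(grepl("[^ACGTN]", x <- toupper(x))))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
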