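#' Build the q-gram index of a genome
#'
#' Indexes every position whose q-gram contains only \code{A,C,G,T} and lies
#' within one record: grams overlapping an \code{N} or a record boundary are
#' dropped. Only the forward strand is indexed; reverse-strand mapping
#' reverse-complements the read instead.
#'
#' @param genome a \linkS4class{Genome}.
#' @param q gram length, 1--16 (so the 2-bit packed key fits a machine word).
#' @return A \linkS4class{QGramIndex}.
#' @examples
#' g <- Genome(c(r = "ACGTACGT"))
#' idx <- buildIndex(g, 4)
#' lookupGram(idx, "ACGT")   # 0 4
#' @export
buildIndex <- function(genome, q) {
  stopifnot(is(genome, "Genome"))
  q <- as.integer(q)
  if (length(q) != 1 || is.na(q) || q < 1 || q > 16)
    stop("q must be a single integer in 1..16")
  raw <- cpp_build_index(unname(genome@seqs), q)
  if (length(raw$positions) == 0)
    warning("empty index: no record contains an N-free stretch of length q = ", q)
  new("QGramIndex", q = q, keys = raw$keys, starts = raw$starts,
      positions = raw$positions, genomeDigest = cpp_digest(unname(genome@seqs)))
}

#' Look up the occurrences of a q-gram
#'
#' @param index a \linkS4class{QGramIndex}.
#' @param gram character scalar of length \code{q}. A gram containing
#'   \code{N} has no occurrences by construction.
#' @return Ascending integer vector of 0-based global start positions
#'   (possibly empty).
#' @export
lookupGram <- function(index, gram) {
  stopifnot(is(index, "QGramIndex"))
  if (!is.character(gram) || length(gram) != 1 || nchar(gram) != index@q)
    stop("gram must be a single string of length q = ", index@q)
  cpp_lookup(index@keys, index@starts, index@positions,
             cpp_gram_key(toupper(gram)))
}

.IDX_MAGIC <- charToRaw("QGIX")
.IDX_VERSION <- 1L

#' Save a q-gram index to disk
#'
#' Versioned binary container (magic bytes, format version, q, genome digest,
#' CSR table), reloadable bit-identically with \code{\link{loadIndex}}.
#'
#' @param index a \linkS4class{QGramIndex}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "QGramIndex"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.IDX_MAGIC, con)
  writeBin(.IDX_VERSION, con, size = 4L, endian = "little")
  writeBin(index@q, con, size = 4L, endian = "little")
  dig <- charToRaw(index@genomeDigest)
  writeBin(length(dig), con, size = 4L, endian = "little")
  writeBin(dig, con)
  writeBin(length(index@keys), con, size = 4L, endian = "little")
  writeBin(index@keys, con, size = 8L, endian = "little")
  writeBin(length(index@starts), con, size = 4L, endian = "little")
  writeBin(index@starts, con, size = 4L, endian = "little")
  writeBin(length(index@positions), con, size = 4L, endian = "little")
  writeBin(index@positions, con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a q-gram index written by \code{\link{saveIndex}}
#'
#' @param path index file.
#' @return A \linkS4class{QGramIndex}.
#' @export
loadIndex <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, .IDX_MAGIC))
    stop("'", path, "' is not a q-gram index file (bad magic bytes)")
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(ver, .IDX_VERSION))
    stop("unsupported index format version ", ver)
  q <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nd <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  dig <- rawToChar(readBin(con, "raw", n = nd))
  nk <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  keys <- readBin(con, "numeric", n = nk, size = 8L, endian = "little")
  ns <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  starts <- readBin(con, "integer", n = ns, size = 4L, endian = "little")
  np <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  positions <- readBin(con, "integer", n = np, size = 4L, endian = "little")
  new("QGramIndex", q = q, keys = keys, starts = starts,
      positions = positions, genomeDigest = dig)
}
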