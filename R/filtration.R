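#' Partition a read into k+1 non-overlapping seeds
#'
#' By the pigeonhole principle, a read matching a reference location within
#' edit distance k has at least one of its k+1 non-overlapping q-gram seeds
#' matching exactly. Seeds are leftmost-packed at offsets
#' \code{0, q, 2q, ..., kq}; any read tail beyond \code{(k+1)q} symbols
#' carries no seed. Seeds containing \code{N} are kept but can produce no
#' index hits.
#'
#' @param seq read sequence (character scalar).
#' @param k edit-distance threshold.
#' @param q gram length.
#' @return data.frame with columns \code{offset} (0-based) and \code{gram},
#'   or \code{NULL} with a warning when the read is shorter than
#'   \code{(k+1) * q} and therefore unmappable at this \code{(k, q)}.
#' @examples
#' partitionRead(strrep("ACGT", 3), k = 2, q = 4)   # offsets 0 4 8
#' @export
partitionRead <- function(seq, k, q) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  m <- nchar(seq)
  k <- as.integer(k); q <- as.integer(q)
  if (k < 0 || q < 1) stop("k must be >= 0 and q >= 1")
  if (m < (k + 1) * q) {
    warning(sprintf("read too short for seeding: length %d < (k+1)*q = %d; read is unmappable at this (k, q)",
                    m, (k + 1) * q))
    return(NULL)
  }
  offset <- q * (0:k)
  data.frame(offset = offset,
             gram = substring(seq, offset + 1, offset + q),
             stringsAsFactors = FALSE)
}

#' Generate candidate verification windows for an oriented read
#'
#' Every exact index hit \code{dq} of a seed at read offset \code{c} implies
#' the anchor \code{d = dq - c}; anchors are deduplicated (the same location
#' reached from several seeds is verified once) and each receives its
#' verification window \code{[d-k, d+m+k)} intersected with its record — the
#' interval that can contain any alignment of the read within k edits of the
#' anchor. Run on the reverse-complemented read for the other strand.
#'
#' @param seq oriented read sequence (character scalar).
#' @param index a \linkS4class{QGramIndex} built on \code{genome} with the
#'   same q used for seeding.
#' @param genome the indexed \linkS4class{Genome}.
#' @param k edit-distance threshold.
#' @param occCap optional cap on seed occurrences: seeds hitting more than
#'   this many reference positions are skipped. Off by default
#'   (\code{Inf}); using a cap forfeits the full-sensitivity guarantee.
#' @return data.frame sorted by anchor with columns \code{anchor},
#'   \code{windowStart}, \code{windowEnd} (0-based global, half-open) and
#'   \code{record} (name). Zero rows is a valid result.
#' @export
candidatesForRead <- function(seq, index, genome, k, occCap = Inf) {
  stopifnot(is(index, "QGramIndex"), is(genome, "Genome"))
  if (index@genomeDigest != cpp_digest(unname(genome@seqs)))
    stop("index was not built from this genome (digest mismatch)")
  seq <- toupper(seq)
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0")
  offs <- genome@offsets
  cap <- if (is.finite(occCap)) as.integer(occCap) else 0L
  res <- cpp_candidates(seq, k, index@q, index@keys, index@starts,
                        index@positions, offs, offs + nchar(genome@seqs), cap)
  data.frame(anchor = res$anchor,
             windowStart = res$windowStart,
             windowEnd = res$windowEnd,
             record = names(genome@seqs)[res$record],
             stringsAsFactors = FALSE)
}

#' Count-filtering q-gram threshold
#'
#' The classical lower bound on the number of q-grams a sequence of length
#' \code{|s|} must share with any match within distance k:
#' \code{T = |s| - (k+1)*q + 1}. Exposed as a utility; the mapper's own
#' filtration uses the pigeonhole principle, not counting.
#'
#' @param seqLen sequence length \code{|s|}.
#' @param k distance threshold.
#' @param q gram length.
#' @return Integer threshold T.
#' @examples
#' countFilterThreshold(100, 4, 10)   # 51
#' @export
countFilterThreshold <- function(seqLen, k, q) {
  t <- seqLen - (k + 1) * q + 1
  if (t < 1)
    stop(sprintf("threshold undefined: |s| = %d < (k+1)*q = %d", seqLen, (k + 1) * q))
  as.integer(t)
}
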