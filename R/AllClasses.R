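#' @import methods
NULL

#' Reference genome with a concatenated coordinate space
#'
#' Ordered named records over the alphabet \code{A,C,G,T,N}, addressable both
#' per record (0-based local positions) and in one concatenated global
#' coordinate space. All internal coordinates in the package are 0-based and
#' half-open; conversion to 1-based happens only at the SAM boundary.
#'
#' @slot seqs named character vector of upper-case record sequences.
#' @slot offsets numeric, 0-based global start of each record in the
#'   concatenated space.
#' @slot totalLength numeric, sum of record lengths.
#' @export
setClass("Genome",
         representation(seqs = "character",
                        offsets = "numeric",
                        totalLength = "numeric"))

setValidity("Genome", function(object) {
  s <- object@seqs
  if (length(s) == 0) return("genome must contain at least one record")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    return("every record needs a non-empty name")
  if (anyDuplicated(names(s)))
    return("record names must be unique")
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    return(sprintf("record '%s' contains symbols outside {A,C,G,T,N}",
                   names(s)[which(bad)[1]]))
  lens <- nchar(s)
  if (!isTRUE(all.equal(object@offsets, cumsum(c(0, lens[-length(lens)])),
                        check.attributes = FALSE)))
    return("offsets must be the cumulative record lengths")
  if (object@totalLength != sum(lens))
    return("totalLength must equal the sum of record lengths")
  TRUE
})

#' Construct a Genome from named sequences
#'
#' Sequences are upper-cased; symbols outside \code{A,C,G,T,N} are rejected.
#'
#' @param seqs named character vector of record sequences.
#' @return A \linkS4class{Genome}.
#' @examples
#' g <- Genome(c(chr1 = "ACGTACGT", chr2 = "ttagg"))
#' totalLength(g)
#' @export
Genome <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0)
    stop("seqs must be a non-empty named character vector")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  new("Genome", seqs = seqs,
      offsets = cumsum(c(0, lens[-length(lens)])),
      totalLength = sum(lens))
}

#' Hash index from q-grams to reference positions
#'
#' Maps every 2-bit-packed q-gram key to the ascending list of 0-based global
#' start positions in the indexed genome. Grams overlapping an \code{N} or a
#' record boundary are never stored. Stored in a flat CSR layout: sorted
#' unique keys, per-key offsets, one ascending position vector.
#'
#' @slot q integer gram length (1--16).
#' @slot keys numeric vector of sorted unique 2-bit packed keys.
#' @slot starts integer vector of length \code{length(keys) + 1}; key
#'   \code{i} owns \code{positions[(starts[i]+1):starts[i+1]]}.
#' @slot positions integer vector of 0-based global start positions.
#' @slot genomeDigest character, FNV-1a digest of the indexed genome.
#' @export
setClass("QGramIndex",
         representation(q = "integer",
                        keys = "numeric",
                        starts = "integer",
                        positions = "integer",
                        genomeDigest = "character"))

setValidity("QGramIndex", function(object) {
  if (length(object@q) != 1 || is.na(object@q) || object@q < 1 || object@q > 16)
    return("q must be a single integer in 1..16")
  if (length(object@starts) != length(object@keys) + 1)
    return("starts must have length(keys) + 1 entries")
  if (is.unsorted(object@keys, strictly = TRUE) && length(object@keys) > 1)
    return("keys must be strictly ascending")
  TRUE
})

#' Packed multi-pattern bit-vector state
#'
#' The initial wide-word state for scoring one read against up to
#' \code{slotCapacity} candidate windows simultaneously. Each pattern owns a
#' slot of \code{2k+2} bits: the \code{2k+1} band bits plus one buffer bit
#' that absorbs addition carries so neighbouring patterns never interact.
#' Wide words are stored as little-endian raw vectors of
#' \code{wordWidth / 8} bytes.
#'
#' @slot windows character vector of candidate window sequences (patterns).
#' @slot k integer edit-distance threshold.
#' @slot wordWidth integer, 64 or 128.
#' @slot slotWidth integer, \code{2k + 2}.
#' @slot slotCapacity integer, \code{floor(wordWidth / (2k + 2))}.
#' @slot VP,VN,E raw vectors: packed vertical-delta words and per-slot
#'   running distances.
#' @slot Peq list of four raw vectors (A, C, G, T match masks for each
#'   pattern's first \code{2k+1} symbols).
#' @slot bandMask,bufferMask,baseMask raw vectors: precomputed wide masks
#'   (band bits, buffer bits, slot base bits).
#' @slot active logical per-slot liveness flags for the branch-cut.
#' @export
setClass("PackedState",
         representation(windows = "character",
                        k = "integer",
                        wordWidth = "integer",
                        slotWidth = "integer",
                        slotCapacity = "integer",
                        VP = "raw", VN = "raw", E = "raw",
                        Peq = "list",
                        bandMask = "raw", bufferMask = "raw", baseMask = "raw",
                        active = "logical"))

setValidity("PackedState", function(object) {
  if (!(object@wordWidth %in% c(64L, 128L)))
    return("wordWidth must be 64 or 128")
  if (object@slotWidth != 2L * object@k + 2L)
    return("slotWidth must equal 2k + 2")
  if (length(object@windows) > object@slotCapacity)
    return("more patterns than slots")
  if (object@slotWidth * object@slotCapacity > object@wordWidth)
    return("slots exceed the word width")
  TRUE
})

#' @export
setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome: %d record(s), %s bp total\n",
              length(object@seqs), format(object@totalLength, big.mark = ",")))
  n <- min(5L, length(object@seqs))
  for (i in seq_len(n))
    cat(sprintf("  %s  %s bp  [global offset %s]\n", names(object@seqs)[i],
                format(nchar(object@seqs[[i]]), big.mark = ","),
                format(object@offsets[i], big.mark = ",")))
  if (length(object@seqs) > n) cat(sprintf("  ... and %d more\n", length(object@seqs) - n))
})

#' @export
setMethod("show", "QGramIndex", function(object) {
  cat(sprintf("QGramIndex: q = %d, %s distinct grams, %s positions (genome %s)\n",
              object@q, format(length(object@keys), big.mark = ","),
              format(length(object@positions), big.mark = ","),
              object@genomeDigest))
})

#' @export
setMethod("show", "PackedState", function(object) {
  cat(sprintf("PackedState: %d pattern(s) in %d-bit word, k = %d, slot width %d bits, capacity %d\n",
              length(object@windows), object@wordWidth, object@k,
              object@slotWidth, object@slotCapacity))
})
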