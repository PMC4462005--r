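#' Full semi-global edit-distance matrix
#'
#' The classic dynamic-programming matrix C of size (m+1) x (n+1) with
#' semi-global boundary \code{C[0,j] = 0}, \code{C[i,0] = i}: the read must
#' be consumed in full, the text substring is free at both ends. \code{N} in
#' either sequence mismatches every symbol. The semi-global distance is
#' \code{min(C[m+1, ])}. This is the package's reference oracle; the banded
#' bit-vector verifiers are validated against it.
#'
#' @param read read sequence (rows).
#' @param text text sequence (columns).
#' @return Integer matrix of dimensions \code{(m+1) x (n+1)}.
#' @examples
#' C <- dpEditMatrix("ACGT", "TTACGTTT")
#' min(C[5, ])   # 0: exact substring
#' @export
dpEditMatrix <- function(read, text) {
  stopifnot(is.character(read), is.character(text),
            length(read) == 1, length(text) == 1)
  if (nchar(read) < 1 || nchar(text) < 1)
    stop("read and text must be non-empty")
  cpp_dp_edit_matrix(toupper(read), toupper(text))
}

#' Semi-global edit distance
#'
#' Minimum edit distance of \code{read} against any substring of
#' \code{text}: \code{min(C[m+1, ])} of \code{\link{dpEditMatrix}}.
#'
#' @inheritParams dpEditMatrix
#' @return Integer distance.
#' @export
semiGlobalDist <- function(read, text) {
  C <- dpEditMatrix(read, text)
  min(C[nrow(C), ])
}

#' Width of the banded computing area
#'
#' Only \code{2k+1} cells per column of the dynamic-programming matrix can
#' lie on an alignment within k edits of the anchor, so the banded verifiers
#' use bit vectors of exactly this length.
#'
#' @param k edit-distance threshold.
#' @return Integer \code{2k + 1}.
#' @export
bandWidth <- function(k) {
  k <- as.integer(k)
  if (any(k < 0)) stop("k must be non-negative")
  2L * k + 1L
}

#' Number of patterns that fit one packed word
#'
#' Each pattern occupies a slot of \code{2k+2} bits (band plus buffer bit),
#' so a word of width W holds \code{floor(W / (2k+2))} patterns.
#'
#' @param k edit-distance threshold.
#' @param wordWidth word width in bits (64 or 128).
#' @return Integer slot capacity.
#' @examples
#' slotCapacity(4, 128)   # 12
#' @export
slotCapacity <- function(k, wordWidth = 128L) {
  k <- as.integer(k)
  if (any(k < 0)) stop("k must be non-negative")
  if (!all(wordWidth %in% c(64L, 128L))) stop("wordWidth must be 64 or 128")
  as.integer(wordWidth %/% (2L * k + 2L))
}

#' Default number of packed slots actually used
#'
#' Verification stops only when every packed pattern is finished or cut, so
#' very wide packings wait for their slowest slot; a moderate slot count
#' works better. The default is 8 slots where they fit and the full (smaller)
#' capacity otherwise — e.g. 4 slots at k = 15 with a 128-bit word.
#'
#' @inheritParams slotCapacity
#' @return Integer slot count.
#' @export
defaultSlots <- function(k, wordWidth = 128L) {
  pmin(slotCapacity(k, wordWidth), 8L)
}

#' Scalar banded bit-vector verification
#'
#' Scores a read against one candidate window under edit distance using the
#' banded Myers bit-vector algorithm: only the \code{2k+1}-wide band around
#' the base diagonal (shifted k right of the main diagonal) is computed,
#' column by column over the read, with the column update done by word-wide
#' bit operations on the VP/VN delta vectors. Equals the
#' \code{\link{dpEditMatrix}} semi-global minimum whenever that minimum is at
#' most k for windows in full verification-window geometry, and reports no match otherwise.
#' Windows shorter than \code{m + 2k} (clamped at record edges) are padded
#' virtually with a sentinel that matches nothing, so edge effects only ever
#' increase the distance.
#'
#' @param read the read (used as the text: one column step per read symbol).
#' @param window the candidate window (used as the pattern), length at most
#'   \code{m + 2k}.
#' @param k edit-distance threshold; requires \code{2k+2 <= 64}.
#' @param branchCut terminate early once the minimum attainable score in the
#'   band exceeds k. Never changes the result, only the running time.
#' @return list with \code{matched}, \code{distance} (NA when no match),
#'   \code{bestEnd} (0-based end offset within the window, smallest among
#'   equal-distance ends) and \code{cut}.
#' @examples
#' bandedMyers("ACGT", "ACGT", k = 1)$distance   # 0
#' @export
bandedMyers <- function(read, window, k, branchCut = TRUE) {
  stopifnot(is.character(read), is.character(window))
  cpp_banded_myers(toupper(read), toupper(window), as.integer(k),
                   isTRUE(branchCut))
}

#' Pack candidate windows into one wide word
#'
#' Builds the initial \linkS4class{PackedState} for scoring one read against
#' up to \code{floor(W / (2k+2))} windows simultaneously: per-symbol Peq
#' slots are filled with each pattern's first \code{2k+1} symbols, VP, VN and
#' E are zeroed, and the wide shift/carry masks are precomputed. Windows
#' shorter than the band are padded with the sentinel (all Peq bits 0).
#'
#' @param windows character vector of candidate windows from one read's
#'   candidate set.
#' @param k edit-distance threshold.
#' @param wordWidth emulated word width in bits, 64 or 128.
#' @return A \linkS4class{PackedState}.
#' @examples
#' ps <- packPatterns(c("ACGTACGTAC", "ACGTACGAAC"), k = 4, wordWidth = 128)
#' ps@slotCapacity   # 12
#' @export
packPatterns <- function(windows, k, wordWidth = 128L) {
  stopifnot(is.character(windows), length(windows) >= 1)
  k <- as.integer(k); wordWidth <- as.integer(wordWidth)
  p <- cpp_pack_patterns(toupper(windows), k, wordWidth)
  new("PackedState", windows = toupper(windows), k = k,
      wordWidth = wordWidth, slotWidth = p$slotWidth,
      slotCapacity = p$slotCapacity,
      VP = p$VP, VN = p$VN, E = p$E, Peq = p$Peq,
      bandMask = p$bandMask, bufferMask = p$bufferMask, baseMask = p$baseMask,
      active = rep(TRUE, length(windows)))
}

#' Packed multi-pattern banded verification
#'
#' Runs the vectorized banded Myers bit-vector algorithm: one column step per
#' read symbol updates all slots of the packed state at once (HP/HN/D0 from
#' VP/VN; VP/VN update; Peq shifted right with the cross-slot leak masked off
#' and each pattern's next symbol inserted at the slot top; per-slot E
#' updated from D0's bit at the tracked band position). Buffer bits keep
#' additions from propagating between slots, so per-slot results are
#' identical to \code{\link{bandedMyers}} on the same (read, window, k).
#'
#' @param read the read (shared text).
#' @param packed a \linkS4class{PackedState} built for this read's windows.
#' @param branchCut per-slot early termination (soundness-preserving).
#' @param validate check the packed-state invariants (VP & VN = 0, buffer
#'   bits clear) at every column; an error is raised on violation.
#' @return data.frame with one row per pattern: \code{matched},
#'   \code{distance}, \code{bestEnd}, \code{cut}.
#' @export
vectorizedBandedMyers <- function(read, packed, branchCut = TRUE, validate = FALSE) {
  stopifnot(is.character(read), is(packed, "PackedState"))
  r <- cpp_vectorized_banded(toupper(read), packed@windows, packed@k,
                             packed@wordWidth, isTRUE(branchCut),
                             isTRUE(validate))
  data.frame(matched = r$matched, distance = r$distance,
             bestEnd = r$bestEnd, cut = r$cut)
}

#' CIGAR traceback for a verified candidate
#'
#' Recomputes the dynamic-programming matrix over the (sentinel-padded)
#' window and backtracks from \code{(m, bestEnd)}, preferring diagonal over
#' up over left on ties. \code{I} denotes a read symbol absent from the
#' window, \code{D} a window symbol absent from the read; the M+I lengths sum
#' to the read length, and \code{nm} equals the verified distance.
#'
#' @param read the read.
#' @param window the candidate window (unpadded, as extracted from the
#'   record).
#' @param k edit-distance threshold.
#' @param bestEnd 0-based end offset within the (left-padded) window, as
#'   reported by the banded verifiers.
#' @param padLeft number of sentinel symbols the window was short of
#'   \code{anchor - k} at a record start (0 away from record edges).
#' @return list with \code{cigar}, \code{nm}, \code{alnStart} (0-based start
#'   offset within the padded window) and \code{distance}.
#' @export
tracebackCigar <- function(read, window, k, bestEnd, padLeft = 0L) {
  stopifnot(is.character(read), is.character(window))
  cpp_traceback(toupper(read), toupper(window), as.integer(k),
                as.integer(bestEnd), as.integer(padLeft))
}
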