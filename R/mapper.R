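#' Mapping configuration
#'
#' @param k explicit edit-distance threshold; overrides \code{errorRate}.
#' @param errorRate per-read threshold as a fraction of the read length;
#'   the effective k is \code{floor(errorRate * m)}. Default 0.05, the usual
#'   setting for short-read all-mapping (k = 5, 7, 15 for 100, 151, 300 bp).
#' @param q seed gram length; must match the index the reads are mapped
#'   against (see \code{\link{defaultQ}}).
#' @param wordWidth emulated word width for packed verification, 64 or 128.
#' @param slots number of packed slots used per verification call;
#'   \code{NULL} for the default \code{min(floor(W/(2k+2)), 8)}.
#' @param branchCut enable early termination of hopeless candidates.
#' @param occCap optional cap on seed occurrences for pathological repeats;
#'   \code{Inf} (the default) returns all occurrences and keeps the
#'   full-sensitivity guarantee.
#' @return A list of class \code{MapConfig}.
#' @export
mapConfig <- function(k = NULL, errorRate = 0.05, q = NULL,
                      wordWidth = 128L, slots = NULL, branchCut = TRUE,
                      occCap = Inf) {
  if (!is.null(k) && (length(k) != 1 || k < 0))
    stop("k must be a single non-negative integer")
  if (length(errorRate) != 1 || errorRate < 0 || errorRate >= 1)
    stop("errorRate must be in [0, 1)")
  if (!wordWidth %in% c(64L, 128L)) stop("wordWidth must be 64 or 128")
  structure(list(k = if (is.null(k)) NULL else as.integer(k),
                 errorRate = errorRate,
                 q = if (is.null(q)) NULL else as.integer(q),
                 wordWidth = as.integer(wordWidth),
                 slots = if (is.null(slots)) NULL else as.integer(slots),
                 branchCut = isTRUE(branchCut),
                 occCap = occCap),
            class = "MapConfig")
}

#' Effective edit-distance threshold for a read
#'
#' An explicit \code{k} in the configuration wins; otherwise
#' \code{floor(errorRate * m)}, which reproduces the standard thresholds
#' k = 5, 7, 15 for 100, 151 and 300 bp reads at a 5\% rate.
#'
#' @param m read length(s).
#' @param config a \code{\link{mapConfig}}.
#' @return Integer vector of thresholds.
#' @examples
#' effectiveK(c(100, 151, 300), mapConfig())   # 5 7 15
#' @export
effectiveK <- function(m, config = mapConfig()) {
  stopifnot(inherits(config, "MapConfig"), all(m >= 1))
  if (!is.null(config$k)) rep(config$k, length(m))
  else as.integer(floor(config$errorRate * m))
}

#' Default seed length for an index
#'
#' \code{q = max(10, min(16, floor(m / (k+1))))}: the largest seed within the
#' 2-bit key limit that still lets k+1 non-overlapping seeds fit a read of
#' length m, floored at 10 to keep random hits rare. Reads shorter than
#' \code{(k+1) * q} under this rule are reported unmapped.
#'
#' @param m read length.
#' @param k edit-distance threshold.
#' @return Integer gram length.
#' @examples
#' defaultQ(100, 5)   # 16
#' @export
defaultQ <- function(m, k) {
  as.integer(pmax(10L, pmin(16L, m %/% (k + 1L))))
}

#' Map a batch of reads, reporting all locations
#'
#' The end-to-end single-end pipeline: each read (forward and
#' reverse-complemented) is partitioned into k+1 seeds, candidate windows are
#' generated by pigeonhole filtration over the index, candidates are verified
#' in packed chunks by the vectorized banded bit-vector algorithm, matches
#' get a CIGAR by banded traceback, and alignments sharing (record, position,
#' strand) are reported once with the minimum distance. All locations within
#' k are reported, sorted by (record, position).
#'
#' @param reads data.frame with columns \code{id}, \code{seq} and optionally
#'   \code{qual} (as from \code{\link{loadReads}}), or a character vector of
#'   sequences (ids are made up).
#' @param index a \linkS4class{QGramIndex} of \code{genome}.
#' @param genome the indexed \linkS4class{Genome}.
#' @param config a \code{\link{mapConfig}}.
#' @return data.frame with columns \code{readId}, \code{refName}, \code{pos}
#'   (1-based leftmost), \code{strand}, \code{distance}, \code{cigar},
#'   \code{nm}. Reads with no row are unmapped. Attribute \code{stats} holds
#'   counts (reads, candidates, verified, cutEarly, mapped, tooShort).
#' @export
mapReads <- function(reads, index, genome, config = mapConfig()) {
  stopifnot(is(index, "QGramIndex"), is(genome, "Genome"),
            inherits(config, "MapConfig"))
  if (is.character(reads))
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (index@genomeDigest != cpp_digest(unname(genome@seqs)))
    stop("index was not built from this genome (digest mismatch)")
  if (!is.null(config$q) && config$q != index@q)
    stop("config q = ", config$q, " does not match the index q = ", index@q)
  m <- nchar(reads$seq)
  ks <- effectiveK(m, config)
  res <- cpp_map_batch(toupper(reads$seq), ks, index@keys, index@starts,
                       index@positions, index@q, unname(genome@seqs),
                       genome@offsets, genome@offsets + nchar(genome@seqs),
                       config$wordWidth,
                       if (is.null(config$slots)) -1L else config$slots,
                       if (is.finite(config$occCap)) as.integer(config$occCap) else 0L,
                       config$branchCut)
  if (any(res$tooShort))
    warning(sum(res$tooShort), " read(s) too short for seeding ",
            "(length < (k+1)*q with q = ", index@q, "); reported unmapped")
  out <- data.frame(readId = reads$id[res$readIdx],
                    refName = names(genome@seqs)[res$record],
                    pos = res$pos,
                    strand = res$strand,
                    distance = res$nm,
                    cigar = res$cigar,
                    nm = res$nm,
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(reads = nrow(reads),
                          res$stats,
                          mapped = length(unique(res$readIdx)),
                          tooShort = sum(res$tooShort))
  out
}

#' Map a single read
#'
#' @param read character scalar (sequence) or one-row data.frame with
#'   \code{id} and \code{seq}.
#' @inheritParams mapReads
#' @return As \code{\link{mapReads}}.
#' @export
mapRead <- function(read, index, genome, config = mapConfig()) {
  if (is.character(read) && length(read) == 1)
    read <- data.frame(id = "read1", seq = read, stringsAsFactors = FALSE)
  mapReads(read, index, genome, config)
}

#' Write mappings as SAM
#'
#' Emits an \code{@HD} (VN:1.6, SO:unsorted) header, one \code{@SQ} line per
#' record and an \code{@PG} line, then one alignment line per mapping: FLAG 0
#' forward, 16 reverse (reverse lines carry the reverse-complemented SEQ and
#' reversed QUAL), plus bit 256 on every line after the first of a read;
#' unmapped reads are emitted once with FLAG 4. MAPQ is 255 (unavailable);
#' \code{NM:i} carries the edit distance.
#'
#' @param mappings data.frame from \code{\link{mapReads}}.
#' @param reads the reads that were mapped (data.frame with \code{id},
#'   \code{seq}, optional \code{qual}); needed for SEQ/QUAL fields and for
#'   emitting unmapped reads.
#' @param genome the reference \linkS4class{Genome}.
#' @param path output SAM file.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(mappings, reads, genome, path) {
  stopifnot(is.data.frame(mappings), is.data.frame(reads), is(genome, "Genome"))
  if (is.null(reads$qual)) reads$qual <- NA_character_
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome@seqs),
                   nchar(genome@seqs)),
           sprintf("@PG\tID:qgmapper\tPN:qgmapper\tVN:%s",
                   as.character(utils::packageVersion("qgmapper"))))
  seqF <- toupper(reads$seq)
  qualF <- ifelse(is.na(reads$qual), "*", reads$qual)
  ridx <- match(mappings$readId, reads$id)
  if (anyNA(ridx)) stop("mappings contain read ids absent from `reads`")
  ord <- order(ridx)  # stable: keeps the per-read (refName, pos) order
  mp <- mappings[ord, , drop = FALSE]
  ridx <- ridx[ord]
  alnLines <- character(0)
  if (nrow(mp) > 0) {
    isRev <- mp$strand == "-"
    seqOut <- seqF[ridx]
    qualOut <- qualF[ridx]
    if (any(isRev)) {
      seqOut[isRev] <- revComp(seqOut[isRev])
      qr <- qualOut[isRev]
      nontrivial <- qr != "*"
      qr[nontrivial] <- vapply(strsplit(qr[nontrivial], NULL),
                               function(x) paste(rev(x), collapse = ""), "")
      qualOut[isRev] <- qr
    }
    flag <- ifelse(isRev, 16L, 0L) + ifelse(duplicated(ridx), 256L, 0L)
    alnLines <- paste(mp$readId, flag, mp$refName,
                      format(mp$pos, scientific = FALSE, trim = TRUE),
                      255L, mp$cigar, "*", 0L, 0L, seqOut, qualOut,
                      sprintf("NM:i:%d", mp$nm), sep = "\t")
  }
  unm <- setdiff(seq_len(nrow(reads)), ridx)
  unmLines <- if (length(unm))
    paste(reads$id[unm], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
          seqF[unm], qualF[unm], sep = "\t")
  else character(0)
  body <- c(alnLines, unmLines)[order(c(ridx, unm))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
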