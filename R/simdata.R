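`%||%` <- function(a, b) if (is.null(a)) b else a

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' I.i.d. symbols with \code{P(G) + P(C) = gc}; deterministic under a seed.
#' An optional repeat injection copies one segment to extra loci, creating
#' known multi-mapping structure.
#'
#' @param length numeric vector of record lengths; names become record names
#'   (default \code{chr1, chr2, ...}).
#' @param gc GC fraction in \code{[0, 1]}.
#' @param seed RNG seed (restored afterwards), or \code{NULL}.
#' @param repeats \code{NULL}, or a list with \code{length} (segment length)
#'   and \code{copies}: a random segment of the first record is copied to
#'   \code{copies} additional random loci (possibly overlapping).
#' @return A \linkS4class{Genome}.
#' @examples
#' g <- randomGenome(1000, gc = 0.5, seed = 7)
#' @export
randomGenome <- function(length, gc = 0.41, seed = NULL, repeats = NULL) {
  stopifnot(all(length >= 1), gc >= 0, gc <= 1)
  .withSeed(seed, {
    nm <- names(length)
    if (is.null(nm)) nm <- paste0("chr", seq_along(length))
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- vapply(length, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
            collapse = ""), "")
    names(seqs) <- nm
    if (!is.null(repeats)) {
      segLen <- repeats$length
      copies <- repeats$copies
      stopifnot(segLen >= 1, copies >= 1, nchar(seqs[1]) >= 2 * segLen)
      src <- sample.int(nchar(seqs[1]) - segLen + 1, 1)
      seg <- substr(seqs[1], src, src + segLen - 1)
      for (i in seq_len(copies)) {
        at <- sample.int(nchar(seqs[1]) - segLen + 1, 1)
        substr(seqs[1], at, at + segLen - 1) <- seg
      }
    }
    Genome(seqs)
  })
}

.randBase <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(exclude)) sample(bases, n, replace = TRUE)
  else vapply(exclude, function(e) sample(setdiff(bases, e), 1), "")
}

#' Sample reads with planted, truth-tracked edits
#'
#' Reads of length m are drawn at uniform start positions (keeping
#' \code{m + maxEdits} clear of record edges), each with a number of edits
#' drawn uniformly from \code{0..maxEdits}, applied at distinct read offsets
#' with types drawn by \code{weights} (substitution : insertion : deletion;
#' the default 4:1:1 mimics Illumina's substitution-dominant profile). Each
#' read is placed on the reverse strand with probability \code{strandProb}
#' (the stored sequence is then the reverse complement of the genome-facing
#' construct). Qualities are the constant \code{"I"}.
#'
#' @param genome a \linkS4class{Genome}.
#' @param m read length.
#' @param count number of reads.
#' @param maxEdits maximum planted edits per read.
#' @param weights numeric length-3 vector of sub/ins/del weights.
#' @param strandProb probability of the reverse strand.
#' @param seed RNG seed (restored afterwards), or \code{NULL}.
#' @return list with \code{reads} (data.frame \code{id}, \code{seq},
#'   \code{qual}) and \code{truth} (data.frame \code{readId}, \code{refName},
#'   \code{truePos} — 0-based planted window start, \code{strand},
#'   \code{edits}, \code{script} — e.g. \code{"sub@12;ins@40"} in read
#'   offsets).
#' @export
sampleReads <- function(genome, m, count, maxEdits = 0,
                        weights = c(4, 1, 1), strandProb = 0.5, seed = NULL) {
  stopifnot(is(genome, "Genome"), m >= 1, count >= 1, maxEdits >= 0,
            length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  lens <- nchar(genome@seqs)
  eligible <- which(lens >= m + 2 * maxEdits + 1)
  if (length(eligible) == 0)
    stop("no record is long enough for reads of length ", m,
         " with maxEdits = ", maxEdits)
  .withSeed(seed, {
    recPick <- eligible[sample.int(length(eligible), count, replace = TRUE,
                                   prob = lens[eligible])]
    ids <- sprintf("sim%06d", seq_len(count))
    seqs <- character(count)
    truePos <- numeric(count)
    strand <- character(count)
    edits <- integer(count)
    script <- character(count)
    qual <- strrep("I", m)
    for (i in seq_len(count)) {
      rec <- recPick[i]
      recSeq <- genome@seqs[[rec]]
      start <- maxEdits + sample.int(lens[rec] - m - 2 * maxEdits, 1) - 1L
      nE <- if (maxEdits > 0) sample.int(maxEdits + 1L, 1L) - 1L else 0L
      ops <- character(0)
      if (nE > 0) {
        offs <- sort(sample.int(m, nE) - 1L)
        type <- sample(c("sub", "ins", "del"), nE, replace = TRUE,
                       prob = weights)
        ops <- paste0(type, "@", offs)
      } else {
        offs <- integer(0)
        type <- character(0)
      }
      # walk read offsets, consuming the genome template
      tmpl <- strsplit(substr(recSeq, start + 1L, start + m + maxEdits), "")[[1]]
      chars <- character(m)
      g <- 0L  # offset into tmpl
      ei <- 1L
      for (p in seq_len(m) - 1L) {
        while (ei <= nE && type[ei] == "del" && offs[ei] == p) {
          g <- g + 1L  # genome symbol skipped before read position p
          ei <- ei + 1L
        }
        gch <- tmpl[g + 1L]
        if (ei <= nE && offs[ei] == p && type[ei] == "sub") {
          chars[p + 1L] <- .randBase(1, exclude = gch)
          g <- g + 1L
          ei <- ei + 1L
        } else if (ei <= nE && offs[ei] == p && type[ei] == "ins") {
          chars[p + 1L] <- .randBase(1)
          ei <- ei + 1L
        } else {
          chars[p + 1L] <- gch
          g <- g + 1L
        }
      }
      fwd <- paste(chars, collapse = "")
      rev <- stats::runif(1) < strandProb
      seqs[i] <- if (rev) revComp(fwd) else fwd
      truePos[i] <- start
      strand[i] <- if (rev) "-" else "+"
      edits[i] <- nE
      script[i] <- paste(ops, collapse = ";")
    }
    list(reads = data.frame(id = ids, seq = seqs, qual = qual,
                            stringsAsFactors = FALSE),
         truth = data.frame(readId = ids,
                            refName = names(genome@seqs)[recPick],
                            truePos = truePos, strand = strand,
                            edits = edits, script = script,
                            stringsAsFactors = FALSE))
  })
}

#' Write reads as FASTQ
#' @param reads data.frame with \code{id}, \code{seq}, \code{qual}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$qual), strrep("I", nchar(reads$seq)), reads$qual)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Write a truth table as TSV
#' @param truth data.frame from \code{\link{sampleReads}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Start-anchored distances of one oriented sequence over a start region
# [from, to) of a record (0-based local). Returns a list(start, dist) of the
# qualifying (<= k) starts.
.scanStarts <- function(seq, recSeq, from, to, k) {
  recLen <- nchar(recSeq)
  from <- max(0, from)
  to <- min(to, recLen)
  if (to <= from) return(NULL)
  m <- nchar(seq)
  textEnd <- min(recLen, to + m + k)
  text <- substr(recSeq, from + 1, textEnd)
  D <- cpp_start_distances(seq, text, k)
  n <- to - from
  keep <- which(D[seq_len(n)] <= k)
  if (length(keep) == 0) return(NULL)
  list(start = from + keep - 1, dist = D[keep])
}

#' Brute-force gold standard of mapping intervals
#'
#' For each read, scans the requested start positions on both strands with
#' the full dynamic-programming oracle (\code{\link{dpEditMatrix}} semantics,
#' start-anchored) and returns every maximal run of start positions within
#' distance k (runs separated by at most k failing starts are bridged, so
#' shifted shadows of one match form one interval) as one gold interval,
#' represented by its best start (Rabema's trace-equivalence collapsed to
#' interval membership). The reverse-strand
#' scan aligns the reverse-complemented read against the forward genome,
#' mirroring the mapper's convention.
#'
#' @param reads data.frame with \code{id} and \code{seq}.
#' @param genome a \linkS4class{Genome}.
#' @param k edit-distance threshold.
#' @param regions \code{NULL} to scan every position of every record
#'   (feasible only for small genomes), or a data.frame with columns
#'   \code{readId} (or \code{NA} for "all reads"), \code{refName},
#'   \code{from}, \code{to} (0-based half-open start-position ranges).
#' @return data.frame with one row per gold interval: \code{readId},
#'   \code{refName}, \code{strand}, \code{from}, \code{to} (run of
#'   qualifying starts, half-open), \code{goldStart} (best start),
#'   \code{dist} (its distance), \code{best} (whether the interval attains
#'   the read's minimum distance over all its intervals).
#' @export
goldStandard <- function(reads, genome, k, regions = NULL) {
  stopifnot(is.data.frame(reads), is(genome, "Genome"), k >= 0)
  recNames <- names(genome@seqs)
  if (is.null(regions))
    regions <- data.frame(readId = NA_character_,
                          refName = rep(recNames, each = 1),
                          from = 0,
                          to = nchar(genome@seqs),
                          stringsAsFactors = FALSE)
  shared <- regions[is.na(regions$readId), , drop = FALSE]
  perRead <- regions[!is.na(regions$readId), , drop = FALSE]
  perReadIdx <- split(seq_len(nrow(perRead)), perRead$readId)
  acc <- list(readId = list(), refName = list(), strand = list(),
              from = list(), to = list(), goldStart = list(), dist = list(),
              best = list())
  n.acc <- 0L
  for (i in seq_len(nrow(reads))) {
    id <- reads$id[i]
    fwd <- toupper(reads$seq[i])
    rcs <- revComp(fwd)
    ridx <- perReadIdx[[id]]
    regRef <- c(perRead$refName[ridx], shared$refName)
    regFrom <- c(perRead$from[ridx], shared$from)
    regTo <- c(perRead$to[ridx], shared$to)
    starts <- dists <- refs <- strands <- list()
    nh <- 0L
    for (j in seq_along(regRef)) {
      recSeq <- genome@seqs[[regRef[j]]]
      for (strand in c("+", "-")) {
        sc <- .scanStarts(if (strand == "+") fwd else rcs, recSeq,
                          regFrom[j], regTo[j], k)
        if (is.null(sc)) next
        nh <- nh + 1L
        starts[[nh]] <- sc$start
        dists[[nh]] <- sc$dist
        refs[[nh]] <- rep(regRef[j], length(sc$start))
        strands[[nh]] <- rep(strand, length(sc$start))
      }
    }
    if (nh == 0L) next
    start <- unlist(starts); dist <- unlist(dists)
    ref <- unlist(refs); strand <- unlist(strands)
    dup <- duplicated(paste(ref, strand, start, sep = "\r"))
    if (any(dup)) {
      start <- start[!dup]; dist <- dist[!dup]
      ref <- ref[!dup]; strand <- strand[!dup]
    }
    o <- order(ref, strand, start)
    start <- start[o]; dist <- dist[o]; ref <- ref[o]; strand <- strand[o]
    nq <- length(start)
    # runs of qualifying starts; gaps of up to k failing starts are bridged,
    # so shifted shadows of one match collapse into one interval
    grp <- cumsum(c(TRUE, ref[-1] != ref[-nq] | strand[-1] != strand[-nq] |
                      diff(start) > k + 1))
    bestIn <- vapply(split(seq_len(nq), grp),
                     function(ix) ix[which.min(dist[ix])], 1L)
    first <- vapply(split(seq_len(nq), grp), min, 1L)
    last <- vapply(split(seq_len(nq), grp), max, 1L)
    n.acc <- n.acc + 1L
    acc$readId[[n.acc]] <- rep(id, length(bestIn))
    acc$refName[[n.acc]] <- ref[bestIn]
    acc$strand[[n.acc]] <- strand[bestIn]
    acc$from[[n.acc]] <- start[first]
    acc$to[[n.acc]] <- start[last] + 1
    acc$goldStart[[n.acc]] <- start[bestIn]
    acc$dist[[n.acc]] <- dist[bestIn]
    acc$best[[n.acc]] <- dist[bestIn] == min(dist[bestIn])
  }
  res <- data.frame(readId = unlist(acc$readId) %||% character(0),
                    refName = unlist(acc$refName) %||% character(0),
                    strand = unlist(acc$strand) %||% character(0),
                    from = unlist(acc$from) %||% numeric(0),
                    to = unlist(acc$to) %||% numeric(0),
                    goldStart = unlist(acc$goldStart) %||% numeric(0),
                    dist = unlist(acc$dist) %||% integer(0),
                    best = unlist(acc$best) %||% logical(0),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.parseSam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand",
                                        "flag"),
                               tag = "NM",
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- b$tag$NM
  if (is.null(nm) || length(nm) != length(b$qname))
    nm <- rep(NA_integer_, length(b$qname))
  data.frame(readId = b$qname, refName = as.character(b$rname),
             pos = b$pos, strand = as.character(b$strand),
             nm = nm, stringsAsFactors = FALSE)
}

#' Rabema-style sensitivity of a SAM file against a gold standard
#'
#' Builds (or accepts) a brute-force gold standard of mapping intervals and
#' scores the alignments in a SAM file against it. A gold interval counts as
#' hit when the SAM reports, for the same read and strand, a position within
#' \code{[goldStart - k, goldStart + k]} (point containment; a
#' simplification of Rabema's trace equivalence suited to synthetic data).
#' Reported are the \emph{all} score (fraction of all intervals within k
#' that are hit), the \emph{all-best} score (fraction of minimum-distance
#' intervals hit) and the \emph{any-best} score (fraction of reads with at
#' least one minimum-distance interval hit).
#'
#' @param sam path to a SAM file of the same reads against \code{genome}.
#' @param truth truth table from \code{\link{sampleReads}} (used to restrict
#'   the oracle scan around the planted loci); ignored when \code{gold} is
#'   supplied or \code{scan = "full"}.
#' @param genome the reference \linkS4class{Genome}.
#' @param k edit-distance threshold.
#' @param reads the reads that were mapped.
#' @param scan \code{"restricted"} (default): scan start positions within
#'   \code{k} of each planted locus, plus \code{control}; \code{"full"}:
#'   scan every genome position for every read.
#' @param control \code{NULL}, or a list \code{(refName, from, to)}: a
#'   negative-control start region scanned exhaustively for every read.
#' @param gold optionally a precomputed \code{\link{goldStandard}} table.
#' @return list of class \code{"sensitivityReport"}: \code{all},
#'   \code{allBest}, \code{anyBest} (percent), \code{nIntervals},
#'   \code{nBest}, \code{nReads}, and the \code{gold} table with a
#'   \code{hit} column.
#' @export
evaluateSensitivity <- function(sam, truth = NULL, genome, k, reads,
                                scan = c("restricted", "full"),
                                control = NULL, gold = NULL) {
  scan <- match.arg(scan)
  stopifnot(is(genome, "Genome"), is.data.frame(reads))
  if (is.null(gold)) {
    regions <- NULL
    if (scan == "restricted") {
      if (is.null(truth)) stop("restricted scan needs a truth table")
      if (!all(truth$readId %in% reads$id))
        stop("truth/reads read-id mismatch")
      regions <- data.frame(readId = truth$readId,
                            refName = truth$refName,
                            from = truth$truePos - k,
                            to = truth$truePos + k + 1,
                            stringsAsFactors = FALSE)
      if (!is.null(control))
        regions <- rbind(regions,
                         data.frame(readId = NA_character_,
                                    refName = control$refName,
                                    from = control$from, to = control$to,
                                    stringsAsFactors = FALSE))
    }
    gold <- goldStandard(reads, genome, k, regions)
  }
  aln <- .parseSam(sam)
  if (!all(aln$readId %in% reads$id))
    stop("SAM contains read ids absent from `reads`")
  alnKey <- paste(aln$readId, aln$refName, aln$strand, sep = "\r")
  alnPos <- split(aln$pos - 1, alnKey)
  goldKey <- paste(gold$readId, gold$refName, gold$strand, sep = "\r")
  gold$hit <- vapply(seq_len(nrow(gold)), function(i) {
    p <- alnPos[[goldKey[i]]]
    !is.null(p) && any(abs(p - gold$goldStart[i]) <= k)
  }, logical(1))
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  best <- gold[gold$best, , drop = FALSE]
  perRead <- tapply(best$hit, best$readId, any)
  res <- list(all = pct(gold$hit),
              allBest = pct(best$hit),
              anyBest = pct(as.logical(perRead)),
              nIntervals = nrow(gold),
              nBest = nrow(best),
              nReads = length(perRead),
              gold = gold)
  class(res) <- "sensitivityReport"
  res
}

#' Write a sensitivity report as TSV
#'
#' One row per gold interval with its hit status, preceded by comment lines
#' summarising the scores and stating the scoring rule (point containment of
#' a reported position within k of the interval's best start — a
#' simplification of trace-equivalence scoring).
#'
#' @param report a report from \code{\link{evaluateSensitivity}}.
#' @param path output file.
#' @param k the threshold the report was computed at (echoed in the header).
#' @return Invisibly, \code{path}.
#' @export
writeSensitivityReport <- function(report, path, k = NA) {
  stopifnot(inherits(report, "sensitivityReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# Rabema-style sensitivity report (simplified scoring):",
    sprintf("# an interval counts as hit when a reported position lies within +/-%s of its best start (point containment, not full trace equivalence)",
            ifelse(is.na(k), "k", k)),
    sprintf("# all: %.4f %%  all-best: %.4f %%  any-best: %.4f %%",
            report$all, report$allBest, report$anyBest),
    sprintf("# intervals: %d  best-intervals: %d  reads: %d",
            report$nIntervals, report$nBest, report$nReads)), con)
  suppressWarnings(utils::write.table(report$gold, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @export
print.sensitivityReport <- function(x, ...) {
  cat("Sensitivity (interval hit = reported pos within +/-k of the gold start):\n")
  cat(sprintf("  all:      %6.2f %%  (%d intervals)\n", x$all, x$nIntervals))
  cat(sprintf("  all-best: %6.2f %%  (%d best intervals)\n", x$allBest, x$nBest))
  cat(sprintf("  any-best: %6.2f %%  (%d reads)\n", x$anyBest, x$nReads))
  invisible(x)
}
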