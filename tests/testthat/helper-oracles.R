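# Independent oracles and generators shared by the test files. Everything
# here is deliberately plain cell-by-cell R code with no bit tricks, so it
# exercises none of the code paths it is used to check.

# The semi-global DP recurrence evaluated only on the banded computing
# area (the 2k+1
# diagonals around the base diagonal, cells outside treated as +Inf), with
# the window implicitly sentinel-padded to m + 2k rows. This is the
# brute-force definition of what the banded bit-vector verifier computes.
bandedDP <- function(read, window, k) {
  m <- nchar(read); n <- nchar(window)
  R <- strsplit(read, "")[[1]]; W <- strsplit(window, "")[[1]]
  rows <- m + 2 * k
  INF <- 1e9
  D <- matrix(INF, rows + 1, m + 1)
  for (r in 0:(2 * k)) D[r + 1, 1] <- 0
  for (c in seq_len(m)) for (r in c:min(c + 2 * k, rows)) {
    wch <- if (r <= n) W[r] else "!"
    e <- if (wch == R[c] && wch != "N" && R[c] != "N") 0 else 1
    best <- D[r, c] + e
    if (r - 1 >= c) best <- min(best, D[r, c + 1] + 1)
    if (r <= c - 1 + 2 * k) best <- min(best, D[r + 1, c] + 1)
    D[r + 1, c + 1] <- best
  }
  cells <- D[(m:rows) + 1, m + 1]
  d <- min(cells)
  if (d > k) return(list(matched = FALSE, distance = NA_integer_,
                         bestEnd = NA_integer_))
  bi <- which.min(cells) - 1
  list(matched = TRUE, distance = as.integer(d),
       bestEnd = as.integer(min(m + bi, n) - 1))
}

# full semi-global DP minimum (free window start/end, read consumed)
fullSemiGlobal <- function(read, window) {
  C <- dpEditMatrix(read, window)
  min(C[nrow(C), ])
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# apply ne random edits (sub/ins/del) to a sequence
mutateSeq <- function(s, ne) {
  v <- strsplit(s, "")[[1]]
  for (i in seq_len(ne)) {
    p <- sample(length(v), 1)
    op <- sample(3, 1)
    if (op == 1) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    else if (op == 2 && length(v) > 1) v <- v[-p]
    else v <- append(v, sample(c("A", "C", "G", "T"), 1), after = p)
  }
  paste(v, collapse = "")
}

# an anchored verification instance: the read derives from the window
# substring starting at offset k (the base diagonal), so its match is
# band-contained by the pigeonhole/window-geometry argument
anchoredCase <- function(k, m0, maxEdits = k) {
  w <- randSeq(m0 + 2 * k)
  ne <- sample(0:maxEdits, 1)
  r <- mutateSeq(substr(w, k + 1, k + m0), ne)
  list(read = r, window = substr(w, 1, nchar(r) + 2 * k), ne = ne)
}

# all strings over an alphabet up to a length
allStrings <- function(maxLen, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(maxLen), function(len)
    do.call(paste0, expand.grid(rep(list(alphabet), len),
                                stringsAsFactors = FALSE))))
}

# edit count implied by replaying a CIGAR of read against a reference record
replayNM <- function(readSeq, refSeq, pos1, cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  ri <- 1L
  gi <- pos1
  nm <- 0L
  for (t in seq_along(ops)) {
    L <- lens[t]
    if (ops[t] == "M") {
      rs <- substr(readSeq, ri, ri + L - 1)
      gs <- substr(refSeq, gi, gi + L - 1)
      nm <- nm + sum(strsplit(rs, "")[[1]] != strsplit(gs, "")[[1]])
      ri <- ri + L; gi <- gi + L
    } else if (ops[t] == "I") {
      nm <- nm + L; ri <- ri + L
    } else if (ops[t] == "D") {
      nm <- nm + L; gi <- gi + L
    }
  }
  nm
}
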