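test_that("the threshold rule reproduces the standard per-length values", {
  expect_equal(effectiveK(c(100, 151, 300), mapConfig()), c(5L, 7L, 15L))
  expect_equal(effectiveK(100, mapConfig(k = 3)), 3L)
  expect_equal(effectiveK(19, mapConfig()), 0L)
  expect_equal(defaultQ(100, 5), 16L)
  expect_equal(defaultQ(60, 5), 10L)
})

test_that("a planted read is recovered at exactly its locus, forward only", {
  set.seed(61)
  g <- randomGenome(30000, seed = 611)
  idx <- buildIndex(g, 16)
  s0 <- 12345
  read <- substr(recordSeqs(g)[[1]], s0 + 1, s0 + 100)
  mp <- mapRead(read, idx, g, mapConfig(k = 5))
  expect_equal(nrow(mp), 1)
  expect_equal(mp$pos, s0 + 1)     # 1-based SAM-style position
  expect_equal(mp$strand, "+")
  expect_equal(mp$distance, 0)
  expect_equal(mp$cigar, "100M")

  # reverse-complemented read maps to the same locus on the minus strand
  mpR <- mapRead(revComp(read), idx, g, mapConfig(k = 5))
  expect_equal(nrow(mpR), 1)
  expect_equal(mpR$pos, s0 + 1)
  expect_equal(mpR$strand, "-")

  # a read with no index hits maps nowhere
  noA <- mapRead(strrep("A", 50), buildIndex(Genome(c(r = strrep("C", 500))), 10),
                 Genome(c(r = strrep("C", 500))), mapConfig(k = 2))
  expect_equal(nrow(noA), 0)
})

test_that("mapping equals the brute-force full-scan oracle on planted edits", {
  set.seed(67)
  g <- randomGenome(c(chrA = 15000, chrB = 6000), gc = 0.45, seed = 671)
  idx <- buildIndex(g, 16)
  sim <- sampleReads(g, m = 100, count = 40, maxEdits = 5, seed = 672)
  mp <- mapReads(sim$reads, idx, g, mapConfig(k = 5))
  gold <- goldStandard(sim$reads, g, k = 5)   # exhaustive full-genome scan

  # no false negatives: every gold interval holds a reported position
  # no false positives: every reported position is a gold start within k,
  # with the oracle's distance
  for (i in seq_len(nrow(mp))) {
    seq <- sim$reads$seq[match(mp$readId[i], sim$reads$id)]
    if (mp$strand[i] == "-") seq <- revComp(seq)
    rec <- recordSeqs(g)[[mp$refName[i]]]
    s0 <- mp$pos[i] - 1
    d <- qgmapper:::cpp_start_distances(
      seq, substr(rec, s0 + 1, min(nchar(rec), s0 + nchar(seq) + 5)))[1]
    expect_lte(d, 5)
    expect_equal(mp$distance[i], d)
  }
  key <- paste(mp$readId, mp$refName, mp$strand)
  pos0 <- split(mp$pos - 1, key)
  gkey <- paste(gold$readId, gold$refName, gold$strand)
  hit <- vapply(seq_len(nrow(gold)), function(i) {
    p <- pos0[[gkey[i]]]
    !is.null(p) && any(p >= gold$from[i] - 5 & p < gold$to[i] + 5)
  }, logical(1))
  expect_true(all(hit))
})

test_that("strand symmetry: mapping rc(read) mirrors the strands", {
  set.seed(71)
  g <- randomGenome(20000, seed = 711)
  idx <- buildIndex(g, 16)
  sim <- sampleReads(g, m = 100, count = 15, maxEdits = 4, seed = 712)
  a <- mapReads(sim$reads, idx, g, mapConfig(k = 5))
  rc <- sim$reads
  rc$seq <- revComp(rc$seq)
  b <- mapReads(rc, idx, g, mapConfig(k = 5))
  flip <- function(s) ifelse(s == "+", "-", "+")
  expect_equal(a[order(a$readId, a$pos, a$strand),
                 c("readId", "refName", "pos", "distance")],
               b[order(b$readId, b$pos, b$strand),
                 c("readId", "refName", "pos", "distance")],
               ignore_attr = TRUE)
  expect_equal(sort(paste(a$readId, a$pos, flip(a$strand))),
               sort(paste(b$readId, b$pos, b$strand)))
})

test_that("reads too short for seeding are unmapped with a warning, not an error", {
  g <- randomGenome(5000, seed = 73)
  idx <- buildIndex(g, 16)
  rd <- data.frame(id = "tiny", seq = randSeq(40))  # needs (5+1)*16 = 96 at k=5
  expect_warning(mp <- mapReads(rd, idx, g, mapConfig(k = 5)), "too short")
  expect_equal(nrow(mp), 0)
  sam <- tempfile(fileext = ".sam")
  writeSam(mp, rd, g, sam)
  body <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  expect_equal(length(body), 1)
  expect_equal(strsplit(body, "\t")[[1]][2], "4")
})

test_that("SAM output is spec-compliant and parses back", {
  set.seed(79)
  g <- randomGenome(c(chr1 = 12000), seed = 791,
                    repeats = list(length = 300, copies = 2))
  idx <- buildIndex(g, 16)
  sim <- sampleReads(g, m = 100, count = 25, maxEdits = 4, seed = 792)
  mp <- mapReads(sim$reads, idx, g, mapConfig(k = 5))
  sam <- tempfile(fileext = ".sam")
  writeSam(mp, sim$reads, g, sam)
  lines <- readLines(sam)
  expect_equal(lines[1], "@HD\tVN:1.6\tSO:unsorted")
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:12000$", lines)))
  expect_true(any(startsWith(lines, "@PG")))

  body <- strsplit(grep("^@", lines, invert = TRUE, value = TRUE), "\t")
  expect_equal(length(body), max(nrow(mp), 0) +
                 sum(!sim$reads$id %in% mp$readId))
  for (f in body) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) {
      expect_equal(f[3], "*"); expect_equal(f[4], "0"); expect_equal(f[6], "*")
    } else {
      expect_true(f[3] %in% names(g))
      expect_gte(as.integer(f[4]), 1)
      # NM equals the CIGAR replay distance against the reference
      nm <- as.integer(sub("NM:i:", "", f[12]))
      seq <- f[10]
      expect_equal(replayNM(seq, recordSeqs(g)[[f[3]]], as.integer(f[4]), f[6]),
                   nm)
      # alignment stays within the record
    }
  }
  # secondary-alignment flag on every line after the first of a read
  mappedLines <- body[vapply(body, function(f) bitwAnd(as.integer(f[2]), 4L) == 0, TRUE)]
  qn <- vapply(mappedLines, `[`, "", 1)
  sec <- vapply(mappedLines, function(f) bitwAnd(as.integer(f[2]), 256L) > 0, TRUE)
  expect_equal(unname(sec), duplicated(qn))

  # parses under Rsamtools (via BAM conversion round-trip)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  parsed <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(parsed$qname), length(body))

  # byte-identical output on a second run over the same inputs
  mp2 <- mapReads(sim$reads, idx, g, mapConfig(k = 5))
  sam2 <- tempfile(fileext = ".sam")
  writeSam(mp2, sim$reads, g, sam2)
  expect_identical(readLines(sam2), lines)
})
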