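test_that("the genome generator is seeded, GC-true and can plant repeats", {
  g1 <- randomGenome(1000, gc = 0.5, seed = 7)
  g2 <- randomGenome(1000, gc = 0.5, seed = 7)
  expect_identical(recordSeqs(g1), recordSeqs(g2))

  gc1 <- randomGenome(2000, gc = 1, seed = 8)
  expect_false(grepl("[AT]", recordSeqs(gc1)[[1]]))
  gc0 <- randomGenome(2000, gc = 0, seed = 8)
  expect_false(grepl("[GC]", recordSeqs(gc0)[[1]]))

  gr <- randomGenome(5000, seed = 9, repeats = list(length = 200, copies = 3))
  s <- recordSeqs(gr)[[1]]
  # some 200-mer occurs at least 3 times
  found <- FALSE
  for (p in 1:(nchar(s) - 199)) {
    seg <- substr(s, p, p + 199)
    n <- length(gregexpr(seg, s, fixed = TRUE)[[1]])
    if (n >= 3) { found <- TRUE; break }
  }
  expect_true(found)

  # multiple records with names
  gm <- randomGenome(c(a = 100, b = 50), seed = 10)
  expect_equal(names(gm), c("a", "b"))
  expect_equal(totalLength(gm), 150)
})

test_that("sampled reads are reproducible with truthful edit bookkeeping", {
  g <- randomGenome(20000, seed = 21)
  s1 <- sampleReads(g, m = 80, count = 30, maxEdits = 4, seed = 22)
  s2 <- sampleReads(g, m = 80, count = 30, maxEdits = 4, seed = 22)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1$reads$seq) == 80))
  expect_true(all(s1$truth$edits <= 4))
  expect_equal(s1$truth$edits, lengths(gregexpr("[a-z]+@", paste0(s1$truth$script, ";"))) -
                 as.integer(s1$truth$script == ""),
               ignore_attr = TRUE)

  # with no edits every read is an exact genome substring (on its strand)
  s0 <- sampleReads(g, m = 60, count = 20, maxEdits = 0, seed = 23)
  for (i in 1:20) {
    seq <- s0$reads$seq[i]
    if (s0$truth$strand[i] == "-") seq <- revComp(seq)
    expect_equal(substr(recordSeqs(g)[[s0$truth$refName[i]]],
                        s0$truth$truePos[i] + 1, s0$truth$truePos[i] + 60), seq)
  }

  # with edits, the planted locus is within `edits` of the read by the oracle
  se <- sampleReads(g, m = 80, count = 25, maxEdits = 5, seed = 24)
  for (i in 1:25) {
    seq <- se$reads$seq[i]
    if (se$truth$strand[i] == "-") seq <- revComp(seq)
    rec <- recordSeqs(g)[[se$truth$refName[i]]]
    s0i <- se$truth$truePos[i]
    d <- qgmapper:::cpp_start_distances(
      seq, substr(rec, s0i + 1, s0i + 95))[1]
    expect_lte(d, se$truth$edits[i])
  }

  expect_error(sampleReads(g, m = 50000, count = 1), "long enough")
})

test_that("gold-standard intervals agree with the DP matrix oracle", {
  set.seed(83)
  g <- randomGenome(8000, seed = 831)
  sim <- sampleReads(g, m = 70, count = 10, maxEdits = 3, seed = 832)
  gold <- goldStandard(sim$reads, g, k = 4)
  expect_gte(nrow(gold), 10)
  for (i in seq_len(nrow(gold))) {
    seq <- sim$reads$seq[match(gold$readId[i], sim$reads$id)]
    if (gold$strand[i] == "-") seq <- revComp(seq)
    rec <- recordSeqs(g)[[gold$refName[i]]]
    s0 <- gold$goldStart[i]
    # start-anchored distance via the full DP matrix on the local window:
    # fix the start by trimming the text at s0
    C <- dpEditMatrix(seq, substr(rec, s0 + 1, min(nchar(rec), s0 + nchar(seq) + 4)))
    expect_equal(min(C[nrow(C), ]), gold$dist[i])
  }
  # every read's best interval covers its planted locus
  best <- gold[gold$best, ]
  for (i in seq_len(nrow(sim$truth))) {
    b <- best[best$readId == sim$truth$readId[i], ]
    expect_true(any(b$refName == sim$truth$refName[i] &
                      abs(b$goldStart - sim$truth$truePos[i]) <= 4))
  }
})

test_that("the sensitivity report scores hits, self-consistency and emptiness", {
  set.seed(89)
  g <- randomGenome(10000, seed = 891)
  idx <- buildIndex(g, 10)
  sim <- sampleReads(g, m = 60, count = 12, maxEdits = 2, seed = 892)
  k <- 3
  gold <- goldStandard(sim$reads, g, k)

  # a SAM built from the gold standard itself scores 100 everywhere
  mk <- gold
  mappings <- data.frame(readId = mk$readId, refName = mk$refName,
                         pos = mk$goldStart + 1, strand = mk$strand,
                         distance = mk$dist, cigar = sprintf("%dM", 60),
                         nm = mk$dist, stringsAsFactors = FALSE)
  sam <- tempfile(fileext = ".sam")
  writeSam(mappings, sim$reads, g, sam)
  rep <- evaluateSensitivity(sam, genome = g, k = k, reads = sim$reads,
                             gold = gold)
  expect_equal(rep$all, 100)
  expect_equal(rep$allBest, 100)
  expect_equal(rep$anyBest, 100)

  # an all-unmapped SAM scores 0
  empty <- tempfile(fileext = ".sam")
  writeSam(mappings[0, ], sim$reads, g, empty)
  rep0 <- evaluateSensitivity(empty, genome = g, k = k, reads = sim$reads,
                              gold = gold)
  expect_equal(rep0$all, 0)
  expect_equal(rep0$allBest, 0)
  expect_equal(rep0$anyBest, 0)

  # the mapper's own output on defaults reaches the oracle's scores
  mp <- mapReads(sim$reads, idx, g, mapConfig(k = k))
  samM <- tempfile(fileext = ".sam")
  writeSam(mp, sim$reads, g, samM)
  repM <- evaluateSensitivity(samM, genome = g, k = k, reads = sim$reads,
                              gold = gold)
  expect_equal(repM$allBest, 100)
  expect_equal(repM$anyBest, 100)
  expect_output(print(repM), "all-best")

  tsv <- tempfile(fileext = ".tsv")
  writeSensitivityReport(repM, tsv, k = k)
  lns <- readLines(tsv)
  expect_true(any(grepl("point containment", lns)))
  tab <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(nrow(tab), repM$nIntervals)
  expect_true(all(tab$hit))
})
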