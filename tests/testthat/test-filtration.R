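test_that("reads partition into k+1 leftmost-packed seeds", {
  p <- partitionRead(strrep("ACGT", 3), k = 2, q = 4)
  expect_equal(p$offset, c(0, 4, 8))
  expect_equal(p$gram, rep("ACGT", 3))

  p <- partitionRead(randSeq(100), k = 5, q = 16)
  expect_equal(nrow(p), 6)
  expect_equal(p$offset, 16 * (0:5))
  # non-overlapping: consecutive offsets differ by exactly q
  expect_true(all(diff(p$offset) >= 16))

  expect_warning(r <- partitionRead(randSeq(10), k = 2, q = 4), "too short")
  expect_null(r)
})

test_that("candidate anchors follow d = dq - c with m+2k windows", {
  set.seed(23)
  g <- Genome(c(chr = randSeq(5000)))
  q <- 10
  idx <- buildIndex(g, q)
  m <- 60
  k <- 2
  read <- substr(recordSeqs(g)[[1]], 1001, 1000 + m)  # planted at d = 1000
  cand <- candidatesForRead(read, idx, g, k)
  expect_true(1000 %in% cand$anchor)
  row <- cand[cand$anchor == 1000, ]
  expect_equal(row$windowStart, 1000 - k)
  expect_equal(row$windowEnd, 1000 + m + k)
  expect_equal(row$windowEnd - row$windowStart, m + 2 * k)

  # anchors deduplicated: all seeds of an exact read imply the same d once
  expect_equal(anyDuplicated(cand[c("anchor", "record")]), 0)
  # sorted output
  expect_false(is.unsorted(cand$anchor))

  # anchor near the record start is clamped, not dropped
  readStart <- substr(recordSeqs(g)[[1]], 1, m)
  cand2 <- candidatesForRead(readStart, idx, g, k)
  expect_true(0 %in% cand2$anchor)
  expect_equal(cand2$windowStart[cand2$anchor == 0], 0)
})

test_that("pigeonhole filtration is fully sensitive on planted edits", {
  # for every genome location within k edits of the read, some seed matches
  # exactly, so the corresponding anchor must be generated
  set.seed(29)
  g <- Genome(c(chr = randSeq(4000)))
  k <- 3
  m0 <- 48
  q <- defaultQ(m0, k)  # 12: 4 seeds fit
  idx <- buildIndex(g, q)
  for (it in 1:40) {
    s0 <- sample(3800, 1)
    read <- mutateSeq(substr(recordSeqs(g)[[1]], s0 + 1, s0 + m0),
                      sample(0:k, 1))
    if (nchar(read) < (k + 1) * q) next
    cand <- candidatesForRead(read, idx, g, k)
    # gold locations via the brute-force start-anchored oracle
    D <- qgmapper:::cpp_start_distances(read, recordSeqs(g)[[1]])
    for (s in which(D <= k) - 1) {
      # an anchor within k of the true start must exist (window covers it)
      expect_true(any(abs(cand$anchor - s) <= k),
                  label = sprintf("anchor near %d (it %d)", s, it))
    }
  }
})

test_that("the occurrence cap drops over-frequent seeds and only them", {
  g <- Genome(c(r = paste0(strrep("ACGTACGTACGT", 30), "GATTACAGCCTA")))
  idx <- buildIndex(g, 12)
  read <- "ACGTACGTACGTGATTACAGCCTA"  # seed 1 repetitive, seed 2 unique
  full <- candidatesForRead(read, idx, g, k = 1)
  capped <- candidatesForRead(read, idx, g, k = 1, occCap = 3)
  expect_gt(nrow(full), nrow(capped))
  # anchors from the rare seed survive
  expect_true(all(capped$anchor %in% full$anchor))
  expect_gt(nrow(capped), 0)
})

test_that("count-filtering threshold matches the closed form", {
  expect_equal(countFilterThreshold(100, 4, 10), 51L)
  expect_equal(countFilterThreshold(100, 5, 16), 5L)
  expect_error(countFilterThreshold(50, 4, 12), "undefined")
})
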