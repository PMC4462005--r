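test_that("the DP matrix implements the semi-global recurrence", {
  C <- dpEditMatrix("ACGT", "ACGT")
  expect_equal(C[1, ], rep(0L, 5))        # C[0, j] = 0
  expect_equal(C[, 1], 0:4)               # C[i, 0] = i
  expect_equal(min(C[5, ]), 0)

  expect_equal(semiGlobalDist("ACGT", "TTACGTTT"), 0)  # exact substring
  expect_equal(semiGlobalDist("ACGT", "AGT"), 1)       # one deletion suffices
  expect_equal(semiGlobalDist("AAAA", "CCCC"), 4)
  # N mismatches everything, including N
  expect_equal(semiGlobalDist("AN", "AN"), 1)
  expect_error(dpEditMatrix("", "ACGT"), "non-empty")

  # adjacency property that the delta encoding exploits
  set.seed(31)
  for (it in 1:20) {
    C <- dpEditMatrix(randSeq(sample(2:12, 1)), randSeq(sample(2:12, 1)))
    expect_true(all(abs(diff(C)) <= 1))       # vertical deltas
    expect_true(all(abs(t(diff(t(C)))) <= 1)) # horizontal deltas
  }
})

test_that("banded verifier equals the plain banded DP on a small exhaustive grid", {
  # the heavy exhaustive grid lives in the acceptance suite; here a smaller
  # slice guards the kernel during development
  strs <- allStrings(4)
  for (k in 0:2) for (r in strs) for (w in strs) {
    if (nchar(w) > nchar(r) + 2 * k) next
    o <- bandedDP(r, w, k)
    b <- bandedMyers(r, w, k)
    expect_identical(b$matched, o$matched)
    if (o$matched) {
      expect_identical(b$distance, o$distance)
      expect_identical(b$bestEnd, o$bestEnd)
    }
  }
})

test_that("banded verifier agrees with the full DP on anchored instances", {
  expect_equal(bandedMyers("ACGTAC", "ACGTAC", k = 2)$distance, 0)
  expect_equal(bandedMyers("ACGTAC", "ACGTAC", k = 2)$bestEnd, 5)

  b <- bandedMyers(strrep("A", 20), strrep("C", 20), k = 3)
  expect_false(b$matched)
  expect_true(b$cut)

  set.seed(37)
  for (it in 1:400) {
    k <- sample(0:7, 1)
    a <- anchoredCase(k, sample(60:160, 1))
    full <- fullSemiGlobal(a$read, a$window)
    b <- bandedMyers(a$read, a$window, k)
    if (full <= k) {
      expect_true(b$matched)
      expect_identical(b$distance, as.integer(full))
      # reported end really achieves the distance in the full DP
      C <- dpEditMatrix(a$read, a$window)
      expect_identical(C[nrow(C), b$bestEnd + 2], as.integer(full))
    } else {
      expect_false(b$matched)
    }
  }
})

test_that("packing arithmetic and state layout follow the slot design", {
  ws <- replicate(3, randSeq(20))
  ps <- packPatterns(ws, k = 4, wordWidth = 128)
  expect_s4_class(ps, "PackedState")
  expect_equal(ps@slotCapacity, 12L)
  expect_equal(ps@slotWidth, 10L)
  expect_equal(packPatterns(ws, k = 4, wordWidth = 64)@slotCapacity, 6L)
  expect_equal(packPatterns(ws, k = 7, wordWidth = 128)@slotCapacity, 8L)
  expect_equal(defaultSlots(4, 128), 8L)
  expect_equal(defaultSlots(15, 128), 4L)

  # VP, VN, E zeroed; Peq holds the first 2k+1 symbols per slot
  expect_true(all(ps@VP == as.raw(0)))
  expect_true(all(ps@VN == as.raw(0)))
  expect_true(all(ps@E == as.raw(0)))
  bits <- function(raws) as.integer(rawToBits(raws))
  peqA <- bits(ps@Peq[[1]])
  for (l in 1:3) {
    slotBits <- peqA[(l - 1) * 10 + 1:9]
    wanted <- as.integer(strsplit(substr(ws[l], 1, 9), "")[[1]] == "A")
    expect_equal(slotBits, wanted)
  }
  # buffer bit of every slot is clear in every Peq plane
  for (a in 1:4) {
    bb <- bits(ps@Peq[[a]])[10 * (1:12)]
    expect_true(all(bb == 0))
  }

  expect_error(packPatterns(replicate(13, randSeq(10)), 4, 128),
               "too many patterns")
  expect_error(bandedMyers("ACGT", "ACGT", k = 40), "word width")
})

test_that("packed verification equals the scalar verifier slot by slot", {
  h <- vectorizedBandedMyers(strrep("ACGT", 5),
                             packPatterns(rep(strrep("ACGT", 5), 6), k = 2),
                             validate = TRUE)
  expect_true(all(h$matched))
  expect_true(all(h$distance == 0))
  expect_equal(length(unique(h$bestEnd)), 1)

  # one zero-distance window among hopeless ones: slot independence
  r <- randSeq(40)
  ws <- c(strrep("C", 40), r, strrep("G", 40))
  v <- vectorizedBandedMyers(r, packPatterns(ws, k = 3), validate = TRUE)
  expect_equal(v$matched, c(FALSE, TRUE, FALSE))
  expect_equal(v$distance[2], 0)

  set.seed(41)
  for (it in 1:150) {
    k <- sample(0:7, 1)
    m0 <- sample(20:120, 1)
    r <- randSeq(m0)
    for (W in c(64L, 128L)) {
      np <- sample(seq_len(slotCapacity(k, W)), 1)
      ws <- vapply(seq_len(np), function(i) {
        if (runif(1) < 0.5)
          substr(paste0(mutateSeq(r, sample(0:(k + 2), 1)), randSeq(2 * k + 4)),
                 1, m0 + 2 * k)
        else randSeq(sample(max(1, m0 - k):(m0 + 2 * k), 1))
      }, "")
      pv <- vectorizedBandedMyers(r, packPatterns(ws, k, W), validate = TRUE)
      for (i in seq_len(np)) {
        sc <- bandedMyers(r, ws[i], k)
        expect_identical(pv$matched[i], sc$matched)
        expect_identical(pv$distance[i], sc$distance)
        expect_identical(pv$bestEnd[i], sc$bestEnd)
      }
    }
  }
})

test_that("slots are isolated: changing one window never affects another", {
  set.seed(43)
  for (it in 1:60) {
    k <- sample(1:6, 1)
    m0 <- sample(30:80, 1)
    r <- randSeq(m0)
    np <- sample(2:slotCapacity(k, 128), 1)
    ws <- vapply(seq_len(np), function(i)
      substr(mutateSeq(r, sample(0:(2 * k), 1)), 1, m0 + 2 * k), "")
    base <- vectorizedBandedMyers(r, packPatterns(ws, k), validate = TRUE)
    tgt <- sample(np, 1)
    ws2 <- ws
    ws2[tgt] <- randSeq(nchar(ws[tgt]))
    pert <- vectorizedBandedMyers(r, packPatterns(ws2, k), validate = TRUE)
    other <- setdiff(seq_len(np), tgt)
    expect_identical(pert$matched[other], base$matched[other])
    expect_identical(pert$distance[other], base$distance[other])
    expect_identical(pert$bestEnd[other], base$bestEnd[other])
  }
})

test_that("branch-cut changes runtime only, never results", {
  set.seed(47)
  for (it in 1:200) {
    k <- sample(0:5, 1)
    m0 <- sample(30:80, 1)
    r <- randSeq(m0)
    w <- if (runif(1) < 0.5)
      substr(mutateSeq(paste0(randSeq(k), r, randSeq(k)), sample(0:3, 1)),
             1, m0 + 2 * k)
    else randSeq(m0 + 2 * k)
    b1 <- bandedMyers(r, w, k, branchCut = TRUE)
    b2 <- bandedMyers(r, w, k, branchCut = FALSE)
    expect_identical(b1[c("matched", "distance", "bestEnd")],
                     b2[c("matched", "distance", "bestEnd")])
    v1 <- vectorizedBandedMyers(r, packPatterns(w, k), branchCut = TRUE)
    v2 <- vectorizedBandedMyers(r, packPatterns(w, k), branchCut = FALSE)
    expect_identical(v1[c("matched", "distance", "bestEnd")],
                     v2[c("matched", "distance", "bestEnd")])
  }
})

test_that("increasing k never loses matches", {
  set.seed(53)
  for (it in 1:50) {
    m0 <- sample(30:60, 1)
    w0 <- randSeq(m0 + 14)
    r <- mutateSeq(substr(w0, 8, 7 + m0), sample(0:5, 1))
    prev <- NULL
    for (k in 0:7) {
      b <- bandedMyers(r, substr(w0, 1, nchar(r) + 2 * k), k)
      if (!is.null(prev) && prev$matched) {
        expect_true(b$matched)
        expect_lte(b$distance, prev$distance)
      }
      prev <- b
    }
  }
})

test_that("traceback produces replayable CIGARs anchored at the right start", {
  m <- 100
  r <- randSeq(m)
  w <- paste0(randSeq(5), r, randSeq(5))
  b <- bandedMyers(r, w, k = 5)
  tb <- tracebackCigar(r, w, 5, b$bestEnd)
  expect_equal(tb$cigar, "100M")
  expect_equal(tb$nm, 0)
  expect_equal(tb$alnStart, 5)

  # one deletion in the read relative to the window
  w2 <- paste0(substr(r, 1, 40), "T", substr(r, 41, m))
  w2 <- paste0(w2, randSeq(1))  # keep |w| <= m + 2k slack
  b2 <- bandedMyers(r, w2, k = 2)
  tb2 <- tracebackCigar(r, w2, 2, b2$bestEnd)
  expect_match(tb2$cigar, "1D")
  expect_equal(tb2$nm, 1)

  expect_error(tracebackCigar("AAAA", "CCCC", 1, 3), "non-match")

  # random matched pairs: nm from CIGAR replay equals the verified distance,
  # and M+I lengths sum to the read length
  set.seed(59)
  for (it in 1:150) {
    k <- sample(1:6, 1)
    a <- anchoredCase(k, sample(40:120, 1))
    b <- bandedMyers(a$read, a$window, k)
    if (!b$matched) next
    tb <- tracebackCigar(a$read, a$window, k, b$bestEnd)
    expect_equal(tb$distance, b$distance)
    expect_equal(tb$nm, b$distance)
    lens <- as.integer(regmatches(tb$cigar, gregexpr("[0-9]+", tb$cigar))[[1]])
    ops <- regmatches(tb$cigar, gregexpr("[MID]", tb$cigar))[[1]]
    expect_equal(sum(lens[ops %in% c("M", "I")]), nchar(a$read))
    expect_equal(replayNM(a$read, a$window, tb$alnStart + 1, tb$cigar), tb$nm)
  }
})
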