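test_that("window trim indices match the stated examples", {
  # 100 scores of 20: every window sums to exactly 400
  expect_equal(qualityTrimIndices(rep(20L, 100)), c(0L, 99L))
  # ten 2s then thirty 30s: first qualifying window starts at 0-based 3
  q <- c(rep(2L, 10), rep(30L, 30))
  expect_equal(qualityTrimIndices(q), c(3L, 39L))
  expect_equal(qualityTrimIndices(q), bruteTrimIndices(q))
  # 60 scores of 10: max window sum 200 < 400
  expect_null(qualityTrimIndices(rep(10L, 60)))
  # shorter than the window: no window exists
  expect_null(qualityTrimIndices(rep(40L, 10)))
})

test_that("trim indices agree with the brute-force window scan", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:150, 1)
    q <- sample(0:45, n, replace = TRUE)
    expect_identical(qualityTrimIndices(q), bruteTrimIndices(q))
  }
})

test_that("quality trimming is idempotent and never grows a read", {
  set.seed(7)
  for (i in 1:50) {
    q <- sample(0:45, sample(20:200, 1), replace = TRUE)
    idx <- qualityTrimIndices(q)
    if (is.null(idx)) next
    expect_lte(idx[2] - idx[1] + 1, length(q))
    trimmed <- q[(idx[1] + 1):(idx[2] + 1)]
    expect_equal(qualityTrimIndices(trimmed), c(0L, length(trimmed) - 1L))
  }
})

test_that("vector and quality trims combine by max/min", {
  # quality (3, 600), vector bounds [10, 550): interval covers 10..549
  tr <- applyTrim(700L, c(3L, 600L), vectorBounds = c(10L, 550L))
  expect_equal(tr$start, 10L)
  expect_equal(tr$end, 550L)
  expect_equal(tr$class, "long")
  # no vector record: quality indices alone
  tr2 <- applyTrim(700L, c(3L, 600L))
  expect_equal(c(tr2$start, tr2$end), c(3L, 601L))
  # trimmed length 49 is below the retention floor
  expect_equal(applyTrim(100L, c(0L, 48L))$class, "discarded")
  # empty quality indices
  expect_equal(applyTrim(100L, NULL)$class, "discarded")
  # inverted vector bounds discard rather than error
  expect_equal(applyTrim(100L, c(0L, 99L), vectorBounds = c(60L, 40L))$class,
               "discarded")
  # vector positions outside the read are rejected
  expect_error(applyTrim(100L, c(0L, 99L), vectorBounds = c(0L, 150L)),
               "outside")
})

test_that("length classes partition at 200 and 50", {
  classOf <- function(len) applyTrim(1000L, c(0L, len - 1L))$class
  expect_equal(classOf(250), "long")
  expect_equal(classOf(120), "short")
  expect_equal(classOf(30), "discarded")
  expect_equal(classOf(200), "long")    # "200 bases or greater"
  expect_equal(classOf(50), "short")    # "greater than or equal to 50"
  trimmed <- data.table::data.table(
    class = vapply(c(250, 120, 30, 200, 50, 49), classOf, character(1)))
  p <- partitionReads(trimmed)
  expect_equal(unname(p$counts), c(2L, 2L, 2L))
  expect_equal(sum(p$counts), nrow(trimmed))
})

test_that("trimming a simulated read set maps coordinates through", {
  ts <- simulateTruth(c(chr1 = 20000), hetRate = 0, refErrorRate = 0,
                      bContribRate = 0, seed = 3)
  rs <- simulateSangerReads(ts, targetDepth = 3, seed = 3)
  tr <- trimSangerReads(rs)
  expect_true(all(tr$trimEnd - tr$trimStart <= tr$origLen))
  kept <- tr[tr$class != "discarded", ]
  expect_gt(nrow(kept), 0)
  # trimmed sequences must match the genome at their mapped-through coords
  chr <- as.character(refSequences(ts))[["chr1"]]
  for (i in seq_len(min(nrow(kept), 25))) {
    g <- substr(chr, kept$gStart[i], kept$gEnd[i])
    readSeq <- if (kept$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(kept$seq[i])))
    else kept$seq[i]
    expect_identical(readSeq, g)
  }
})

test_that("short-read filter applies its five steps in order", {
  mk <- function(seqs, quals) {
    n <- length(seqs)
    df <- data.frame(name = paste0("s", seq_len(n)), seq = seqs,
                     stringsAsFactors = FALSE)
    df$qual <- quals
    df
  }
  # step 1: Q30 fraction (60% kept, 40% removed)
  r1 <- mk(c(strrep("A", 10), strrep("C", 10)),
           list(c(rep(31L, 6), rep(10L, 4)), c(rep(31L, 4), rep(10L, 6))))
  rs <- new("ShortReadSet", r1 = r1, r2 = r1)
  f <- shortReadFilter(rs, q30Fraction = 0.5, minLen = 1L)
  expect_equal(readPairs(f)$r1$name, "s1")

  # step 2: 3' bases below quality 3 trimmed until the floor is met
  r1 <- mk(strrep("A", 4), list(c(30L, 30L, 2L, 1L)))
  f <- shortReadFilter(new("ShortReadSet", r1 = r1, r2 = r1), minLen = 1L)
  expect_equal(readPairs(f)$r1$seq, "AA")

  # step 3: exact 3' adapter clip
  r1 <- mk(paste0(strrep("G", 60), "AGATCGGAAG"), list(rep(35L, 70)))
  f <- shortReadFilter(new("ShortReadSet", r1 = r1, r2 = r1),
                       adapter = "AGATCGGAAG")
  expect_equal(readPairs(f)$r1$seq, strrep("G", 60))

  # step 4: post-trim length 49 removes the pair
  r1 <- mk(strrep("A", 50), list(c(rep(35L, 49), 1L)))
  f <- shortReadFilter(new("ShortReadSet", r1 = r1, r2 = r1))
  expect_equal(nrow(readPairs(f)$r1), 0L)

  # step 5: a pair survives only if both mates survive
  good <- list(rep(35L, 60))
  bad <- list(rep(10L, 60))
  r1 <- mk(strrep("A", 60), good)
  r2 <- mk(strrep("T", 60), bad)
  f <- shortReadFilter(new("ShortReadSet", r1 = r1, r2 = r2))
  expect_equal(nrow(readPairs(f)$r1), 0L)
})
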