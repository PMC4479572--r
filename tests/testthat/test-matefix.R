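test_that("FLAG assembly reproduces the printed bit constants", {
  expect_equal(computeFlag(mapped = TRUE, reverse = FALSE), 0L)
  expect_equal(computeFlag(mapped = TRUE, reverse = TRUE), 16L)
  expect_equal(computeFlag(mapped = FALSE), 4L)
  expect_equal(computeFlag(exemplar = FALSE), 1024L)
  expect_equal(computeFlag(primary = FALSE), 256L)
  expect_equal(computeFlag(mateUsed = TRUE, direction = "F"), 65L)      # 1 + 64
  expect_equal(computeFlag(mateUsed = TRUE, direction = "R"), 129L)     # 1 + 128
  expect_equal(computeFlag(mateUsed = TRUE, direction = "F",
                           mateMapped = FALSE), 73L)                    # 1 + 8 + 64
  # reverse exemplar primary with a mapped mate, direction R: 16 + 1 + 128
  expect_equal(computeFlag(mapped = TRUE, reverse = TRUE, direction = "R",
                           mateUsed = TRUE, mateMapped = TRUE), 145L)
  # an unknown direction token drops the 64/128 bit with a warning
  expect_warning(f <- computeFlag(mateUsed = TRUE, direction = "X"), "token")
  expect_equal(f, 1L)
})

test_that("FLAG encode/decode round-trips over every valid combination", {
  ctxs <- allFlagContexts()
  flags <- vapply(ctxs, function(cx) do.call(computeFlag, cx), integer(1))
  expect_equal(anyDuplicated(flags), 0L)   # the decomposition is unique
  for (i in seq_along(ctxs)) {
    dec <- decodeFlag(flags[i])
    expect_equal(do.call(computeFlag, dec), flags[i])
    # semantic fields survive the round trip
    expect_equal(dec$exemplar, ctxs[[i]]$exemplar)
    expect_equal(dec$primary, ctxs[[i]]$primary)
    expect_equal(dec$mateUsed, ctxs[[i]]$mateUsed)
    if (ctxs[[i]]$mapped) expect_equal(dec$reverse, ctxs[[i]]$reverse)
  }
  expect_error(decodeFlag(4L + 16L), "unmapped")
  expect_error(decodeFlag(8L), "paired")
  expect_error(decodeFlag(64L + 128L + 1L), "first and second")
})

test_that("exemplar selection needs > 50 bases and takes the best mean quality", {
  expect_equal(selectExemplar(c(300L, 400L), c(25, 30)), 2L)
  # length gates before quality: a 45-base read cannot be exemplar
  expect_equal(selectExemplar(c(45L, 300L), c(35, 20)), 2L)
  expect_equal(selectExemplar(200L, 30), 1L)
  expect_true(is.na(selectExemplar(c(45L, 50L), c(35, 35))))
  # ties: longer read, then name
  expect_equal(selectExemplar(c(100L, 200L), c(30, 30)), 2L)
  expect_equal(selectExemplar(c(100L, 100L), c(30, 30), c("b", "a")), 2L)
})

test_that("primary selection requires quality above 40 with a fallback", {
  expect_equal(selectPrimary(c(55L, 20L)), 1L)
  expect_equal(selectPrimary(c(20L, 55L)), 2L)
  # none above 40: highest overall wins
  expect_equal(selectPrimary(c(30L, 35L)), 2L)
  expect_equal(selectPrimary(42L), 1L)
  # ties broken by chromosome order then leftmost position
  expect_equal(selectPrimary(c(30L, 30L), c("chr2", "chr1"), c(5L, 9L)), 2L)
  expect_equal(selectPrimary(c(30L, 30L), c("chr1", "chr1"), c(9L, 5L)), 2L)
})

test_that("mate fields follow the template-length conventions", {
  # read at chr2:1000 spanning 600, mate at chr2:5000 spanning 700
  mf <- fillMateFields("chr2", 1000L, 600L, "chr2", 5000L, 700L)
  expect_equal(mf$mrnm, "=")
  expect_equal(mf$mpos, 5000L)
  expect_equal(mf$isize, 4700L)            # 5699 - 1000 + 1
  mfR <- fillMateFields("chr2", 5000L, 700L, "chr2", 1000L, 600L)
  expect_equal(mfR$isize, -4700L)
  # unmapped mate: no coordinates exist
  expect_equal(fillMateFields("chr2", 1000L, 600L, NA, NA, NA),
               list(mrnm = "*", mpos = 0L, isize = 0L))
  # mate on another chromosome: named MRNM, undefined template length
  mfX <- fillMateFields("chr1", 1000L, 600L, "chr3", 42L, 500L)
  expect_equal(mfX$mrnm, "chr3")
  expect_equal(mfX$mpos, 42L)
  expect_equal(mfX$isize, 0L)
})

test_that("repair reconstructs pair information from a mate-blind SAM", {
  sam <- samFrom(list(
    samRecord("c1_F", 0L, pos = 1000L, len = 600L),
    samRecord("c1_R", 16L, pos = 5000L, len = 700L)))
  rep <- repairSam(sam)
  rec <- samRecords(rep)
  expect_equal(rec$flag, c(0L + 1L + 64L, 16L + 1L + 128L))
  expect_equal(rec$rnext, c("=", "="))
  expect_equal(rec$pnext, c(5000L, 1000L))
  expect_equal(rec$tlen, c(4700L, -4700L))
})

test_that("repair marks duplicates, secondaries and unmapped mates", {
  q200 <- paste(rep("5", 200), collapse = "")   # q20
  q200hi <- paste(rep("I", 200), collapse = "") # q40
  sam <- samFrom(list(
    # clone c1: two F reads (duplicate marking) and one unmapped R mate
    samRecord("c1_F",   0L, pos = 100L, seq = strrep("A", 200), qual = q200),
    samRecord("c1_F_2", 0L, pos = 100L, seq = strrep("A", 200), qual = q200hi),
    samRecord("c1_R",   4L, rname = "*", pos = 0L, mapq = 0L, len = 150L),
    # clone c2: one F read mapped twice (primary selection), no mate
    samRecord("c2_F", 0L, pos = 2000L, mapq = 55L, len = 300L),
    samRecord("c2_F", 0L, pos = 7000L, mapq = 20L, len = 300L),
    # unparseable name passes through untouched
    samRecord("odd-name", 0L, pos = 9000L, len = 100L)))
  rep <- repairSam(sam)
  rec <- samRecords(rep)
  byName <- function(nm) rec[rec$qname == nm, ]

  # exemplar is the higher-quality copy; the other gets +1024
  expect_equal(bitwAnd(byName("c1_F")$flag, 1024L), 1024L)
  expect_equal(bitwAnd(byName("c1_F_2")$flag, 1024L), 0L)
  # both F records are paired to an unmapped mate: +1 +8 +64
  expect_equal(bitwAnd(byName("c1_F_2")$flag, 1L + 8L + 64L), 73L)
  expect_equal(byName("c1_F_2")$rnext, "*")
  expect_equal(byName("c1_F_2")$tlen, 0L)
  # the unmapped R read is paired to a mapped mate: 4 + 1 + 128
  expect_equal(byName("c1_R")$flag, 4L + 1L + 128L)

  # primary has mapq 55; the mapq-20 record gets +256; neither is paired
  c2 <- byName("c2_F")
  expect_equal(c2$flag[c2$mapq == 55L], 0L)
  expect_equal(c2$flag[c2$mapq == 20L], 256L)

  # unparseable record untouched, counted in the report
  expect_equal(byName("odd-name")$flag, 0L)
  expect_equal(attr(rep, "repairReport")[["unparseable"]], 1L)

  # record count, sequence and CIGAR unchanged; exactly one primary per read
  expect_equal(nrow(rec), nrow(samRecords(sam)))
  expect_equal(rec$seq, samRecords(sam)$seq)
  expect_equal(rec$cigar, samRecords(sam)$cigar)
  mapped <- rec[bitwAnd(rec$flag, 4L) == 0L & rec$qname != "odd-name", ]
  prim <- tapply(bitwAnd(mapped$flag, 256L) == 0L, mapped$qname, sum)
  expect_true(all(prim == 1))
})

test_that("repair is idempotent and empty input passes through", {
  ts <- simulateTruth(c(chr1 = 40000), seed = 31)
  rs <- simulateSangerReads(ts, targetDepth = 3, duplicateFraction = 0.2, seed = 31)
  tr <- trimSangerReads(rs)
  sam <- emitAlignments(partitionReads(tr)$long, ts, multimapFraction = 0.1,
                        unmappedFraction = 0.05, seed = 31)
  r1 <- repairSam(sam)
  r2 <- repairSam(r1)
  expect_equal(as.data.frame(samRecords(r1)), as.data.frame(samRecords(r2)))

  # mate symmetry on primary exemplar records of full pairs
  rec <- data.table::as.data.table(samRecords(r1))
  pri <- rec[bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 1024L) == 0L &
               bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 8L) == 0L &
               bitwAnd(flag, 1L) == 1L]
  pri[, clone := sub("_[FR](_[0-9]+)?$", "", qname)]
  pairs <- pri[, .N, by = clone][N == 2]$clone
  for (cl in utils::head(pairs, 20)) {
    p <- pri[clone == cl]
    expect_equal(p$pnext, rev(p$pos))
    expect_equal(sum(p$tlen), 0L)
  }

  empty <- samFrom(list())
  expect_equal(nrow(samRecords(repairSam(empty))), 0L)
  expect_equal(samHeader(repairSam(empty)), samHeader(empty))
})
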