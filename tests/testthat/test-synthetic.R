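test_that("truth simulation honours its ledgers and rates", {
  # all rates zero: reference identical to both haplotypes everywhere
  ts0 <- simulateTruth(c(chr1 = 5000), hetRate = 0, refErrorRate = 0,
                       bContribRate = 0, seed = 1)
  h <- haplotypes(ts0)
  expect_identical(as.character(refSequences(ts0)), as.character(h$A1))
  expect_identical(as.character(refSequences(ts0)), as.character(h$A2))
  expect_equal(nrow(hetSites(ts0)), 0L)

  # het ledger size within 3 sigma of binomial(1e5, 0.001)
  ts <- simulateTruth(c(chr1 = 100000), hetRate = 0.001, refErrorRate = 0,
                      bContribRate = 0, seed = 11)
  n <- nrow(hetSites(ts))
  sigma <- sqrt(100000 * 0.001 * 0.999)
  expect_lt(abs(n - 100), 3 * sigma)

  # one 500-base N run: exactly 500 Ns in the reference
  gap <- data.frame(chrom = "chr1", start = 1001L, length = 500L)
  tsg <- simulateTruth(c(chr1 = 10000), nGapSpec = gap, seed = 2)
  expect_equal(unname(countNs(refSequences(tsg))), 500)

  # determinism: identical seed, identical world
  a <- simulateTruth(c(chr1 = 5000), seed = 9)
  b <- simulateTruth(c(chr1 = 5000), seed = 9)
  expect_identical(as.character(refSequences(a)), as.character(refSequences(b)))
  expect_identical(refErrors(a), refErrors(b))

  # ledgers are disjoint and the reference differs from A exactly there
  ts2 <- simulateTruth(c(chr1 = 20000), hetRate = 0.005, refErrorRate = 0.002,
                       bContribRate = 0.002, seed = 5)
  keys <- c(paste(refErrors(ts2)$chrom, refErrors(ts2)$pos),
            paste(bContribs(ts2)$chrom, bContribs(ts2)$pos),
            paste(hetSites(ts2)$chrom, hetSites(ts2)$pos))
  expect_equal(anyDuplicated(keys), 0L)
  refc <- strsplit(as.character(refSequences(ts2))[["chr1"]], "")[[1]]
  h1c <- strsplit(as.character(haplotypes(ts2)$A1)[["chr1"]], "")[[1]]
  diffPos <- which(refc != h1c)
  expect_setequal(diffPos, c(refErrors(ts2)$pos, bContribs(ts2)$pos))

  expect_error(simulateTruth(c(chr1 = 5000), hetRate = 0.2), "rates")
  expect_error(simulateTruth(c(chr1 = 500)), "1 kb")
})

test_that("sanger read simulation hits its depth and encodes reads correctly", {
  ts <- simulateTruth(c(chr1 = 1000000L), hetRate = 0, refErrorRate = 0,
                      bContribRate = 0, seed = 4)
  rs <- simulateSangerReads(ts, targetDepth = 8, seed = 4)
  reads <- sangerReads(rs)
  totalBases <- sum(nchar(reads$seq))
  expect_gte(totalBases, 7.2e6)
  expect_lte(totalBases, 8.8e6)
  expect_true(all(reads$direction %in% c("F", "R")))
  # F/R reads come from opposite insert ends: R genomic interval right of F's
  dt <- data.table::as.data.table(reads)
  both <- dt[, if (.N == 2) .(f = gStart[direction == "F"],
                              r = gEnd[direction == "R"]), by = clone]
  expect_true(all(both$r >= both$f))

  # duplicate_fraction 0: exactly one read per (clone, direction)
  ts2 <- simulateTruth(c(chr1 = 50000), seed = 5)
  rs2 <- simulateSangerReads(ts2, targetDepth = 3, duplicateFraction = 0, seed = 5)
  grp <- table(paste(sangerReads(rs2)$clone, sangerReads(rs2)$direction))
  expect_true(all(grp == 1))

  # sidecar bounds a non-empty insert
  sc <- vectorSidecar(rs2)
  expect_true(all(sc$rightVectorStart - sc$leftVectorEnd >= 2))
})

test_that("reference-error carrier reads bear the errant base at low quality", {
  ts <- simulateTruth(c(chr1 = 50000), hetRate = 0, refErrorRate = 0.002,
                      bContribRate = 0, seed = 6)
  rs <- simulateSangerReads(ts, targetDepth = 6, errorCarrierFraction = 1, seed = 6)
  reads <- data.table::as.data.table(sangerReads(rs))
  carriers <- reads[reads$errorCarrier == TRUE]
  expect_gt(nrow(carriers), 0)
  errs <- refErrors(ts)
  found <- 0L
  for (i in seq_len(nrow(carriers))) {
    rd <- carriers[i]
    hits <- errs[errs$pos >= rd$gStart & errs$pos <= rd$gEnd, ]
    for (j in seq_len(nrow(hits))) {
      off <- if (rd$strand == "+") hits$pos[j] - rd$gStart else rd$gEnd - hits$pos[j]
      idx <- rd$vLeft + off + 1L
      b <- substr(rd$seq, idx, idx)
      want <- hits$errantAllele[j]
      if (rd$strand == "-")
        want <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(want)))
      if (b == want && rd$qual[[1]][idx] <= 18L) found <- found + 1L
    }
  }
  expect_gte(found, nrow(carriers))   # every carrier carries >= 1 errant base, q <= 18
})

test_that("short-read pairs are error-free at rate zero and hit their depth", {
  ts <- simulateTruth(c(chr1 = 100000L), hetRate = 0.001, seed = 8)
  sr <- simulateShortReads(ts, targetDepth = 40, readLen = 100, subRate = 0,
                           seed = 8)
  p <- readPairs(sr)
  expect_true(all(nchar(p$r1$seq) == 100))
  totalBases <- sum(nchar(p$r1$seq)) + sum(nchar(p$r2$seq))
  expect_gte(totalBases, 3.6e6)
  expect_lte(totalBases, 4.4e6)
  # with no substitutions every read substring-matches one A haplotype
  h <- haplotypes(ts)
  h1 <- as.character(h$A1)[["chr1"]]; h2 <- as.character(h$A2)[["chr1"]]
  idx <- sample(nrow(p$r1), 20)
  for (i in idx) {
    expect_true(grepl(p$r1$seq[i], h1, fixed = TRUE) ||
                  grepl(p$r1$seq[i], h2, fixed = TRUE))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p$r2$seq[i])))
    expect_true(grepl(rc, h1, fixed = TRUE) || grepl(rc, h2, fixed = TRUE))
  }
  expect_error(simulateShortReads(ts, targetDepth = 40, readLen = 30), "readLen")
  expect_error(simulateShortReads(ts, targetDepth = 0), "targetDepth")
})

test_that("emitted alignments follow the SAM conventions of a mate-blind mapper", {
  ts <- simulateTruth(c(chr1 = 30000), seed = 10)
  rs <- simulateSangerReads(ts, targetDepth = 2, duplicateFraction = 0,
                            vectorFlankRange = c(0L, 0L), seed = 10)
  reads <- sangerReads(rs)
  sam <- emitAlignments(reads, ts, multimapFraction = 0, unmappedFraction = 0,
                        seed = 10)
  rec <- samRecords(sam)
  expect_equal(nrow(rec), nrow(reads))
  expect_true(all(rec$flag %in% c(0L, 16L)))
  expect_true(all(rec$rnext == "*" & rec$pnext == 0 & rec$tlen == 0))
  # an R-direction read is stored reverse-complemented
  rrec <- rec[rec$flag == 16L, ][1, ]
  orig <- reads$seq[reads$name == rrec$qname]
  expect_identical(
    rrec$seq,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(orig))))
  # stored sequence matches the reference at its coordinates (no variants here)
  chr <- as.character(refSequences(ts))[["chr1"]]
  hits <- vapply(seq_len(nrow(rec)), function(i) {
    g <- substr(chr, rec$pos[i], rec$pos[i] + nchar(rec$seq[i]) - 1L)
    mean(strsplit(rec$seq[i], "")[[1]] == strsplit(g, "")[[1]])
  }, numeric(1))
  expect_gt(mean(hits > 0.99), 0.9)   # most reads are exact; hets absent here? rates default
  # unmapped fraction: FLAG 4, position 0
  sam2 <- emitAlignments(reads, ts, unmappedFraction = 1, seed = 10)
  rec2 <- samRecords(sam2)
  expect_true(all(rec2$flag == 4L & rec2$pos == 0L & rec2$rname == "*"))
  # multimapping adds records with lower quality
  sam3 <- emitAlignments(reads, ts, multimapFraction = 1, seed = 10)
  expect_equal(nrow(samRecords(sam3)), 2 * nrow(reads))
  # reads without source intervals are rejected
  bad <- reads; bad$chrom[1] <- NA
  expect_error(emitAlignments(bad, ts, seed = 1), "source interval")
})

test_that("the pileup genotyper reproduces the canonical GT/AD records", {
  ref <- refFrom(chr1 = strrep("A", 10))
  # 6 reference + 5 alternate high-quality reads: called heterozygote, AD 11
  v1 <- tallyVariants(pileupAt(2, c(rep("A", 6), rep("G", 5)), rep(30, 11)), ref)
  expect_equal(v1$gt, "0/1")
  expect_equal(v1$ad, "6,5")
  # 3 high-quality alternate + 1 low-quality reference read: called homozygote
  v2 <- tallyVariants(pileupAt(2, c(rep("G", 3), "A"), c(30, 30, 30, 10)), ref)
  expect_equal(v2$gt, "1/1")
  expect_equal(v2$ad, "1,3")
  expect_equal(v2$adRef, 1L)
  # all 5 reads alternate: homozygote with reference depth zero
  v3 <- tallyVariants(pileupAt(2, rep("G", 5), rep(30, 5)), ref)
  expect_equal(v3$gt, "1/1")
  expect_equal(v3$ad, "0,5")
  expect_equal(v3$adRef, 0L)
  # two distinct alternates: het-non-ref
  v4 <- tallyVariants(pileupAt(2, c(rep("G", 4), rep("T", 3)), rep(30, 7)), ref)
  expect_equal(v4$gt, "1/2")
  expect_equal(v4$alt, "G,T")
  # bases below the AD floor are invisible; below the GT floor still count in AD
  v5 <- tallyVariants(pileupAt(2, c(rep("G", 3), "G"), c(30, 30, 30, 4)), ref)
  expect_equal(v5$ad, "0,3")
  # no position differs from the reference: empty stream
  v6 <- tallyVariants(pileupAt(2, rep("A", 5), rep(30, 5)), ref)
  expect_equal(nrow(v6), 0L)
  # thresholds must be ordered; unsorted pileups are rejected
  expect_error(tallyVariants(pileupAt(2, "G", 30), ref, minGtQual = 5, minAdQual = 20),
               "minAdQual")
  unsorted <- data.table::data.table(chrom = "chr1", pos = c(5L, 2L),
                                     base = "G", qual = 30L)
  expect_error(tallyVariants(unsorted, ref), "sorted")
})

test_that("emitted files round-trip through their parsers", {
  ts <- simulateTruth(c(chr1 = 20000), seed = 12)
  rs <- simulateSangerReads(ts, targetDepth = 1, seed = 12,
                            vectorFlankRange = c(0L, 0L))
  tmp <- withr::local_tempdir()

  fq <- file.path(tmp, "reads.fastq")
  writeFastq(sangerReads(rs), fq)
  back <- readFastq(fq)
  expect_identical(back$name, sangerReads(rs)$name)
  expect_identical(back$seq, sangerReads(rs)$seq)
  expect_identical(unclass(back$qual)[[3]], sangerReads(rs)$qual[[3]])

  fa <- file.path(tmp, "ref.fasta")
  writeFasta(refSequences(ts), fa)
  expect_identical(as.character(readFasta(fa)), as.character(refSequences(ts)))

  sam <- emitAlignments(sangerReads(rs), ts, seed = 12)
  sp <- file.path(tmp, "aln.sam")
  writeSam(sam, sp)
  back <- readSam(sp)
  expect_identical(samHeader(back), samHeader(sam))
  expect_equal(as.data.frame(samRecords(back)), as.data.frame(samRecords(sam)))

  sc <- file.path(tmp, "vec.tsv")
  writeSidecar(vectorSidecar(rs), sc)
  expect_equal(readVectorSidecar(sc), vectorSidecar(rs))

  v <- tallyVariants(basePileup(sam), refSequences(ts))
  vp <- file.path(tmp, "calls.vcf")
  writeVcf(v, vp, refSequences(ts))
  vb <- readVcfRecords(vp)
  expect_equal(as.data.frame(vb), as.data.frame(v[, names(vb), with = FALSE]))
})
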