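#' @importFrom data.table setkey setkeyv fifelse
NULL

# coerce read containers to the flat read table emitAlignments works on
asReadTable <- function(reads) {
  if (is(reads, "SangerReadSet")) return(as.data.table(sangerReads(reads)))
  if (is(reads, "ShortReadSet")) {
    p <- readPairs(reads)
    p$r1$name <- paste0(p$r1$name, "_F")
    p$r2$name <- paste0(p$r2$name, "_R")
    return(rbindlist(list(as.data.table(p$r1), as.data.table(p$r2)), fill = TRUE))
  }
  as.data.table(reads)
}

samHeaderFor <- function(reference, so = "coordinate") {
  lens <- Biostrings::width(reference)
  c(paste0("@HD\tVN:1.6\tSO:", so),
    paste0("@SQ\tSN:", names(reference), "\tLN:", lens))
}

#' Emit mapper-style SAM records for simulated reads
#'
#' Places each read at its true genomic coordinates (1-based), with a CIGAR
#' of a single full-length match, emulating the output of a long-read mapper
#' that treats every read independently: no mate fields are set (`RNEXT "*"`,
#' `PNEXT 0`, `TLEN 0`) and the FLAG is limited to 0 (forward), 16 (reverse)
#' or 4 (unmapped). Reverse-strand reads are stored reverse-complemented with
#' reversed qualities, per the SAM orientation convention. A configurable
#' fraction of reads receives a second, lower-quality mapping at a random
#' position (for primary-selection tests), and a configurable fraction is
#' left unmapped (FLAG 4, position 0).
#'
#' Reads must carry their true source interval (`chrom`, `gStart`, `gEnd`,
#' `strand`); for trimmed Sanger reads use the coordinates produced by
#' [trimSangerReads()].
#'
#' @param reads a [SangerReadSet-class], [ShortReadSet-class], or a
#'   data.frame with columns `name`, `seq`, `qual`, `chrom`, `gStart`,
#'   `gEnd`, `strand`.
#' @param truth a [TruthSet-class] (supplies the `@SQ` header lines).
#' @param multimapFraction fraction of mapped reads given an extra mapping
#'   with mapping quality in 10-39.
#' @param unmappedFraction fraction of reads emitted unmapped.
#' @param seed integer seed.
#' @return a coordinate-sorted [SamSet-class] (unmapped records last).
#' @export
emitAlignments <- function(reads, truth, multimapFraction = 0,
                           unmappedFraction = 0, seed = 1L) {
  rt <- asReadTable(reads)
  need <- c("name", "seq", "qual", "chrom", "gStart", "gEnd", "strand")
  stopifnot2(all(need %in% names(rt)), "reads lack required columns")
  stopifnot2(nrow(rt) == 0 || !anyNA(rt$chrom) && !anyNA(rt$gStart),
             "reads without source intervals cannot be aligned")
  set.seed(seed)
  ref <- refSequences(truth)
  header <- samHeaderFor(ref)
  if (nrow(rt) == 0)
    return(SamSet(header, data.table(qname = character(), flag = integer(),
                                     rname = character(), pos = integer(),
                                     mapq = integer(), cigar = character(),
                                     rnext = character(), pnext = integer(),
                                     tlen = integer(), seq = character(),
                                     qual = character())))
  stopifnot2(all(nchar(rt$seq) == rt$gEnd - rt$gStart + 1),
             "read length must match its source interval")

  n <- nrow(rt)
  unm <- runif(n) < unmappedFraction
  mm <- !unm & runif(n) < multimapFraction

  qualChar <- vapply(rt$qual, function(q) rawToChar(as.raw(pmin(q, 93L) + 33L)),
                     character(1))
  rev <- rt$strand == "-"
  seqOut <- rt$seq
  if (any(rev))
    seqOut[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rt$seq[rev])))
  qualOut <- qualChar
  if (any(rev))
    qualOut[rev] <- vapply(strsplit(qualChar[rev], "", fixed = TRUE),
                           function(x) paste(rev(x), collapse = ""), character(1))

  rec <- data.table(
    qname = rt$name,
    flag = fifelse(unm, 4L, fifelse(rev, 16L, 0L)),
    rname = fifelse(unm, "*", rt$chrom),
    pos = fifelse(unm, 0L, as.integer(rt$gStart)),
    mapq = fifelse(unm, 0L, sample(41:60, n, replace = TRUE)),
    cigar = fifelse(unm, "*", paste0(nchar(rt$seq), "M")),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = fifelse(unm, rt$seq, seqOut),
    qual = fifelse(unm, qualChar, qualOut))

  if (any(mm)) {
    lens <- setNames(Biostrings::width(ref), names(ref))
    sec <- rec[mm]
    len <- nchar(sec$seq)
    sec[, rname := sample(names(lens), .N, replace = TRUE, prob = lens)]
    sec[, pos := floor(runif(.N) * pmax(1, lens[rname] - len + 1)) + 1L]
    sec[, mapq := sample(10:39, .N, replace = TRUE)]
    rec <- rbindlist(list(rec, sec))
  }

  chromOrder <- c(names(ref), "*")
  rec <- rec[order(match(rname, chromOrder), pos)]
  SamSet(header, rec)
}

#' Per-base and per-position pileups from alignments
#'
#' `basePileup()` expands mapped alignment records into one row per aligned
#' base: `chrom`, `pos` (1-based), `base` (reference-forward), `qual`
#' (integer phred). Records flagged unmapped, secondary (+256) or duplicate
#' (+1024) are skipped, as a pileup engine would. Only pure-match CIGARs are
#' supported.
#'
#' `depthPileup()` reduces this to the samtools-style depth column: `chrom`,
#' `pos`, `ref` (the reference base) and `depth`, sorted by chromosome and
#' position, with zero-coverage positions absent.
#'
#' @param sam a [SamSet-class] or a base-pileup data.table.
#' @param reference a [Biostrings::DNAStringSet] (for `depthPileup`).
#' @return a data.table (see above).
#' @export
basePileup <- function(sam) {
  rec <- as.data.table(samRecords(sam))
  keep <- rec[bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
                bitwAnd(flag, 1024L) == 0L]
  if (nrow(keep) == 0)
    return(data.table(chrom = character(), pos = integer(),
                      base = character(), qual = integer()))
  stopifnot2(all(grepl("^[0-9]+M$", keep$cigar)),
             "basePileup supports only pure-match CIGARs")
  len <- nchar(keep$seq)
  pu <- data.table(
    chrom = rep(keep$rname, len),
    pos = rep(as.integer(keep$pos), len) + sequence(len) - 1L,
    base = unlist(strsplit(keep$seq, "", fixed = TRUE), use.names = FALSE),
    qual = as.integer(charToRaw(paste(keep$qual, collapse = ""))) - 33L)
  setkey(pu, chrom, pos)
  pu[]
}

#' @rdname basePileup
#' @export
depthPileup <- function(sam, reference) {
  pu <- if (is(sam, "SamSet")) basePileup(sam) else as.data.table(sam)
  dp <- pu[, .(depth = .N), by = .(chrom, pos)]
  refchars <- explodeSeq(reference)
  dp[, ref := refchars[[.BY$chrom]][pos], by = chrom]
  setkey(dp, chrom, pos)
  dp[, .(chrom, pos, ref, depth)]
}

#' Call genotypes with allelic depths from a pileup
#'
#' A deliberately simple pileup genotyper standing in for an external variant
#' caller, producing records with the same GT/AD semantics. At every position
#' where at least one read base differs from the reference:
#'
#' * **AD** counts reads per allele using bases with quality >= `minAdQual`,
#'   reference allele first, alternates in discovery order (order of first
#'   appearance in the read stream);
#' * **GT** uses only bases with quality >= `minGtQual`; an allele is called
#'   *present* when supported by at least 2 such reads or at least 20% of
#'   them. Genotypes are `0/1` (reference plus one alternate), `1/1` (one
#'   alternate only), het-non-ref (`1/2`) for two distinct alternates, `0/0`
#'   when only the reference is supported, and `./.` when nothing is.
#'
#' @param pileup a base pileup from [basePileup()] (or a [SamSet-class],
#'   which is expanded first), sorted by chromosome and position.
#' @param reference a [Biostrings::DNAStringSet].
#' @param minGtQual minimum base quality for genotype support (default 20).
#' @param minAdQual minimum base quality for AD counting (default 5); must be
#'   below `minGtQual`.
#' @return a data.table of variant records: `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated), `gt`, `ad` (comma-separated, reference first),
#'   `adRef` (integer convenience copy of the first AD entry).
#' @export
tallyVariants <- function(pileup, reference, minGtQual = 20L, minAdQual = 5L) {
  stopifnot2(minAdQual < minGtQual, "minAdQual must be below minGtQual")
  pu <- if (is(pileup, "SamSet")) basePileup(pileup) else as.data.table(pileup)
  if (nrow(pu)) {
    srt <- pu[, .(un = is.unsorted(pos)), by = chrom]
    stopifnot2(!any(srt$un) && !anyDuplicated(rle(pu$chrom)$values),
               "pileup must be sorted by chromosome and position")
  }
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), ad = character(),
                      adRef = integer())
  if (nrow(pu) == 0) return(empty)
  refchars <- explodeSeq(reference)
  pu[, refb := refchars[[.BY$chrom]][pos], by = chrom]
  vp <- unique(pu[base != refb & refb != "N" & base != "N", .(chrom, pos)])
  if (nrow(vp) == 0) return(empty)
  sub <- pu[vp, on = .(chrom, pos)]
  out <- sub[, {
    refb1 <- refb[1]
    adBase <- base[qual >= minAdQual]
    alts <- unique(adBase[adBase != refb1])
    adRef <- sum(adBase == refb1)
    adAlt <- vapply(alts, function(a) sum(adBase == a), integer(1))
    hq <- base[qual >= minGtQual]
    tot <- length(hq)
    cand <- c(refb1, alts)
    cnt <- vapply(cand, function(a) sum(hq == a), integer(1))
    present <- cand[cnt >= 2L | (tot > 0L & cnt >= 0.2 * tot & cnt > 0L)]
    pAlt <- intersect(alts, present)
    gt <- if (tot == 0L || length(present) == 0L) "./."
    else if (refb1 %in% present) {
      if (length(pAlt) == 0L) "0/0"
      else paste0("0/", match(pAlt[which.max(cnt[match(pAlt, cand)])], alts))
    } else if (length(pAlt) == 1L) {
      i <- match(pAlt, alts); paste0(i, "/", i)
    } else {
      i <- sort(match(pAlt[order(-cnt[match(pAlt, cand)])][1:2], alts))
      paste0(i[1], "/", i[2])
    }
    .(ref = refb1,
      alt = if (length(alts)) paste(alts, collapse = ",") else ".",
      gt = gt,
      ad = paste(c(adRef, adAlt), collapse = ","),
      adRef = adRef)
  }, by = .(chrom, pos)]
  pu[, refb := NULL]
  out[]
}
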