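# Independent brute-force oracles and tiny fixture builders used across tests.

# exhaustive sliding-window scan: every window start, both directions
bruteTrimIndices <- function(q, window = 20L, threshold = 400L) {
  n <- length(q)
  if (n < window) return(NULL)
  starts <- 1:(n - window + 1)
  sums <- vapply(starts, function(s) sum(q[s:(s + window - 1)]), numeric(1))
  ok <- which(sums >= threshold)
  if (length(ok) == 0) return(NULL)
  left <- min(ok) - 1L                      # 0-based first position, L -> R scan
  right <- max(ok) + window - 1L - 1L       # 0-based last position, R -> L scan
  c(left, right)
}

# naive per-position depth array from a depth pileup
naiveDepthArray <- function(pileup, chromLen, chromName = "chr1") {
  d <- rep(0L, chromLen)
  p <- pileup[pileup$chrom == chromName, ]
  d[p$pos] <- p$depth
  d
}

# runs of TRUE as 1-based inclusive intervals
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# build a depth pileup from random read intervals over one chromosome
randomIntervalPileup <- function(chromLen, nReads, maxLen = 50L, chrom = "chr1") {
  depth <- rep(0L, chromLen)
  for (i in seq_len(nReads)) {
    len <- sample(seq_len(maxLen), 1)
    s <- sample(chromLen - len + 1, 1)
    depth[s:(s + len - 1)] <- depth[s:(s + len - 1)] + 1L
  }
  covered <- which(depth > 0)
  list(pileup = data.frame(chrom = rep(chrom, length(covered)), pos = covered,
                           ref = rep("A", length(covered)),
                           depth = depth[covered]),
       depth = depth)
}

randomDNAString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a reference with given sequence string(s)
refFrom <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

# base pileup rows for one position
pileupAt <- function(pos, bases, quals, chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         base = bases, qual = as.integer(quals))
}

# minimal SamSet from a record list
samFrom <- function(records, chromLens = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(chromLens), "\tLN:", chromLens))
  if (length(records) == 0)
    return(SamSet(hdr, data.frame(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character())))
  SamSet(hdr, data.table::rbindlist(records))
}

samRecord <- function(qname, flag = 0L, rname = "chr1", pos = 1L, mapq = 50L,
                      len = 100L, seq = NULL, qual = NULL) {
  if (is.null(seq)) seq <- paste(rep("A", len), collapse = "")
  if (is.null(qual)) qual <- paste(rep("I", nchar(seq)), collapse = "")  # q40
  list(qname = qname, flag = as.integer(flag), rname = rname,
       pos = as.integer(pos), mapq = as.integer(mapq),
       cigar = if (flag == 4L) "*" else paste0(nchar(seq), "M"),
       rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = qual)
}

# all valid FLAG bit combinations under the reprocessing rules
allFlagContexts <- function() {
  out <- list()
  for (mapped in c(TRUE, FALSE))
    for (reverse in if (mapped) c(FALSE, TRUE) else FALSE)
      for (exemplar in c(TRUE, FALSE))
        for (primary in c(TRUE, FALSE))
          for (mateUsed in c(FALSE, TRUE)) {
            dirs <- if (mateUsed) c("F", "R") else NA_character_
            mm <- if (mateUsed) c(TRUE, FALSE) else TRUE
            for (direction in dirs)
              for (mateMapped in mm)
                out[[length(out) + 1]] <- list(
                  mapped = mapped, reverse = reverse, direction = direction,
                  exemplar = exemplar, primary = primary,
                  mateUsed = mateUsed, mateMapped = mateMapped)
          }
  out
}
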