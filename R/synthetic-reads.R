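#' @importFrom data.table data.table rbindlist setDT as.data.table setorder :=
NULL

# quality ramp for a Sanger-style read: low first ~rampLen bases, plateau,
# decaying tail; jitter keeps window sums from being degenerate
rampQual <- function(n, rampLen = 50, plateauQ = 40, tailLen = 150, tailQ = 5,
                     jitter = 3) {
  q <- rep(plateauQ, n)
  r <- min(rampLen, n)
  q[seq_len(r)] <- pmin(q[seq_len(r)], round(seq(3, plateauQ, length.out = r)))
  t <- min(tailLen, n)
  tq <- round(seq(plateauQ, tailQ, length.out = t))
  idx <- (n - t + 1L):n
  q[idx] <- pmin(q[idx], tq)
  q <- q + sample(-jitter:jitter, n, replace = TRUE)
  as.integer(pmax(2L, pmin(q, plateauQ)))
}

#' Simulate Sanger-style paired clone-end reads
#'
#' Emulates capillary reads produced by sequencing both ends of large-insert
#' clones. Clone start positions are uniform over the genome; the forward (F)
#' read comes from the left end of the insert and the reverse (R) read from
#' the right end, reverse-complemented. Read lengths are uniform in
#' `readLenRange`; per-base qualities follow a ramp (low first ~50 bases, high
#' plateau, decaying tail) so that sliding-window quality trimming has
#' something to cut. Reads carry cloning-vector flanks whose extent is
#' recorded in a sidecar table ([vectorSidecar()]).
#'
#' A configurable fraction of clone/directions receives more than one read
#' (to exercise exemplar selection), and for each ledgered reference error a
#' covering read is designated as the *carrier*: it bears the errant allele
#' with a low phred quality (at most 18), the generative source of that
#' reference error.
#'
#' @param truth a [TruthSet-class].
#' @param targetDepth desired fold coverage of the genome (total sequenced
#'   bases / genome length lands within ~10% of it). Default 8, a typical
#'   Sanger-era whole-genome shotgun depth.
#' @param insertMix named numeric vector of insert-size probabilities over
#'   4000, 10000 and 40000 bases.
#' @param seed integer seed.
#' @param individual `"A"` (diploid; each clone drawn from one haplotype) or
#'   `"B"` (haploid consensus).
#' @param duplicateFraction fraction of clone/directions sequenced twice.
#' @param errorCarrierFraction probability that a ledgered reference error
#'   has its carrier read injected (individual A only).
#' @param readLenRange integer range of read lengths.
#' @param vectorFlankRange integer range of left vector-flank lengths; use
#'   `c(0, 0)` for flank-free reads.
#' @param rightFlankProb probability that a read runs into right vector.
#' @param rampLen,plateauQ,tailLen,tailQ quality-ramp shape parameters.
#' @return a [SangerReadSet-class].
#' @examples
#' ts <- simulateTruth(c(chr1 = 10000), seed = 1)
#' rs <- simulateSangerReads(ts, targetDepth = 2, seed = 1)
#' head(sangerReads(rs)$name)
#' @export
simulateSangerReads <- function(truth, targetDepth = 8,
                                insertMix = c("4000" = 1/3, "10000" = 1/3, "40000" = 1/3),
                                seed = 1L, individual = c("A", "B"),
                                duplicateFraction = 0.05,
                                errorCarrierFraction = 1,
                                readLenRange = c(500L, 900L),
                                vectorFlankRange = c(5L, 30L),
                                rightFlankProb = 0.2,
                                rampLen = 50, plateauQ = 40, tailLen = 150,
                                tailQ = 5) {
  stopifnot2(targetDepth > 0, "targetDepth must be > 0")
  individual <- match.arg(individual)
  stopifnot2(all(names(insertMix) %in% c("4000", "10000", "40000")),
             "insertMix must be over insert sizes 4000, 10000, 40000")
  set.seed(seed)

  ref <- refSequences(truth)
  lens <- setNames(Biostrings::width(ref), names(ref))
  haps <- haplotypes(truth)
  hapStr <- list(as.character(haps$A1), as.character(haps$A2))
  if (individual == "B") {
    b <- as.character(consensusB(truth))
    hapStr <- list(b, b)
  }
  G <- sum(lens)
  meanLen <- mean(readLenRange)
  nClones <- max(1L, round(targetDepth * G / (2 * meanLen * (1 + duplicateFraction))))

  chromV <- sample(names(lens), nClones, replace = TRUE, prob = lens)
  insertV <- as.integer(sample(names(insertMix), nClones, replace = TRUE,
                               prob = insertMix))
  insertV <- pmin(insertV, lens[chromV])
  startV <- floor(runif(nClones) * (lens[chromV] - insertV + 1)) + 1L
  hapV <- sample(1:2, nClones, replace = TRUE)

  rows <- vector("list", nClones * 2L)
  k <- 0L
  mkread <- function(cl, dir, copy) {
    cn <- chromV[cl]
    ins <- insertV[cl]
    cs <- startV[cl]
    rl <- min(sample(readLenRange[1]:readLenRange[2], 1L), ins)
    if (dir == "F") {
      gs <- cs; ge <- cs + rl - 1L; strand <- "+"
      insert <- substr(hapStr[[hapV[cl]]][[match(cn, names(lens))]], gs, ge)
    } else {
      ge <- cs + ins - 1L; gs <- ge - rl + 1L; strand <- "-"
      insert <- revcompChar(substr(hapStr[[hapV[cl]]][[match(cn, names(lens))]], gs, ge))
    }
    vl <- if (vectorFlankRange[2] > 0)
      sample(vectorFlankRange[1]:vectorFlankRange[2], 1L) else 0L
    rightFlank <- if (runif(1) < rightFlankProb && vectorFlankRange[2] > 0)
      sample(5:30, 1L) else 0L
    sq <- paste0(if (vl > 0) randomDNA(vl) else "", insert,
                 if (rightFlank > 0) randomDNA(rightFlank) else "")
    n <- nchar(sq)
    nm <- paste0(chromV[cl], "c", cl, "_", dir, if (copy > 1L) paste0("_", copy) else "")
    list(name = nm, clone = paste0(chromV[cl], "c", cl), direction = dir,
         seq = sq, qual = list(rampQual(n, rampLen, plateauQ, tailLen, tailQ)),
         chrom = cn, gStart = gs, gEnd = ge, strand = strand,
         vLeft = vl, vRight = vl + rl, errorCarrier = FALSE)
  }
  for (cl in seq_len(nClones)) {
    for (dir in c("F", "R")) {
      k <- k + 1L
      rows[[k]] <- mkread(cl, dir, 1L)
      if (runif(1) < duplicateFraction) {
        k <- k + 1L
        rows[[k]] <- mkread(cl, dir, 2L)
      }
    }
  }
  reads <- rbindlist(rows[seq_len(k)])

  # reads spanning an assembly gap cannot map to the reference: drop them,
  # which thins coverage at gap flanks just as real contig boundaries do
  gaps <- nGapRuns(ref)
  if (any(vapply(gaps, nrow, integer(1)) > 0))
    reads <- reads[!overlapsNGap(reads$chrom, reads$gStart, reads$gEnd, gaps)]

  # carrier reads for ledgered reference errors: the single low-quality read
  # whose miscalled base became the reference allele
  errs <- refErrors(truth)
  if (individual == "A" && nrow(errs) > 0 && errorCarrierFraction > 0) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (j in seq_len(nrow(errs))) {
      if (runif(1) > errorCarrierFraction) next
      cov <- which(reads$chrom == errs$chrom[j] &
                     reads$gStart <= errs$pos[j] & reads$gEnd >= errs$pos[j])
      if (!length(cov)) next
      i <- if (length(cov) == 1L) cov else sample(cov, 1L)
      off <- if (reads$strand[i] == "+") errs$pos[j] - reads$gStart[i]
             else reads$gEnd[i] - errs$pos[j]
      idx <- reads$vLeft[i] + off + 1L          # 1-based index within the read
      newb <- errs$errantAllele[j]
      if (reads$strand[i] == "-") newb <- comp[[newb]]
      sq <- reads$seq[i]
      substr(sq, idx, idx) <- newb
      q <- reads$qual[[i]]
      q[idx] <- sample(5:18, 1L)
      data.table::set(reads, i, "seq", sq)
      data.table::set(reads, i, "qual", list(list(q)))
      data.table::set(reads, i, "errorCarrier", TRUE)
    }
  }

  sidecar <- data.frame(name = reads$name,
                        leftVectorEnd = reads$vLeft,
                        rightVectorStart = reads$vRight + 1L,
                        stringsAsFactors = FALSE)
  new("SangerReadSet", reads = as.data.frame(reads), sidecar = sidecar)
}

#' Simulate paired-end short reads
#'
#' Emulates a paired-end short-read run (100-cycle sequencing of a
#' 300-400 bp insert library): fragments uniform over the genome, each end
#' read inward, the second mate reverse-complemented, mates synchronized.
#' Reads are error-free except for a configurable per-base substitution rate;
#' base qualities are a constant plateau.
#'
#' @param truth a [TruthSet-class].
#' @param targetDepth desired fold coverage (default 40, the resequencing
#'   depth the audit assumes).
#' @param readLen read length in `[50, 150]` (default 100).
#' @param seed integer seed.
#' @param insertRange fragment-length range (default 300-400).
#' @param subRate per-base substitution error rate (default 0.001).
#' @param baseQ constant base quality (default 37).
#' @param individual `"A"` (diploid, haplotype chosen per fragment) or `"B"`.
#' @return a [ShortReadSet-class].
#' @export
simulateShortReads <- function(truth, targetDepth = 40, readLen = 100L,
                               seed = 1L, insertRange = c(300L, 400L),
                               subRate = 0.001, baseQ = 37L,
                               individual = c("A", "B")) {
  stopifnot2(targetDepth > 0, "targetDepth must be > 0")
  stopifnot2(readLen >= 50 && readLen <= 150, "readLen must lie in [50, 150]")
  stopifnot2(subRate >= 0 && subRate < 1, "subRate must lie in [0, 1)")
  individual <- match.arg(individual)
  set.seed(seed)

  ref <- refSequences(truth)
  lens <- setNames(Biostrings::width(ref), names(ref))
  stopifnot2(all(lens >= insertRange[2]),
             "chromosomes must be at least one insert long")
  haps <- haplotypes(truth)
  hapStr <- list(as.character(haps$A1), as.character(haps$A2))
  if (individual == "B") {
    b <- as.character(consensusB(truth))
    hapStr <- list(b, b)
  }
  G <- sum(lens)
  nPairs <- max(1L, round(targetDepth * G / (2 * readLen)))

  chromV <- sample(names(lens), nPairs, replace = TRUE, prob = lens)
  insV <- sample(insertRange[1]:insertRange[2], nPairs, replace = TRUE)
  gsV <- floor(runif(nPairs) * (lens[chromV] - insV + 1)) + 1L
  geV <- gsV + insV - 1L
  hapV <- sample(1:2, nPairs, replace = TRUE)

  s1 <- character(nPairs); s2 <- character(nPairs)
  for (cn in unique(chromV)) {
    for (h in 1:2) {
      sel <- which(chromV == cn & hapV == h)
      if (!length(sel)) next
      hs <- hapStr[[h]][[match(cn, names(lens))]]
      s1[sel] <- substring(hs, gsV[sel], gsV[sel] + readLen - 1L)
      s2[sel] <- substring(hs, geV[sel] - readLen + 1L, geV[sel])
    }
  }
  s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s2)))

  injectSubs <- function(s) {
    hit <- which(runif(nPairs * readLen) < subRate)
    for (x in hit) {
      i <- (x - 1L) %/% readLen + 1L
      p <- (x - 1L) %% readLen + 1L
      substr(s[i], p, p) <- otherBase(substr(s[i], p, p))
    }
    s
  }
  if (subRate > 0) {
    s1 <- injectSubs(s1)
    s2 <- injectSubs(s2)
  }

  # drop pairs whose either mate spans an assembly gap (unmappable there)
  gaps <- nGapRuns(ref)
  if (any(vapply(gaps, nrow, integer(1)) > 0)) {
    bad <- overlapsNGap(chromV, gsV, gsV + readLen - 1L, gaps) |
      overlapsNGap(chromV, geV - readLen + 1L, geV, gaps)
    keep <- !bad
    chromV <- chromV[keep]; gsV <- gsV[keep]; geV <- geV[keep]
    s1 <- s1[keep]; s2 <- s2[keep]
    nPairs <- sum(keep)
  }

  q <- rep(list(rep(as.integer(baseQ), readLen)), nPairs)
  nm <- paste0("s", seq_len(nPairs))
  r1 <- data.frame(name = nm, seq = s1, chrom = chromV, gStart = gsV,
                   gEnd = gsV + readLen - 1L, strand = "+",
                   stringsAsFactors = FALSE)
  r1$qual <- q
  r2 <- data.frame(name = nm, seq = s2, chrom = chromV,
                   gStart = geV - readLen + 1L, gEnd = geV, strand = "-",
                   stringsAsFactors = FALSE)
  r2$qual <- q
  new("ShortReadSet", r1 = r1, r2 = r2)
}
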