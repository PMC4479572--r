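#' @importFrom IRanges IRanges reduce gaps
#' @importFrom GenomicRanges GRanges
NULL

#' Count assembly-gap N bases per chromosome
#'
#' Counts the Ns per chromosome as the difference between the original
#' chromosome length and its length after removing every N, the correction
#' later applied to the zero-coverage bin of the depth histogram.
#'
#' @param reference a [Biostrings::DNAStringSet] (any IUPAC letters), or a
#'   named character vector of sequences.
#' @return named numeric vector of N counts per chromosome.
#' @export
countNs <- function(reference) {
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(reference)  # rejects non-IUPAC
  full <- Biostrings::width(reference)
  # the modified, N-free reference: remove Ns and re-measure
  stripped <- Biostrings::width(Biostrings::DNAStringSet(
    gsub("N", "", as.character(reference), fixed = TRUE)))
  setNames(as.numeric(full - stripped), names(reference))
}

#' Depth histogram with a gap- and N-corrected zero bin
#'
#' Tallies how many reference positions sit at each read depth. Positions
#' with zero coverage are absent from a pileup, so the zero bin is
#' reconstructed from the gaps: for every internal gap, the left-flank
#' position is subtracted from the right-flank position and one is
#' subtracted; leading and trailing uncovered ranges contribute their full
#' lengths (excluding chromosome ends would break conservation). The N count
#' of the reference is then subtracted from this raw zero bin (clamped at
#' zero), since arbitrary N runs at contig boundaries cannot be covered.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (1-based), `depth`,
#'   sorted by chromosome and position; zero-coverage positions absent.
#' @param reference a [Biostrings::DNAStringSet] whose names cover every
#'   pileup chromosome.
#' @return a [DepthHistogram-class].
#' @export
depthHistogram <- function(pileup, reference) {
  pu <- as.data.table(pileup)
  lens <- setNames(Biostrings::width(reference), names(reference))
  stopifnot2(all(pu$chrom %in% names(lens)), "pileup chromosome not in reference")
  if (nrow(pu)) {
    srt <- pu[, .(un = is.unsorted(pos, strictly = TRUE)), by = chrom]
    stopifnot2(!any(srt$un) && !anyDuplicated(rle(pu$chrom)$values),
               "pileup must be sorted by chromosome and position")
  }
  counts <- pu[, .(n = .N), by = depth]
  rawZero <- 0
  for (cn in names(lens)) {
    p <- pu[chrom == cn, pos]
    if (length(p) == 0) {
      rawZero <- rawZero + lens[[cn]]
      next
    }
    gaps <- diff(p) - 1L                     # right flank - left flank - 1
    rawZero <- rawZero + sum(gaps) + (p[1] - 1L) + (lens[[cn]] - p[length(p)])
  }
  nc <- countNs(reference)
  zero <- max(0, rawZero - sum(nc))
  depths <- sort(unique(c(0, counts$depth)))
  v <- setNames(numeric(length(depths)), as.character(depths))
  v[as.character(counts$depth)] <- counts$n
  v["0"] <- zero
  new("DepthHistogram", counts = v, nCounts = nc,
      nonNLength = sum(lens) - sum(nc), refLength = sum(lens))
}

#' Depth-capped average fold coverage
#'
#' Multiplies the number of positions at each depth by that depth, for depths
#' 1 through `depthCap` only, and divides by the non-N reference length.
#' Depths above the cap are ignored entirely: deep pileups are typically
#' collapsed repeats and would inflate the average.
#'
#' @param histogram a [DepthHistogram-class].
#' @param depthCap highest depth considered (default 25).
#' @return average fold coverage (numeric scalar).
#' @export
foldCoverage <- function(histogram, depthCap = 25L) {
  stopifnot2(is(histogram, "DepthHistogram"), "need a DepthHistogram")
  stopifnot2(nonNLength(histogram) > 0, "zero-length reference")
  cnt <- depthCounts(histogram)
  d <- as.integer(names(cnt))
  keep <- d >= 1 & d <= depthCap
  sum(d[keep] * cnt[keep]) / nonNLength(histogram)
}

#' Low- and zero-coverage annotation tracks
#'
#' Builds two merged interval tracks from a depth pileup: the *low* track of
#' regions covered by `lowMax` or fewer reads (zero included -- the track
#' reads "two or fewer reads"), and the *zero* track of regions covered by no
#' read at all. Intervals are 0-based half-open, sorted, non-overlapping,
#' with abutting runs merged, ready to be written as BED ([writeBed()]).
#'
#' @param pileup data.frame with `chrom`, `pos` (1-based), `depth`; sorted.
#' @param reference a [Biostrings::DNAStringSet].
#' @param lowMax highest depth included in the low track (default 2).
#' @return list of two [GenomicRanges::GRanges]: `low` and `zero`.
#' @export
coverageBeds <- function(pileup, reference, lowMax = 2L) {
  pu <- as.data.table(pileup)
  lens <- setNames(Biostrings::width(reference), names(reference))
  lowL <- list(); zeroL <- list()
  for (cn in names(lens)) {
    p <- pu[chrom == cn]
    covered <- IRanges::reduce(IRanges::IRanges(p$pos, width = 1L))
    uncovered <- IRanges::gaps(covered, start = 1L, end = lens[[cn]])
    lowCov <- IRanges::reduce(IRanges::IRanges(p[depth <= lowMax, pos], width = 1L))
    lowAll <- IRanges::reduce(c(lowCov, uncovered))
    if (length(lowAll))
      lowL[[cn]] <- GenomicRanges::GRanges(cn, lowAll)
    if (length(uncovered))
      zeroL[[cn]] <- GenomicRanges::GRanges(cn, uncovered)
  }
  cat0 <- function(lst) {
    if (length(lst) == 0) return(GenomicRanges::GRanges())
    do.call(c, unname(lst))
  }
  list(low = cat0(lowL), zero = cat0(zeroL))
}
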