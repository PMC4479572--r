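#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# round half away from zero, as printed tables do (base round() is banker's)
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# sample DNA with no Ns
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a base different from each element of `base`, uniformly among the other three
otherBase <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

phredToChar <- function(q) {
  vapply(q, function(qq) rawToChar(as.raw(pmin(qq, 93L) + 33L)), character(1))
}

charToPhred <- function(s) {
  lapply(s, function(ss) as.integer(charToRaw(ss)) - 33L)
}

# split chromosome sequences into per-position character vectors
explodeSeq <- function(dss) {
  setNames(strsplit(as.character(dss), "", fixed = TRUE), names(dss))
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# 1-based intervals of N runs per chromosome of a reference
nGapRuns <- function(reference) {
  lapply(explodeSeq(reference), function(chars) {
    r <- rle(chars == "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  })
}

# TRUE for read intervals overlapping any N run (reads cannot map onto gaps)
overlapsNGap <- function(chrom, gStart, gEnd, gapRuns) {
  vapply(seq_along(chrom), function(i) {
    runs <- gapRuns[[chrom[i]]]
    if (is.null(runs) || nrow(runs) == 0) return(FALSE)
    any(gStart[i] <= runs[, "end"] & gEnd[i] >= runs[, "start"])
  }, logical(1))
}
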