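#' Sliding-window quality trim indices
#'
#' Scans an integer array of per-base quality scores with a sliding window.
#' Moving from the left end inward, the first window whose quality sum
#' reaches `threshold` (an average of `threshold / window` per base) marks
#' the left quality index at its *first* position. The right quality index is
#' found in the same manner scanning from the right end inward, and marks the
#' *last* position of the first qualifying window.
#'
#' Indices are 0-based positions into the read. If the read is shorter than
#' the window, or no window qualifies, the read is unusable and `NULL` is
#' returned.
#'
#' @param qualities non-empty integer vector of phred scores.
#' @param window window size (default 20).
#' @param threshold minimum within-window quality sum (default 400, i.e. a
#'   window average of 20, about a 1% error rate per base).
#' @return integer vector `c(left, right)` of 0-based indices, or `NULL`.
#' @examples
#' qualityTrimIndices(rep(20L, 100))        # c(0, 99)
#' qualityTrimIndices(rep(10L, 60))         # NULL: no window reaches 400
#' @export
qualityTrimIndices <- function(qualities, window = 20L, threshold = 400L) {
  stopifnot2(length(qualities) > 0, "qualities must be non-empty")
  stopifnot2(window >= 1, "window must be >= 1")
  n <- length(qualities)
  if (n < window) return(NULL)
  cs <- cumsum(as.numeric(qualities))
  wsum <- cs[window:n] - c(0, cs)[1:(n - window + 1)]
  ok <- which(wsum >= threshold)
  if (length(ok) == 0) return(NULL)
  left <- ok[1] - 1L                       # first position of first window, 0-based
  right <- ok[length(ok)] + window - 2L    # last position of first right-to-left window
  c(as.integer(left), as.integer(right))
}

#' Combine quality indices with vector-trim positions
#'
#' The final trim combines the quality scan with the cloning-vector
#' annotation: the left trim is the greater of the left quality index and the
#' end of the left vector; the right trim is the smaller of the right quality
#' index and the start of the right vector. The resulting interval is stored
#' 0-based half-open.
#'
#' `vectorBounds` gives the insert interval allowed by the vector annotation,
#' 0-based half-open, as produced by [readVectorSidecar()] from the 1-based
#' inclusive sidecar positions (last left-vector base `L`, first right-vector
#' base `R` map to `c(L, R - 1)`).
#'
#' A read is *discarded* when the quality indices are `NULL`, when the vector
#' bounds invert the interval, or when the trimmed length falls below
#' `minLen`; remaining reads are classed `long` (>= `longCutoff`) or `short`.
#'
#' @param readLength original read length in bases.
#' @param qualityIndices result of [qualityTrimIndices()] (may be `NULL`).
#' @param vectorBounds optional numeric `c(start, end)`, 0-based half-open
#'   insert interval from the vector annotation.
#' @param minLen minimum retained length (default 50).
#' @param longCutoff boundary between the short and long classes (default 200).
#' @return list with `start`, `end` (0-based half-open) and `class`
#'   (`"long"`, `"short"` or `"discarded"`).
#' @export
applyTrim <- function(readLength, qualityIndices, vectorBounds = NULL,
                      minLen = 50L, longCutoff = 200L) {
  discarded <- list(start = 0L, end = 0L, class = "discarded")
  if (is.null(qualityIndices)) return(discarded)
  start <- qualityIndices[1]
  end <- qualityIndices[2] + 1L
  if (!is.null(vectorBounds)) {
    stopifnot2(vectorBounds[1] >= 0 && vectorBounds[2] <= readLength,
               "vector positions outside the read")
    if (vectorBounds[1] >= vectorBounds[2]) return(discarded)
    start <- max(start, as.integer(vectorBounds[1]))
    end <- min(end, as.integer(vectorBounds[2]))
  }
  if (end - start < minLen) return(discarded)
  list(start = as.integer(start), end = as.integer(end),
       class = if (end - start >= longCutoff) "long" else "short")
}

#' Trim a set of Sanger-style reads
#'
#' Applies [qualityTrimIndices()] and [applyTrim()] to every read of a
#' [SangerReadSet-class], using its vector sidecar, and returns a trimmed
#' read table with the genomic coordinates of each trimmed read mapped
#' through (so that [emitAlignments()] can place them).
#'
#' @param readSet a [SangerReadSet-class].
#' @param window,threshold see [qualityTrimIndices()].
#' @param minLen,longCutoff see [applyTrim()].
#' @return a data.table with columns `name`, `clone`, `direction`, `origLen`,
#'   `trimStart`, `trimEnd` (0-based half-open), `class`, and for
#'   non-discarded reads the trimmed `seq`, `qual`, and genomic `chrom`,
#'   `gStart`, `gEnd`, `strand`.
#' @export
trimSangerReads <- function(readSet, window = 20L, threshold = 400L,
                            minLen = 50L, longCutoff = 200L) {
  reads <- as.data.table(sangerReads(readSet))
  sc <- vectorSidecar(readSet)
  vb <- vectorBoundsFromSidecar(sc)
  n <- nrow(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- reads$qual[[i]]
    len <- length(q)
    qi <- qualityTrimIndices(q, window, threshold)
    bounds <- vb[[reads$name[i]]]
    tr <- applyTrim(len, qi, bounds, minLen, longCutoff)
    row <- list(name = reads$name[i], clone = reads$clone[i],
                direction = reads$direction[i], origLen = len,
                trimStart = tr$start, trimEnd = tr$end, class = tr$class,
                seq = NA_character_, qual = list(integer()),
                chrom = NA_character_, gStart = NA_integer_,
                gEnd = NA_integer_, strand = reads$strand[i])
    if (tr$class != "discarded") {
      s <- tr$start; e <- tr$end
      row$seq <- substr(reads$seq[i], s + 1L, e)
      row$qual <- list(q[(s + 1L):e])
      row$chrom <- reads$chrom[i]
      if (reads$strand[i] == "+") {
        row$gStart <- reads$gStart[i] + (s - reads$vLeft[i])
        row$gEnd <- row$gStart + (e - s) - 1L
      } else {
        row$gEnd <- reads$gEnd[i] - (s - reads$vLeft[i])
        row$gStart <- row$gEnd - (e - s) + 1L
      }
    }
    out[[i]] <- row
  }
  rbindlist(out)
}

# sidecar (1-based inclusive vector positions) -> 0-based half-open insert bounds
vectorBoundsFromSidecar <- function(sidecar) {
  if (is.null(sidecar) || nrow(sidecar) == 0) return(list())
  b <- Map(function(l, r) c(l, r - 1L),
           sidecar$leftVectorEnd, sidecar$rightVectorStart)
  names(b) <- sidecar$name
  b
}

#' Partition trimmed reads into length classes
#'
#' Reads of `longCutoff` bases or greater go to the `long` class (mapped with
#' a long-read aligner downstream), reads between `minLen` and
#' `longCutoff - 1` to `short`, and anything below `minLen` (including reads
#' with no qualifying quality window) is `discarded`.
#'
#' @param trimmed a trimmed read table from [trimSangerReads()].
#' @return list with elements `long`, `short`, `discarded` (data.tables) and
#'   `counts` (named integer vector summing to the input size).
#' @export
partitionReads <- function(trimmed) {
  trimmed <- as.data.table(trimmed)
  parts <- list(long = trimmed[class == "long"],
                short = trimmed[class == "short"],
                discarded = trimmed[class == "discarded"])
  parts$counts <- c(long = nrow(parts$long), short = nrow(parts$short),
                    discarded = nrow(parts$discarded))
  parts
}

#' Quality filter for paired short reads
#'
#' Filters a [ShortReadSet-class] the way a stringent short-read cleanup
#' pipeline does, in this order:
#'
#' 1. discard reads with fewer than `q30Fraction` of bases at quality >= 30;
#' 2. from the 3' end, trim bases with quality below `tailFloor` until a base
#'    meeting the floor is reached;
#' 3. clip an exact occurrence of the adapter sequence (everything from its
#'    first occurrence to the read end is removed);
#' 4. discard reads shorter than `minLen`;
#' 5. re-synchronize mates: a pair survives only if both mates survive.
#'
#' @param readSet a [ShortReadSet-class].
#' @param adapter optional adapter sequence for step 3.
#' @param q30Fraction minimum fraction of bases at quality >= 30 (default 0.5).
#' @param tailFloor 3' trimming quality floor (default 3).
#' @param minLen minimum retained read length (default 50).
#' @return a filtered [ShortReadSet-class].
#' @export
shortReadFilter <- function(readSet, adapter = NULL, q30Fraction = 0.5,
                            tailFloor = 3L, minLen = 50L) {
  p <- readPairs(readSet)
  stopifnot2(identical(p$r1$name, p$r2$name), "desynchronized mates")
  filterOne <- function(df) {
    n <- nrow(df)
    keep <- logical(n)
    for (i in seq_len(n)) {
      q <- df$qual[[i]]
      if (mean(q >= 30) < q30Fraction) next              # step 1
      e <- length(q)
      while (e >= 1 && q[e] < tailFloor) e <- e - 1L     # step 2
      if (e == 0L) next
      s <- substr(df$seq[i], 1L, e)
      q <- q[seq_len(e)]
      if (!is.null(adapter)) {                           # step 3
        hit <- regexpr(adapter, s, fixed = TRUE)
        if (hit > 0) {
          s <- substr(s, 1L, hit - 1L)
          q <- q[seq_len(hit - 1L)]
        }
      }
      if (nchar(s) < minLen) next                        # step 4
      keep[i] <- TRUE
      df$seq[i] <- s
      df$qual[[i]] <- q
      # a 3'-trimmed read still maps to a prefix of its source interval
      if (all(c("gStart", "gEnd", "strand") %in% names(df))) {
        if (df$strand[i] == "+") df$gEnd[i] <- df$gStart[i] + nchar(s) - 1L
        else df$gStart[i] <- df$gEnd[i] - nchar(s) + 1L
      }
    }
    list(df = df, keep = keep)
  }
  f1 <- filterOne(p$r1)
  f2 <- filterOne(p$r2)
  keep <- f1$keep & f2$keep                              # step 5
  new("ShortReadSet", r1 = f1$df[keep, , drop = FALSE],
      r2 = f2$df[keep, , drop = FALSE])
}
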