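#' Simulate a diploid truth world for the assembly audit
#'
#' Generates a haploid reference together with the diploid genome of the
#' source individual A and the haploid consensus of a related individual B,
#' plus truth ledgers recording every way the reference deviates from A:
#'
#' * **reference errors** — positions where the reference carries an errant
#'   allele that A does not (in the generative story, a base miscalled on a
#'   single low-quality read that made it into the consensus);
#' * **B contributions** — positions where the reference carries B's allele
#'   while A is homozygous for a different one;
#' * **A heterozygous sites** — positions where A's two haplotypes differ and
#'   the reference retains the haplotype-1 allele.
#'
#' Ledger positions are drawn independently per position at the stated rates
#' and kept mutually disjoint (priority error > B contribution > het; a
#' lower-priority draw colliding with a higher-priority one is re-drawn at a
#' free position). Runs of N can be placed to emulate assembly gaps; ledger
#' positions never fall inside them.
#'
#' @param chromLengths named integer vector of chromosome lengths (>= 1000).
#' @param hetRate per-position probability of an A-heterozygous site
#'   (default 0.001, a typical mammalian heterozygosity).
#' @param refErrorRate per-position probability of an injected reference
#'   error (default 5e-4).
#' @param bContribRate per-position probability that the reference allele is
#'   contributed by individual B (default 2e-4).
#' @param nGapSpec optional data.frame with columns `chrom`, `start`
#'   (1-based), `length` giving N runs to place in the reference.
#' @param seed integer seed; identical seed and parameters give an identical
#'   TruthSet.
#' @return a [TruthSet-class] object.
#' @examples
#' ts <- simulateTruth(c(chr1 = 2000), hetRate = 0.01, seed = 1)
#' nrow(hetSites(ts))
#' @export
simulateTruth <- function(chromLengths, hetRate = 0.001, refErrorRate = 5e-4,
                          bContribRate = 2e-4, nGapSpec = NULL, seed = 1L) {
  stopifnot2(length(chromLengths) >= 1 && !is.null(names(chromLengths)) &&
               !any(names(chromLengths) == ""),
             "chromLengths must be a named vector")
  stopifnot2(all(chromLengths >= 1000), "chromosome lengths must be >= 1 kb")
  rates <- c(hetRate = hetRate, refErrorRate = refErrorRate, bContribRate = bContribRate)
  stopifnot2(all(rates >= 0 & rates <= 0.05), "rates must lie in [0, 0.05]")
  if (!is.null(nGapSpec)) {
    stopifnot2(all(c("chrom", "start", "length") %in% names(nGapSpec)),
               "nGapSpec needs chrom, start, length columns")
    stopifnot2(all(nGapSpec$chrom %in% names(chromLengths)) &&
                 all(nGapSpec$start >= 1) &&
                 all(nGapSpec$start + nGapSpec$length - 1 <= chromLengths[nGapSpec$chrom]),
               "nGapSpec intervals must lie within chromosome bounds")
  }
  set.seed(seed)

  emptyErr <- data.frame(chrom = character(), pos = integer(),
                         trueAllele = character(), errantAllele = character(),
                         stringsAsFactors = FALSE)
  emptyB <- data.frame(chrom = character(), pos = integer(),
                       aAllele = character(), refAllele = character(),
                       stringsAsFactors = FALSE)
  emptyHet <- data.frame(chrom = character(), pos = integer(),
                         allele1 = character(), allele2 = character(),
                         stringsAsFactors = FALSE)

  refL <- a1L <- a2L <- bL <- character(length(chromLengths))
  errs <- list(); bcs <- list(); hets <- list()
  for (i in seq_along(chromLengths)) {
    cn <- names(chromLengths)[i]
    L <- as.integer(chromLengths[i])
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    gap <- rep(FALSE, L)
    if (!is.null(nGapSpec)) {
      for (j in which(nGapSpec$chrom == cn)) {
        s <- nGapSpec$start[j]
        gap[s:(s + nGapSpec$length[j] - 1L)] <- TRUE
      }
    }
    pool <- which(!gap)
    draw <- function(rate, pool) {
      n <- rbinom(1L, length(pool), rate)
      if (n == 0L) integer() else sort(sample(pool, n))
    }
    errPos <- draw(refErrorRate, pool)
    pool <- setdiff(pool, errPos)
    bPos <- draw(bContribRate, pool)
    pool <- setdiff(pool, bPos)
    hetPos <- draw(hetRate, pool)

    trueAll <- base[errPos]
    errant <- otherBase(trueAll)
    aAll <- base[bPos]
    refAll <- otherBase(aAll)
    h1 <- base[hetPos]
    h2 <- otherBase(h1)

    a1 <- base                      # haplotype 1 == reference allele at hets
    a2 <- base; a2[hetPos] <- h2
    ref <- base
    ref[errPos] <- errant
    ref[bPos] <- refAll
    ref[gap] <- "N"
    b <- base                       # B agrees with A except where it donated
    b[bPos] <- refAll

    refL[i] <- paste(ref, collapse = "")
    a1L[i] <- paste(a1, collapse = "")
    a2L[i] <- paste(a2, collapse = "")
    bL[i] <- paste(b, collapse = "")
    if (length(errPos))
      errs[[cn]] <- data.frame(chrom = cn, pos = errPos, trueAllele = trueAll,
                               errantAllele = errant, stringsAsFactors = FALSE)
    if (length(bPos))
      bcs[[cn]] <- data.frame(chrom = cn, pos = bPos, aAllele = aAll,
                              refAllele = refAll, stringsAsFactors = FALSE)
    if (length(hetPos))
      hets[[cn]] <- data.frame(chrom = cn, pos = hetPos, allele1 = h1,
                               allele2 = h2, stringsAsFactors = FALSE)
  }
  mkdss <- function(x) {
    d <- Biostrings::DNAStringSet(x)
    names(d) <- names(chromLengths)
    d
  }
  bindOr <- function(lst, empty) if (length(lst)) do.call(rbind, unname(lst)) else empty
  new("TruthSet",
      reference = mkdss(refL), haplotypeA1 = mkdss(a1L), haplotypeA2 = mkdss(a2L),
      consensusB = mkdss(bL),
      refErrors = bindOr(errs, emptyErr),
      bContribs = bindOr(bcs, emptyB),
      hetSites = bindOr(hets, emptyHet))
}
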