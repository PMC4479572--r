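#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' TruthSet: a simulated diploid truth world
#'
#' Container for a simulated haploid reference together with the diploid
#' genome of the source individual ("A"), the haploid consensus of a second,
#' related individual ("B"), and the three truth ledgers that record how the
#' reference deviates from A: injected reference errors (the reference carries
#' an allele seen only on a single low-quality read), positions contributed by
#' B (the reference carries B's allele where A is homozygous for another), and
#' A's heterozygous sites.
#'
#' At every position not listed in a ledger and not masked by N, the reference
#' equals both A haplotypes. Ledger positions are mutually disjoint.
#'
#' @slot reference [Biostrings::DNAStringSet] haploid reference, may contain N runs.
#' @slot haplotypeA1,haplotypeA2 [Biostrings::DNAStringSet] the two haplotypes
#'   of individual A (no Ns).
#' @slot consensusB [Biostrings::DNAStringSet] haploid consensus of individual B.
#' @slot refErrors data.frame with columns `chrom`, `pos` (1-based),
#'   `trueAllele` (the allele A carries), `errantAllele` (the allele the
#'   reference carries).
#' @slot bContribs data.frame with columns `chrom`, `pos`, `aAllele`,
#'   `refAllele` (= B's allele, carried by the reference).
#' @slot hetSites data.frame with columns `chrom`, `pos`, `allele1` (on
#'   haplotype 1, equal to the reference allele), `allele2` (on haplotype 2).
#'
#' @seealso [simulateTruth()]
#' @export
setClass("TruthSet", slots = c(
  reference   = "DNAStringSet",
  haplotypeA1 = "DNAStringSet",
  haplotypeA2 = "DNAStringSet",
  consensusB  = "DNAStringSet",
  refErrors   = "data.frame",
  bContribs   = "data.frame",
  hetSites    = "data.frame"
))

setValidity("TruthSet", function(object) {
  msg <- character()
  lens <- setNames(Biostrings::width(object@reference), names(object@reference))
  for (slotnm in c("haplotypeA1", "haplotypeA2", "consensusB")) {
    s <- slot(object, slotnm)
    if (!identical(names(s), names(object@reference)) ||
        !identical(unname(Biostrings::width(s)), unname(lens)))
      msg <- c(msg, sprintf("%s must have the same names and lengths as the reference", slotnm))
  }
  ledgers <- list(refErrors = object@refErrors, bContribs = object@bContribs,
                  hetSites = object@hetSites)
  keys <- lapply(names(ledgers), function(nm) {
    l <- ledgers[[nm]]
    if (!all(c("chrom", "pos") %in% names(l))) {
      msg <<- c(msg, sprintf("%s must have chrom and pos columns", nm))
      return(character())
    }
    if (nrow(l) > 0L) {
      bad <- !(l$chrom %in% names(lens)) | l$pos < 1L | l$pos > lens[l$chrom]
      if (any(bad)) msg <<- c(msg, sprintf("%s has positions outside chromosome bounds", nm))
    }
    paste(l$chrom, l$pos)
  })
  allk <- unlist(keys)
  if (anyDuplicated(allk))
    msg <- c(msg, "ledger positions must be mutually disjoint")
  if (length(msg)) msg else TRUE
})

#' DepthHistogram: read-depth distribution over a reference
#'
#' Counts of reference positions at each read depth, with the zero-coverage
#' bin corrected for assembly gap Ns: uncovered stretches are first tallied
#' from the gaps in a sorted pileup (right flank minus left flank minus one
#' for internal gaps, plus leading/trailing uncovered range lengths), then the
#' number of N bases is subtracted, since arbitrary runs of N at contig
#' boundaries cannot be covered and would otherwise inflate the zero bin.
#'
#' @slot counts named numeric vector; names are depths ("0", "1", ...) and
#'   values are numbers of reference positions at that depth.
#' @slot nCounts named numeric vector of N bases per chromosome.
#' @slot nonNLength total reference length minus total N count.
#' @slot refLength total reference length.
#'
#' @seealso [depthHistogram()], [foldCoverage()]
#' @export
setClass("DepthHistogram", slots = c(
  counts     = "numeric",
  nCounts    = "numeric",
  nonNLength = "numeric",
  refLength  = "numeric"
))

setValidity("DepthHistogram", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) || anyNA(suppressWarnings(as.integer(names(object@counts)))))
    msg <- c(msg, "counts must be named by integer depth")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(object@nCounts < 0)) msg <- c(msg, "N counts must be non-negative")
  if (object@nonNLength < 0 || object@nonNLength > object@refLength)
    msg <- c(msg, "nonNLength must lie in [0, refLength]")
  if (length(msg)) msg else TRUE
})

#' AuditSummary: totals of the variant audit
#'
#' The summary surface of the audit: how many called variants are heterozygous
#' versus homozygous, how many called homozygotes have no read support at all
#' for the reference allele ("reference not detected", AD for the reference
#' equal to 0), how many of those are attributable to a second contributing
#' individual whose reads carry the reference allele, and how many remain
#' unexplained (reference-not-detected minus attributable).
#'
#' Percentages are computed from the het/hom counts and rounded half-up to two
#' decimals.
#'
#' @slot total,het,hom numeric counts of called variants (het + hom = total;
#'   records with genotype 0/0 or missing are excluded).
#' @slot hetPct,homPct percentages of total, two decimals.
#' @slot refUndetected number of called homozygotes with reference AD 0.
#' @slot attributable number of those carried by the second individual.
#' @slot unexplained refUndetected - attributable.
#' @slot skipped records dropped for missing/uncalled genotype or absent AD.
#'
#' @seealso [summarizeAudit()]
#' @export
setClass("AuditSummary", slots = c(
  total         = "numeric",
  het           = "numeric",
  hom           = "numeric",
  hetPct        = "numeric",
  homPct        = "numeric",
  refUndetected = "numeric",
  attributable  = "numeric",
  unexplained   = "numeric",
  skipped       = "numeric"
))

setValidity("AuditSummary", function(object) {
  msg <- character()
  if (object@het + object@hom != object@total)
    msg <- c(msg, "het + hom must equal total")
  if (!is.na(object@refUndetected)) {
    if (object@refUndetected > object@hom)
      msg <- c(msg, "refUndetected cannot exceed hom")
    if (!is.na(object@attributable)) {
      if (object@attributable < 0 || object@attributable > object@refUndetected)
        msg <- c(msg, "attributable must lie in [0, refUndetected]")
      if (object@unexplained != object@refUndetected - object@attributable)
        msg <- c(msg, "unexplained must equal refUndetected - attributable")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SangerReadSet: simulated Sanger-style reads with a vector sidecar
#'
#' Long reads named `<clone>_<F|R>[_<copy>]`, carrying per-base integer
#' qualities, cloning-vector flanks, and the true genomic source interval of
#' the insert portion (used by [emitAlignments()]). The sidecar table mirrors
#' the "information file" that accompanies trace archives: per read, the
#' 1-based position of the last left-vector base (`leftVectorEnd`, 0 if none)
#' and of the first right-vector base (`rightVectorStart`, read length + 1
#' when the insert runs to the read end).
#'
#' @slot reads data.frame with columns `name`, `clone`, `direction`,
#'   `seq` (the read as sequenced), `qual` (list of integer phred scores),
#'   `chrom`, `gStart`, `gEnd` (genomic interval of the insert portion),
#'   `strand`, `vLeft`, `vRight` (0-based half-open insert interval within the
#'   read), `errorCarrier`.
#' @slot sidecar data.frame with columns `name`, `leftVectorEnd`,
#'   `rightVectorStart` (1-based inclusive).
#' @seealso [simulateSangerReads()]
#' @export
setClass("SangerReadSet", slots = c(reads = "data.frame", sidecar = "data.frame"))

setValidity("SangerReadSet", function(object) {
  msg <- character()
  r <- object@reads
  if (nrow(r)) {
    if (!all(r$direction %in% c("F", "R")))
      msg <- c(msg, "direction must be F or R")
    if (!all(grepl("^.+_[FR](_[0-9]+)?$", r$name)))
      msg <- c(msg, "read names must parse to <clone>_<F|R>[_copy]")
  }
  s <- object@sidecar
  if (nrow(s) && !all(s$rightVectorStart - s$leftVectorEnd >= 2))
    msg <- c(msg, "sidecar vector positions must bound a non-empty insert")
  if (length(msg)) msg else TRUE
})

#' ShortReadSet: simulated paired short reads
#'
#' Mates are kept synchronized: row i of `r1` and row i of `r2` are the two
#' ends of fragment i.
#'
#' @slot r1,r2 data.frames with columns `name`, `seq`, `qual` (list of
#'   integer phred scores), `chrom`, `gStart`, `gEnd`, `strand`.
#' @seealso [simulateShortReads()]
#' @export
setClass("ShortReadSet", slots = c(r1 = "data.frame", r2 = "data.frame"))

setValidity("ShortReadSet", function(object) {
  if (nrow(object@r1) != nrow(object@r2))
    return("r1 and r2 must have the same number of reads")
  if (nrow(object@r1) && !identical(object@r1$name, object@r2$name))
    return("mates must be synchronized (same names, same order)")
  TRUE
})

#' SamSet: alignment records plus header
#'
#' A plain-text SAM file held in memory: header lines and a data.frame of
#' records with the eleven mandatory columns (`qname`, `flag`, `rname`,
#' `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`).
#'
#' @slot header character vector of header lines (`@HD`, `@SQ`, ...).
#' @slot records data.frame of alignment records.
#' @seealso [emitAlignments()], [repairSam()], [readSam()], [writeSam()]
#' @export
setClass("SamSet", slots = c(header = "character", records = "data.frame"))

setValidity("SamSet", function(object) {
  need <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "rnext", "pnext", "tlen", "seq", "qual")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @rdname SamSet-class
#' @param header character vector of SAM header lines.
#' @param records data.frame of SAM records.
#' @export
SamSet <- function(header, records) new("SamSet", header = header,
                                        records = as.data.frame(records))

setMethod("show", "SangerReadSet", function(object) {
  cat("SangerReadSet with", nrow(object@reads), "reads from",
      length(unique(object@reads$clone)), "clones\n")
})

setMethod("show", "ShortReadSet", function(object) {
  cat("ShortReadSet with", nrow(object@r1), "read pairs\n")
})

setMethod("show", "SamSet", function(object) {
  cat("SamSet:", length(object@header), "header lines,",
      nrow(object@records), "records\n")
})

setMethod("show", "TruthSet", function(object) {
  lens <- Biostrings::width(object@reference)
  cat("TruthSet with", length(object@reference), "chromosome(s),",
      format(sum(lens), big.mark = ","), "bp total\n")
  cat("  A-het sites:       ", nrow(object@hetSites), "\n")
  cat("  reference errors:  ", nrow(object@refErrors), "\n")
  cat("  B contributions:   ", nrow(object@bContribs), "\n")
})

setMethod("show", "DepthHistogram", function(object) {
  cat("DepthHistogram over", format(object@refLength, big.mark = ","),
      "bp (", format(object@nonNLength, big.mark = ","), "non-N )\n")
  cat("  zero bin (N-corrected):", object@counts[["0"]], "\n")
  cat("  max depth:", max(as.integer(names(object@counts))), "\n")
})

setMethod("show", "AuditSummary", function(object) {
  f <- function(x) format(x, big.mark = ",")
  cat("Variant audit summary\n")
  cat(sprintf("  Total variants            %s\n", f(object@total)))
  cat(sprintf("  Called heterozygotes      %s (%.2f%% of total)\n", f(object@het), object@hetPct))
  cat(sprintf("  Called homozygotes        %s (%.2f%% of total)\n", f(object@hom), object@homPct))
  if (!is.na(object@refUndetected))
    cat(sprintf("  Hom., ref not detected    %s\n", f(object@refUndetected)))
  if (!is.na(object@attributable)) {
    cat(sprintf("  Attributable to 2nd ind.  %s\n", f(object@attributable)))
    cat(sprintf("  Unexplained               %s\n", f(object@unexplained)))
  }
  if (object@skipped > 0)
    cat(sprintf("  (skipped records: %s)\n", f(object@skipped)))
})
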