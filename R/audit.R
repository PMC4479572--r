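#' Classify called genotypes
#'
#' Classifies each variant record by its genotype: two identical non-reference
#' allele indices give a *homozygote*, two distinct indices a *heterozygote*
#' (which includes het-non-ref calls such as 1/2 -- two alleles were
#' detected), and two reference indices the *reference* class, which is
#' excluded from variant totals. Records with a missing or uncalled genotype
#' (`./.` or `NA`) are returned as `NA` and should be skipped (and counted)
#' by callers.
#'
#' @param gt character vector of genotypes (`"0/1"`, `"1/1"`, `"1|2"`, ...).
#' @return factor with levels `heterozygote`, `homozygote`, `reference`;
#'   `NA` for uncalled records.
#' @examples
#' classifyGenotype(c("0/1", "1/1", "1/2", "0/0", "./."))
#' @export
classifyGenotype <- function(gt) {
  if (length(gt) == 0)
    return(factor(character(), levels = c("heterozygote", "homozygote", "reference")))
  parts <- data.table::tstrsplit(gt, "[/|]")
  a <- suppressWarnings(as.integer(parts[[1]]))
  b <- suppressWarnings(as.integer(parts[[2]]))
  out <- rep(NA_character_, length(gt))
  called <- !is.na(a) & !is.na(b)
  out[called & a != b] <- "heterozygote"
  out[called & a == b & a > 0L] <- "homozygote"
  out[called & a == 0L & b == 0L] <- "reference"
  factor(out, levels = c("heterozygote", "homozygote", "reference"))
}

#' Is the reference allele undetected?
#'
#' For called homozygotes, tests whether the allelic-depth (AD) entry of the
#' reference allele is zero, i.e. not a single read carried the reference
#' allele at that position. Such positions are candidates for alleles
#' contributed by another individual (or artifacts with no basis in the
#' source reads). Only the first AD entry is consulted, also for
#' multi-allelic records.
#'
#' @param adRef integer vector: AD of the reference allele (first AD entry).
#'   `NA` (absent AD) gives `NA`, to be excluded from tallies and logged.
#' @return logical vector.
#' @export
referenceNotDetected <- function(adRef) {
  adRef == 0L
}

#' Observed allele sets of a second individual
#'
#' For each queried position (typically the reference-not-detected homozygote
#' set), collects the set of distinct bases observed on the second
#' individual's reads with base quality at least `minBaseQual`. Positions
#' covered by no qualifying read get an empty set (uncallable).
#'
#' Raising `minBaseQual` can only shrink each allele set.
#'
#' @param positions data.frame with columns `chrom`, `pos`.
#' @param pileup base pileup of the second individual ([basePileup()]).
#' @param minBaseQual minimum base quality (default 20, mirroring the
#'   trimming quality standard).
#' @return list of character vectors, one per row of `positions` (in order),
#'   named `chrom:pos`.
#' @export
genotypeSecondIndividual <- function(positions, pileup, minBaseQual = 20L) {
  pos <- as.data.table(positions)[, .(chrom, pos)]
  if (nrow(pos) == 0) return(list())
  pu <- as.data.table(pileup)[qual >= minBaseQual & base != "N"]
  hits <- pu[pos, on = .(chrom, pos), allow.cartesian = TRUE]
  sets <- hits[, .(alleles = list(sort(unique(stats::na.omit(base))))),
               by = .(chrom, pos)]
  out <- sets[pos, on = .(chrom, pos)]$alleles
  out <- lapply(out, function(x) if (is.null(x)) character() else x)
  names(out) <- paste0(pos$chrom, ":", pos$pos)
  out
}

#' Attribute reference alleles to the second individual
#'
#' A reference-not-detected position is *attributable* when the second
#' individual's observed allele set contains the reference allele -- the
#' reference base is then consistent with having been contributed by that
#' individual's reads. All other positions, including those with no
#' qualifying coverage, remain *unexplained*. The two sets partition the
#' input.
#'
#' @param positions data.frame with columns `chrom`, `pos`, `ref`.
#' @param alleleSets list from [genotypeSecondIndividual()], parallel to
#'   `positions`.
#' @return list with data.frames `attributable` and `unexplained`.
#' @export
attributePositions <- function(positions, alleleSets) {
  pos <- as.data.frame(positions)
  stopifnot2(length(alleleSets) == nrow(pos),
             "alleleSets must be parallel to positions")
  hit <- mapply(function(ref, set) ref %in% set, pos$ref, alleleSets,
                USE.NAMES = FALSE)
  if (nrow(pos) == 0) hit <- logical(0)
  list(attributable = pos[hit, , drop = FALSE],
       unexplained = pos[!hit, , drop = FALSE])
}

#' Summarize the variant audit
#'
#' Produces the audit totals: called variants, heterozygote and homozygote
#' counts with percentages (rounded half-up to two decimals), the number of
#' called homozygotes whose reference allele was not detected on any read,
#' and -- when an attribution is supplied -- how many of those are
#' attributable to the second individual versus unexplained
#' (reference-not-detected minus attributable).
#'
#' @param records data.frame of variant records with columns `gt` and
#'   `adRef` (see [tallyVariants()]).
#' @param attribution optional result of [attributePositions()].
#' @return an [AuditSummary-class].
#' @export
summarizeAudit <- function(records, attribution = NULL) {
  rec <- as.data.table(records)
  cls <- classifyGenotype(rec$gt)
  skipped <- sum(is.na(cls))
  het <- sum(cls == "heterozygote", na.rm = TRUE)
  hom <- sum(cls == "homozygote", na.rm = TRUE)
  total <- het + hom
  isHom <- !is.na(cls) & cls == "homozygote"
  adMissing <- isHom & is.na(rec$adRef)
  skipped <- skipped + sum(adMissing)
  refUndet <- sum(referenceNotDetected(rec$adRef[isHom]), na.rm = TRUE)
  attributable <- NA_real_
  unexplained <- NA_real_
  if (!is.null(attribution)) {
    attributable <- nrow(attribution$attributable)
    unexplained <- refUndet - attributable
  }
  new("AuditSummary",
      total = total, het = het, hom = hom,
      hetPct = if (total > 0) roundHalfUp(100 * het / total) else NA_real_,
      homPct = if (total > 0) roundHalfUp(100 * hom / total) else NA_real_,
      refUndetected = refUndet,
      attributable = attributable,
      unexplained = unexplained,
      skipped = skipped)
}

#' Reference-not-detected homozygote positions of a record stream
#'
#' Convenience selector: called homozygotes whose reference AD is zero,
#' returned with their reference alleles for [attributePositions()].
#'
#' @param records data.frame of variant records (see [tallyVariants()]).
#' @return data.frame with columns `chrom`, `pos`, `ref`.
#' @export
refUndetectedPositions <- function(records) {
  rec <- as.data.table(records)
  cls <- classifyGenotype(rec$gt)
  sel <- !is.na(cls) & cls == "homozygote" & !is.na(rec$adRef) & rec$adRef == 0L
  as.data.frame(rec[sel, .(chrom, pos, ref)])
}
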