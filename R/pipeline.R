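#' Configuration for a full audit run
#'
#' Collects every knob of the simulate-trim-align-coverage-audit-repair
#' pipeline in one validated list. A single integer seed drives all draws
#' (stage seeds are derived from it by fixed offsets), so two runs with the
#' same configuration are identical.
#'
#' @param seed master integer seed.
#' @param chromLengths named vector of chromosome lengths.
#' @param hetRate,refErrorRate,bContribRate,nGapSpec see [simulateTruth()].
#' @param sangerDepth Sanger-read fold coverage of individual A (default 8).
#' @param bravoDepth Sanger-read fold coverage of individual B (default 8,
#'   deep enough that attribution is testable at essentially every queried
#'   position).
#' @param shortDepth short-read fold coverage of individual A (default 40).
#' @param readLen,subRate see [simulateShortReads()].
#' @param window,threshold,minLen,longCutoff see [trimSangerReads()].
#' @param lowMax,depthCap see [coverageBeds()] and [foldCoverage()].
#' @param minGtQual,minAdQual see [tallyVariants()].
#' @param minBaseQual see [genotypeSecondIndividual()].
#' @param outDir optional output directory for the artifact tree; `NULL`
#'   keeps everything in memory.
#' @return a validated config list of class `auditConfig`.
#' @export
runConfig <- function(seed = 1L, chromLengths = c(chr1 = 100000L),
                      hetRate = 0.001, refErrorRate = 5e-4,
                      bContribRate = 2e-4, nGapSpec = NULL,
                      sangerDepth = 8, bravoDepth = 8, shortDepth = 40,
                      readLen = 100L, subRate = 0.001,
                      window = 20L, threshold = 400L, minLen = 50L,
                      longCutoff = 200L, lowMax = 2L, depthCap = 25L,
                      minGtQual = 20L, minAdQual = 5L, minBaseQual = 20L,
                      outDir = NULL) {
  cfg <- as.list(environment())
  stopifnot2(is.numeric(seed) && length(seed) == 1, "seed must be one integer")
  stopifnot2(sangerDepth > 0 && shortDepth > 0 && bravoDepth > 0,
             "depth targets must be positive")
  if (!is.null(outDir)) {
    parent <- dirname(normalizePath(outDir, mustWork = FALSE))
    stopifnot2(dir.exists(parent),
               sprintf("output location %s is not resolvable", parent))
  }
  class(cfg) <- "auditConfig"
  cfg
}

#' Run the full assembly audit on synthetic data
#'
#' Orchestrates every stage end to end: simulate a truth world, sequence
#' Sanger-style reads of individual A and B and short reads of A, trim, emit
#' alignments and pileups, compute the coverage histogram (fold coverage,
#' low/zero BED tracks), call variants against the simulated reference,
#' classify them and attribute reference-not-detected homozygotes to B,
#' repair FLAG and mate fields of the raw Sanger SAM, and score the audit
#' against the truth ledgers. With `outDir` set, a deterministic artifact
#' tree is written (FASTA/FASTQ/sidecar, SAM before and after repair, BED
#' tracks, histogram TSV, VCFs, audit summary and recovery table as TSV, and
#' a JSON run report).
#'
#' @param config a config from [runConfig()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly, when writing) a list with elements `truth`, `sanger`,
#'   `trimmed`, `partition`, `samRaw`, `samRepaired`, `histogram`,
#'   `foldCoverage`, `beds`, `variantsSanger`, `variantsShort`,
#'   `auditSanger`, `auditShort`, `attribution`, `recovery`.
#' @export
runAll <- function(config = runConfig(), quiet = FALSE) {
  stopifnot2(inherits(config, "auditConfig"), "need a runConfig() object")
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(cfg$seed)

  say("stage truth: %d chromosome(s), seed %d", length(cfg$chromLengths), seed)
  truth <- simulateTruth(cfg$chromLengths, cfg$hetRate, cfg$refErrorRate,
                         cfg$bContribRate, cfg$nGapSpec, seed = seed)
  ref <- refSequences(truth)

  say("stage sanger reads: depth %g", cfg$sangerDepth)
  sanger <- simulateSangerReads(truth, targetDepth = cfg$sangerDepth,
                                seed = seed + 1L)
  trimmed <- trimSangerReads(sanger, cfg$window, cfg$threshold, cfg$minLen,
                             cfg$longCutoff)
  part <- partitionReads(trimmed)
  say("stage trim: long %d / short %d / discarded %d",
      part$counts[["long"]], part$counts[["short"]], part$counts[["discarded"]])

  samRaw <- emitAlignments(part$long, truth, seed = seed + 2L)

  say("stage bravo reads: depth %g", cfg$bravoDepth)
  bravo <- simulateSangerReads(truth, targetDepth = cfg$bravoDepth,
                               seed = seed + 3L, individual = "B",
                               vectorFlankRange = c(0L, 0L),
                               duplicateFraction = 0)
  samBravo <- emitAlignments(sangerReads(bravo), truth, seed = seed + 4L)
  bravoPileup <- basePileup(samBravo)

  say("stage coverage")
  mergedPu <- rbindlist(list(basePileup(samRaw), bravoPileup))
  setkey(mergedPu, chrom, pos)
  dp <- depthPileup(mergedPu, ref)
  hist <- depthHistogram(dp, ref)
  fold <- foldCoverage(hist, cfg$depthCap)
  beds <- coverageBeds(dp, ref, cfg$lowMax)
  say("  fold coverage (capped): %.2f", fold)

  say("stage variants: sanger")
  vSanger <- tallyVariants(basePileup(samRaw), ref, cfg$minGtQual, cfg$minAdQual)
  auditSanger <- summarizeAudit(vSanger)

  say("stage short reads: depth %g", cfg$shortDepth)
  shorts <- simulateShortReads(truth, targetDepth = cfg$shortDepth,
                               readLen = cfg$readLen, seed = seed + 5L,
                               subRate = cfg$subRate)
  shorts <- shortReadFilter(shorts)
  samShort <- emitAlignments(shorts, truth, seed = seed + 6L)
  vShort <- tallyVariants(basePileup(samShort), ref, cfg$minGtQual, cfg$minAdQual)

  say("stage audit: attribution against bravo")
  undet <- refUndetectedPositions(vShort)
  sets <- genotypeSecondIndividual(undet, bravoPileup, cfg$minBaseQual)
  attribution <- attributePositions(undet, sets)
  auditShort <- summarizeAudit(vShort, attribution)

  say("stage mate repair")
  samRepaired <- repairSam(samRaw)

  recovery <- recoveryReport(truth, vShort, attribution)

  res <- list(truth = truth, sanger = sanger, trimmed = trimmed,
              partition = part$counts, samRaw = samRaw,
              samRepaired = samRepaired, histogram = hist,
              foldCoverage = fold, beds = beds,
              variantsSanger = vSanger, variantsShort = vShort,
              auditSanger = auditSanger, auditShort = auditShort,
              attribution = attribution, recovery = recovery)

  if (!is.null(cfg$outDir)) writeRunArtifacts(res, cfg)
  invisible(res)
}

# artifact tree for a run; every file is plain text
writeRunArtifacts <- function(res, cfg) {
  d <- cfg$outDir
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  ref <- refSequences(res$truth)
  writeFasta(ref, file.path(d, "reference.fasta"))
  writeFastq(sangerReads(res$sanger), file.path(d, "sanger_reads.fastq"))
  writeSidecar(vectorSidecar(res$sanger), file.path(d, "sanger_vector_info.tsv"))
  writeSam(res$samRaw, file.path(d, "sanger_raw.sam"))
  writeSam(res$samRepaired, file.path(d, "sanger_repaired.sam"))
  fwrite(as.data.frame(res$trimmed)[c("name", "class", "trimStart", "trimEnd",
                                      "origLen")],
         file.path(d, "trim_report.tsv"), sep = "\t")
  part <- partitionReads(res$trimmed)
  for (cl in c("long", "short"))
    if (nrow(part[[cl]]) > 0)
      writeFastq(part[[cl]], file.path(d, sprintf("sanger_trimmed_%s.fastq", cl)))
  cnt <- depthCounts(res$histogram)
  fwrite(data.frame(depth = as.integer(names(cnt)), positions = as.numeric(cnt)),
         file.path(d, "coverage_histogram.tsv"), sep = "\t")
  writeBed(res$beds$low, file.path(d, "low_coverage.bed"))
  writeBed(res$beds$zero, file.path(d, "zero_coverage.bed"))
  writeVcf(res$variantsSanger, file.path(d, "variants_sanger.vcf"), ref)
  writeVcf(res$variantsShort, file.path(d, "variants_short.vcf"), ref)
  cls <- classifyGenotype(res$variantsShort$gt)
  isHom <- !is.na(cls) & cls == "homozygote"
  writeVcf(res$variantsShort[!is.na(cls) & cls == "heterozygote"],
           file.path(d, "variants_short_het.vcf"), ref)
  writeVcf(res$variantsShort[isHom], file.path(d, "variants_short_hom.vcf"), ref)
  writeVcf(res$variantsShort[isHom & res$variantsShort$adRef == 0L],
           file.path(d, "variants_short_refundetected.vcf"), ref)
  fwrite(res$recovery, file.path(d, "recovery.tsv"), sep = "\t")
  a <- auditCounts(res$auditShort)
  report <- list(
    config = cfg[setdiff(names(cfg), "outDir")],
    partition = as.list(res$partition),
    foldCoverage = res$foldCoverage,
    auditSanger = as.list(auditCounts(res$auditSanger)),
    auditShort = as.list(a))
  jsonlite::write_json(report, file.path(d, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(d)
}

#' Truth-versus-audit recovery table
#'
#' Confusion table between the truth ledgers and the audit's classification:
#' for each ledger category (A-heterozygous sites, reference errors, B
#' contributions) it counts how many positions were called at all, called
#' heterozygous, called homozygous, flagged reference-not-detected, and
#' attributed to B, with the recovery fraction each category is expected to
#' achieve (heterozygous calls for A-het sites; homozygous,
#' reference-not-detected, attributable calls for B contributions).
#'
#' @param truth a [TruthSet-class].
#' @param records variant records of the audited read set.
#' @param attribution result of [attributePositions()] on those records.
#' @return data.frame with one row per category.
#' @export
recoveryReport <- function(truth, records, attribution) {
  rec <- as.data.table(records)
  rec[, cls := as.character(classifyGenotype(gt))]
  attrKey <- if (nrow(attribution$attributable))
    paste0(attribution$attributable$chrom, ":", attribution$attributable$pos)
  else character()
  scoreLedger <- function(led, want) {
    if (nrow(led) == 0)
      return(list(n = 0L, called = 0L, het = 0L, hom = 0L, refUndet = 0L,
                  attributed = 0L, recovered = 0L, recovery = NA_real_))
    key <- paste0(led$chrom, ":", led$pos)
    m <- rec[paste0(chrom, ":", pos) %in% key]
    mkey <- paste0(m$chrom, ":", m$pos)
    het <- sum(m$cls == "heterozygote", na.rm = TRUE)
    hom <- sum(m$cls == "homozygote", na.rm = TRUE)
    undet <- m$cls == "homozygote" & !is.na(m$adRef) & m$adRef == 0L
    attributed <- sum(mkey[which(undet)] %in% attrKey)
    recovered <- switch(want,
                        het = het,
                        bcontrib = attributed,
                        error = sum(undet, na.rm = TRUE))
    list(n = nrow(led), called = nrow(m), het = het, hom = hom,
         refUndet = sum(undet, na.rm = TRUE), attributed = attributed,
         recovered = recovered, recovery = recovered / nrow(led))
  }
  rows <- list(
    c(list(category = "A_het"), scoreLedger(hetSites(truth), "het")),
    c(list(category = "ref_error"), scoreLedger(refErrors(truth), "error")),
    c(list(category = "B_contribution"), scoreLedger(bContribs(truth), "bcontrib")))
  rec[, cls := NULL]
  rbindlist(rows)
}
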