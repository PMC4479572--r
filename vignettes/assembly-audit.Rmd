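---
title: "Auditing a reference assembly against its source reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a reference assembly against its source reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refaudit)
```

# The model

A haploid reference assembled from one diploid individual (call it A) keeps
exactly one allele at each of A's heterozygous sites. Mapping A's own reads
back to the finished reference and genotyping therefore has a sharp null
expectation: *called variants should be heterozygous*. The audit classifies
departures from this expectation:

* **Called heterozygote** (`0/1`, or het-non-ref such as `1/2`): two alleles
  detected — the expected signature of a site where A is heterozygous. We
  count `1/2` as heterozygous because the defining observation is that two
  alleles were detected.
* **Called homozygote** (`1/1`): every well-supported read contradicts the
  reference. Either the reference base is an error, or it came from another
  genome.
* Within the homozygotes, the **allelic depth** field separates the two
  stories further. `AD` counts reads per allele, reference allele first. If
  `AD[ref] > 0`, at least one (possibly low-quality) read carried the
  reference base — consistent with an error retained from a single bad read.
  If `AD[ref] == 0` ("reference not detected"), the reference base has *no
  basis at all* in A's reads, and a second contributor becomes the prime
  suspect.
* **Attribution**: for each reference-not-detected position we collect the
  bases observed in a second individual B's reads at base quality ≥ 20. If
  the set contains the reference allele, the position is *attributable* to
  B; otherwise (including positions B's reads do not cover) it stays
  *unexplained*. The two sets partition the input, so
  `unexplained = refUndetected − attributable` and the summary is internally
  consistent by construction (the `AuditSummary` validity enforces it).

Percentages in the summary are computed from the het/hom counts and rounded
*half away from zero* to two decimals, matching how such tables are
conventionally printed (base R's banker's rounding would differ on exact
halves).

# The synthetic world

The `synthetic_data` generators are first-class, tested code: they create the
inputs the audit assumes, with truth ledgers that make every downstream
classification scorable.

`simulateTruth()` draws a random genome, then three mutually disjoint
per-position ledgers (priority error > B-contribution > het on collision, the
loser re-drawn at a free position):

| ledger | reference carries | A carries | B carries |
|---|---|---|---|
| reference error | errant allele | true allele (hom) | true allele |
| B contribution | B's allele | another allele (hom) | the reference allele |
| A heterozygous | haplotype-1 allele | both alleles | haplotype-1 allele |

Default rates: `hetRate = 0.001` (a typical mammalian heterozygosity of one
het site per kilobase), `refErrorRate = 5e-4` and `bContribRate = 2e-4`.
The error and contribution rates are chosen once as plausible desk-scale
magnitudes that leave dozens of ledger entries in a 100 kb genome — enough
for stable recovery fractions — while keeping errors more common than
second-individual contributions, as an audit of a real assembly finds. N runs
(assembly gaps) are placed explicitly via `nGapSpec`; ledger positions never
fall inside them, and simulated reads whose span would cross an N run are
dropped, because no read maps onto a gap — this is also what thins coverage
at contig boundaries in real data.

`simulateSangerReads()` emulates paired clone-end capillary reads: clone
starts uniform, insert sizes drawn from {4 000, 10 000, 40 000}, each clone
sequenced from both ends (the R read reverse-complemented), read lengths
uniform in 500–900. Per-base qualities follow a ramp — low over the first
~50 bases, a plateau at Q40, a decaying tail over the last ~150 — so the
window-20/sum-400 trimmer has something real to cut; the ramp is a stand-in,
not a claim about any particular basecaller's error profile. Cloning-vector
flanks of 5–30 bases are prepended (and occasionally appended), with their
extent recorded in a 1-based inclusive sidecar table, mirroring how trace
archives ship vector annotation separately from the reads. A 5% duplicate
fraction gives exemplar selection something to do, and for every ledgered
reference error one covering read is made the *carrier*: it bears the errant
allele at phred quality ≤ 18, the generative origin of that reference base.

`simulateShortReads()` emulates a 100-cycle paired-end run of a 300–400 bp
insert library at 40X. Reads are error-free apart from a per-base
substitution rate of 0.001 (within the range of a filtered short-read run)
at a constant Q37. Substitutions are the one noise source that can
"re-detect" the reference allele at a true contribution site by chance, so a
small rate keeps the audit honest without drowning it.

`emitAlignments()` stands in for the external mapper: records at the true
coordinates, one full-length-match CIGAR, FLAG limited to {0, 16, 4} and no
mate fields — exactly the mate-blind output the repair stage exists to fix.
`tallyVariants()` stands in for the external genotyper: at each position
where any read base differs from the reference it emits GT and AD with the
conventional semantics. Its thresholds are our own defaults, stated and
overridable: AD counts bases at quality ≥ 5; genotypes use bases at
quality ≥ 20, an allele being *present* with ≥ 2 supporting reads or ≥ 20%
of them. Alternates are listed in discovery order (first appearance in the
read stream), reference allele first in AD, per the VCF convention.

# Numerical and coordinate conventions

* **Trim intervals** are 0-based half-open internally. The sidecar's 1-based
  inclusive vector positions (last left-vector base `L`, first right-vector
  base `R`) convert to insert bounds `[L, R − 1)` on ingest; `R` is read as
  the first vector base, i.e. the exclusive end of the insert (whether the
  original annotation meant it inclusively is unknowable from the outside;
  we fixed one reading and documented it).
* **Right quality index**: the trimming description fixes the left index as
  the *first* position of the first qualifying window; we take the right
  index as the *last* position of the first qualifying right-to-left window,
  by symmetry. Reads shorter than the window have no window and are
  discarded. Quality trimming is idempotent: the first window of an already
  trimmed read qualifies by construction.
* **Vector bounds that invert the interval** (left ≥ right) discard the read
  rather than raising an error — a malformed annotation should not abort a
  30-million-read run.
* **Zero-coverage bin**: internal pileup gaps contribute
  `right flank − left flank − 1`; leading and trailing uncovered ranges
  contribute their full lengths. Counting chromosome ends is our extension —
  only internal gaps are described in the printed formula, but excluding
  ends would undercount and break the conservation property (histogram bins
  summing to the non-N length). N counts are subtracted from the raw zero
  bin, clamped at zero.
* **Fold coverage** ignores depths above the cap (default 25) entirely, and
  divides by the *non-N* length: N bases cannot be covered and are already
  excluded from the zero bin, so including them in the denominator would mix
  conventions. Whether the original calculation included them is unstated;
  this is our recorded choice, not an inference about intent.
* **Low-coverage track** ("two or fewer reads") includes depth-0 runs; the
  zero track is also emitted separately so users can subtract. Intervals are
  0-based half-open, merged when abutting.
* **FLAG assembly**: orientation base 0/16/4, +1024 non-exemplar, +256
  non-primary, and the pairing bits (+1, +8 mate unmapped, +64 direction F /
  +128 direction R) *only for reads whose mate was used in the study*. The
  printed rules list the increments separately; gating 64/128 on pairing is
  forced by the stated example of an unpaired forward read keeping FLAG 0,
  and matches the SAM specification, under which first/second-in-pair bits
  are meaningless without the paired bit. The +1 is applied literally to
  every record of a read with a mate in the study, duplicates included.
* **Exemplar selection** requires length strictly > 50 (as printed) even
  though trimming retains reads ≥ 50; the one-base discrepancy is preserved.
  Mean-quality ties break to the longer read, then lexicographic name.
* **Primary selection** takes the highest mapping quality > 40; when no
  mapping exceeds 40 the highest overall wins (ties: chromosome order, then
  leftmost) — a fallback the source description leaves open, chosen so that
  every mapped read has exactly one primary record.
* **ISIZE** follows the SAM signing rule (positive on the leftmost record,
  negative on the rightmost, zero across chromosomes), computed from the
  mate's *primary* alignment: rightmost aligned end − leftmost aligned
  start + 1. The mate of a read is the exemplar of the opposite direction of
  its clone, falling back to the best-mean-quality read when no opposite
  read exceeds 50 bases.
* **Genotyper degenerate cases**: positions whose reference base is N are
  skipped; records with uncalled genotypes (`./.`) or missing AD are skipped
  and counted, never silently dropped.

# What a green test establishes — and what it does not

The simulator reproduces the *statistical structure* the audit relies on:
Poisson-like coverage, clone-end pairing, quality ramps, vector flanks,
ledgered errors with low-quality carriers, and a second genome contributing
reference alleles. It does not model chromatogram artifacts, indel error
modes, homopolymer miscalls, chimeric clones, mapping ambiguity in repeats,
or reference bias — so the parameter-recovery results (≥ 95% of ledgered
B-contributions recovered as homozygous ∧ reference-not-detected ∧
attributable, ≥ 95% of het sites called heterozygous, at 40X short reads on
100 kb) validate the *pipeline logic*, not the error profile of any real
instrument. Genome-scale figures from a real audit (average coverage,
fractions of the genome at low coverage, table totals in the millions)
depend on the real 30-million-read archives and are deliberately out of
scope; the tests instead pin the in-table arithmetic (percentages, the
unexplained remainder) and the bit-level FLAG algebra exactly.

One further recorded observation: in the published short-read table the
printed total is 360 smaller than the sum of its printed het and hom counts;
since the summary here derives the total as het + hom, the tests assert the
percentages (which round identically under either reading) rather than the
inconsistent printed total.

# Tunable parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `window`, `threshold` | 20, 400 | quality window length and sum (mean Q20) |
| `minLen`, `longCutoff` | 50, 200 | discard / long-read boundaries (bases) |
| `q30Fraction`, `tailFloor` | 0.5, 3 | short-read Q30 filter and 3' floor |
| `lowMax`, `depthCap` | 2, 25 | low-coverage track bound; fold-coverage cap |
| `minAdQual`, `minGtQual` | 5, 20 | base-quality floors for AD and GT |
| `minBaseQual` | 20 | floor for second-individual genotyping |
| `hetRate`, `refErrorRate`, `bContribRate` | 1e-3, 5e-4, 2e-4 | per-bp ledger rates |
| `sangerDepth`, `shortDepth`, `bravoDepth` | 8, 40, 8 | fold-coverage targets |

`bravoDepth = 8` deserves a note: a real BAC-end dataset covers its genome
far more thinly, which is why a real audit can attribute only a fraction of
its candidate positions. The default here is deliberately deep so that
attribution is *testable* at essentially every queried position and the
recovery criterion measures classification logic rather than B's coverage;
lowering it moves positions from attributable to unexplained-by-lack-of-
coverage, which `recoveryReport()` makes visible.

# Limitations

Indels flow through the variant audit (allele comparison is exact string
match) but the bundled genotyper only emits SNVs, so indel handling is
exercised only at the record level. Adapter clipping is exact substring
matching; mismatch-tolerant clipping belongs to dedicated tools. The SAM
reader/writer handles the eleven mandatory columns of the plain-text format
and pure-match CIGARs — BAM conversion and general CIGAR algebra are
delegated to standard tooling.
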