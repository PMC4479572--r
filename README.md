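# refaudit

Audit a haploid reference assembly against the sequence reads it was built
from.

## The problem

A haploid reference built from a single diploid individual collapses that
individual's two alleles into one. When the source reads are mapped back to
the finished reference and genotyped, almost every called variant should be
**heterozygous** — the read pileup shows both alleles, the reference kept one
of them. A **called homozygous** difference (genotype `1/1`: every
well-supported read disagrees with the reference) is a red flag. It means
either

* the reference base is an **error** — typically a base miscalled on a single
  low-quality read that was nonetheless chosen for the consensus in a
  low-coverage region, or
* the reference base was **contributed by a different individual** whose
  reads (e.g. BAC-end sequences used for scaffolding) entered the assembly.

The two are separable with the VCF **allelic depth** field (`AD`, per-allele
read counts, reference allele first) and a second individual's reads: a
called homozygote with `AD[ref] == 0` ("reference not detected") whose
reference allele *is* observed in the second individual's reads is
attributable to that individual; the remainder is unexplained by either
genome:

```
unexplained = (# hom with AD[ref] == 0) − (# attributable to individual B)
```

Alongside the variant audit the package computes a depth-of-coverage
histogram whose zero bin is reconstructed from pileup gaps (right flank −
left flank − 1) and corrected for assembly-gap Ns, the depth-capped fold
coverage (Σ d·count(d), d ≤ 25, over the non-N length), BED tracks of low
(≤ 2 reads) and zero coverage, Sanger sliding-window quality/vector trimming
(window 20, sum ≥ 400), and reconstruction of SAM pair information (bitwise
FLAG, MRNM/MPOS/ISIZE) for clone-end reads a mate-blind mapper aligned
independently.

Everything runs on synthetic data with known truth: a simulated diploid
individual A, a related individual B, and a reference derived from A but
carrying ledgered errors and B-contributed alleles, so every classification
can be scored against the generating truth.

## Worked example

```r
library(refaudit)
cfg <- runConfig(seed = 1, chromLengths = c(chr1 = 50000L))
res <- runAll(cfg, quiet = TRUE)
res$auditShort
#> Variant audit summary
#>   Total variants            120
#>   Called heterozygotes      78 (65.00% of total)
#>   Called homozygotes        42 (35.00% of total)
#>   Hom., ref not detected    42
#>   Attributable to 2nd ind.  16
#>   Unexplained               26
res$recovery[, c("category", "n", "het", "hom", "refUndet", "attributed", "recovery")]
#>          category  n het hom refUndet attributed recovery
#> 1:          A_het 65  65   0        0          0        1
#> 2:      ref_error 26   0  26       26          0        1
#> 3: B_contribution 16   0  16       16         16        1
```

Reading the output: 50 kb of genome simulated at the default rates carries 65
heterozygous sites, 26 injected reference errors and 16 B-contributed
reference alleles. Auditing 40X of simulated short reads called all 65 het
sites heterozygous, and all 42 error/B positions homozygous with the
reference allele absent from A's reads; genotyping B's reads at those
positions attributed exactly the 16 B contributions, leaving the 26 errors
unexplained — a perfect recovery of the generating truth (last column). With
`outDir` set, `runAll()` also writes the artifact tree (FASTA/FASTQ/sidecar,
SAM before and after mate repair, BED tracks, histogram TSV, VCFs, recovery
table, JSON run report).

## Acceptance script

`scripts/acceptance.R` recomputes the acceptance targets from scratch with
the installed package — it rebuilds the relevant alignment context, runs the
package's FLAG reconstruction through both its direct and its SAM-reprocessing
route, and writes the resulting values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
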