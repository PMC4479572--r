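Package: refaudit
Title: Auditing a Reference Assembly Against Its Own Source Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to audit a haploid reference assembly against the sequence
    reads it was built from. Implements sliding-window quality and vector
    trimming of Sanger-style reads, depth-of-coverage histograms with a gap-
    and N-corrected zero bin and low/zero-coverage BED annotation, allelic
    depth (AD) based classification of variant calls into heterozygous and
    homozygous discrepancies, detection of homozygous positions where the
    reference allele is absent from the source individual's reads,
    attribution of such positions to a second contributing individual, and
    reconstruction of bitwise FLAG and mate fields (MRNM, MPOS, ISIZE) in
    alignment records. A synthetic-data module simulates diploid truth
    genomes, Sanger-like and Illumina-like reads, alignments, pileups and
    variant calls with known truth ledgers so that the full audit can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'audit.R'
    'coverage.R'
    'io.R'
    'matefix.R'
    'pipeline.R'
    'refaudit-package.R'
    'synthetic-align.R'
    'synthetic-reads.R'
    'synthetic-truth.R'
    'trim.R'
    'utils.R'
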