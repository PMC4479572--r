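#' @importFrom data.table fread fwrite
NULL

#' Read and write the audit's file formats
#'
#' Thin wrappers over Biostrings and data.table for the plain-text formats
#' the pipeline exchanges: FASTA references, phred+33 FASTQ, SAM, VCF 4.2
#' with GT and AD, samtools-style depth pileups (`chrom`, `pos`, `ref`,
#' `depth`), the tab-separated vector-trim sidecar (`name`, `leftVectorEnd`,
#' `rightVectorStart`; 1-based inclusive), and 3-column BED (0-based
#' half-open).
#'
#' @param path file path.
#' @param reference a [Biostrings::DNAStringSet].
#' @name io
NULL

#' @rdname io
#' @export
writeFasta <- function(reference, path) {
  S4Vectors::mcols(reference) <- NULL
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' @rdname io
#' @export
readFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname io
#' @param reads data.frame with `name`, `seq` and `qual` (list of integer
#'   phred scores), e.g. [sangerReads()] or one mate of [readPairs()].
#' @export
writeFastq <- function(reads, path) {
  qc <- vapply(reads$qual, function(q) rawToChar(as.raw(pmin(q, 93L) + 33L)),
               character(1))
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+", qc))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
readFastq <- function(path) {
  # Biostrings warns while dropping the (empty) mcols it attaches internally
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(name = names(x), seq = as.character(x),
             qual = I(as.list(methods::as(Biostrings::quality(x), "IntegerList"))),
             stringsAsFactors = FALSE)
}

#' @rdname io
#' @param sidecar data.frame as in [vectorSidecar()].
#' @export
writeSidecar <- function(sidecar, path) {
  fwrite(sidecar, path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @export
readVectorSidecar <- function(path) {
  as.data.frame(fread(path, sep = "\t", colClasses = list(
    character = "name", integer = c("leftVectorEnd", "rightVectorStart"))))
}

#' @rdname io
#' @param sam a [SamSet-class].
#' @export
writeSam <- function(sam, path) {
  rec <- as.data.frame(samRecords(sam))
  body <- if (nrow(rec) == 0) character() else
    do.call(paste, c(rec[c("qname", "flag", "rname", "pos", "mapq", "cigar",
                           "rnext", "pnext", "tlen", "seq", "qual")],
                     sep = "\t"))
  writeLines(c(samHeader(sam), body), path)
  invisible(path)
}

#' @rdname io
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    rec <- data.table(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(), tlen = integer(),
                      seq = character(), qual = character())
    return(SamSet(hdr, rec))
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  rec <- data.table(qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
                    pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]),
                    cigar = f[[6]], rnext = f[[7]], pnext = as.integer(f[[8]]),
                    tlen = as.integer(f[[9]]), seq = f[[10]], qual = f[[11]])
  SamSet(hdr, rec)
}

#' @rdname io
#' @param pileup data.frame with `chrom`, `pos`, `ref`, `depth`.
#' @export
writePileup <- function(pileup, path) {
  fwrite(as.data.frame(pileup)[c("chrom", "pos", "ref", "depth")], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readPileup <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "pos", "ref", "depth"))
  dt[]
}

#' @rdname io
#' @param records variant records as from [tallyVariants()].
#' @param sampleName sample column name in the VCF.
#' @export
writeVcf <- function(records, path, reference = NULL, sampleName = "sample") {
  rec <- as.data.table(records)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(reference))
             paste0("##contig=<ID=", names(reference), ",length=",
                    Biostrings::width(reference), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sampleName, sep = "\t"))
  body <- if (nrow(rec) == 0) character() else
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".", "PASS", ".",
          "GT:AD", paste0(rec$gt, ":", rec$ad), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname io
#' @export
readVcfRecords <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), ad = character(),
                      adRef = integer())
  if (length(body) == 0) return(empty)
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  fmt <- strsplit(f[[9]], ":", fixed = TRUE)
  smp <- strsplit(f[[10]], ":", fixed = TRUE)
  pick <- function(key) mapply(function(k, v) {
    i <- match(key, k)
    if (is.na(i)) NA_character_ else v[i]
  }, fmt, smp, USE.NAMES = FALSE)
  ad <- pick("AD")
  data.table(chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]],
             alt = f[[5]], gt = pick("GT"), ad = ad,
             adRef = suppressWarnings(as.integer(sub(",.*$", "", ad))))
}

#' @rdname io
#' @param gr a [GenomicRanges::GRanges] (e.g. from [coverageBeds()]).
#' @export
writeBed <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr), sep = "\t"), path)
  invisible(path)
}
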