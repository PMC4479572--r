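#' Assemble and decompose the bitwise FLAG
#'
#' `computeFlag()` assembles the SAM FLAG from the audit's reprocessing
#' rules: the orientation base is 0 (forward), 16 (reverse) or 4 (unmapped);
#' 1024 is added for non-exemplar (duplicate) reads; if the read's mate was
#' used in the study, 1 is added, plus 8 when that mate is unmapped, plus 64
#' for direction F ("first in pair") or 128 for direction R ("second in
#' pair"); 256 is added to every record that is not the primary alignment.
#' The pairing bits (1/8/64/128) are only set for reads whose mate was used
#' -- an unpaired forward exemplar primary record keeps FLAG 0. A direction
#' token that is neither F nor R leaves 64/128 unset (with a warning).
#'
#' `decodeFlag()` splits a FLAG into these components; the decomposition is
#' unique, and `computeFlag(decodeFlag(f)) == f` for every valid FLAG.
#'
#' @param mapped is this record mapped?
#' @param reverse is the read mapped in reverse orientation? (ignored when
#'   unmapped)
#' @param direction direction token, `"F"` or `"R"`.
#' @param exemplar is the read the exemplar of its clone/direction group?
#' @param primary is this record the primary alignment?
#' @param mateUsed was a mate of this read used in the study?
#' @param mateMapped is the mate's primary alignment mapped?
#' @return `computeFlag`: integer FLAG. `decodeFlag`: named list of the
#'   arguments above.
#' @examples
#' computeFlag(mapped = TRUE, reverse = FALSE)                   # 0
#' computeFlag(mapped = FALSE)                                   # 4
#' computeFlag(mapped = TRUE, reverse = TRUE, direction = "R",
#'             mateUsed = TRUE, mateMapped = TRUE)               # 145
#' @export
computeFlag <- function(mapped = TRUE, reverse = FALSE, direction = NA_character_,
                        exemplar = TRUE, primary = TRUE,
                        mateUsed = FALSE, mateMapped = TRUE) {
  flag <- if (!mapped) 4L else if (reverse) 16L else 0L
  if (!exemplar) flag <- flag + 1024L
  if (mateUsed) {
    flag <- flag + 1L
    if (!mateMapped) flag <- flag + 8L
    if (identical(direction, "F")) flag <- flag + 64L
    else if (identical(direction, "R")) flag <- flag + 128L
    else warning("direction token is neither F nor R; 64/128 omitted")
  }
  if (!primary) flag <- flag + 256L
  flag
}

#' @rdname computeFlag
#' @param flag integer FLAG to decompose.
#' @export
decodeFlag <- function(flag) {
  has <- function(bit) bitwAnd(flag, bit) != 0L
  stopifnot2(!(has(4L) && has(16L)), "FLAG cannot be both unmapped and reverse")
  stopifnot2(!has(8L) || has(1L), "mate-unmapped bit requires the paired bit")
  stopifnot2(!(has(64L) && has(128L)), "FLAG cannot be both first and second in pair")
  list(mapped = !has(4L),
       reverse = has(16L),
       direction = if (has(64L)) "F" else if (has(128L)) "R" else NA_character_,
       exemplar = !has(1024L),
       primary = !has(256L),
       mateUsed = has(1L),
       mateMapped = !has(8L))
}

#' Select the exemplar read of a clone/direction group
#'
#' When a clone was sequenced more than once in the same direction, the
#' single read longer than 50 bases with the highest average quality score is
#' the *exemplar*; every other read of the group is a duplicate (+1024 in the
#' FLAG). Ties on mean quality are broken by the longer read, then by name.
#' If no read exceeds 50 bases the group has no exemplar and all members are
#' duplicates.
#'
#' @param lengths integer vector of read lengths.
#' @param meanQuals numeric vector of mean base qualities.
#' @param names optional character vector of read names (tie-break).
#' @return integer index of the exemplar, or `NA` if no read qualifies.
#' @export
selectExemplar <- function(lengths, meanQuals, names = NULL) {
  stopifnot2(length(lengths) > 0, "group must be non-empty")
  cand <- which(lengths > 50L)
  if (length(cand) == 0) return(NA_integer_)
  if (is.null(names)) names <- as.character(seq_along(lengths))
  o <- order(-meanQuals[cand], -lengths[cand], names[cand])
  cand[o[1]]
}

#' Select the primary mapping of a multiply-mapped read
#'
#' The mapping with the highest quality greater than 40 is primary; all
#' other records get +256. When no mapping exceeds quality 40, the highest
#' quality overall wins, with ties broken by chromosome order, then leftmost
#' position.
#'
#' @param mapq integer vector of mapping qualities.
#' @param chrom,pos optional vectors for tie-breaking.
#' @return integer index of the primary mapping.
#' @export
selectPrimary <- function(mapq, chrom = NULL, pos = NULL) {
  stopifnot2(length(mapq) > 0, "need at least one mapping")
  if (is.null(chrom)) chrom <- rep("", length(mapq))
  if (is.null(pos)) pos <- seq_along(mapq)
  cand <- which(mapq > 40L)
  if (length(cand) == 0) cand <- seq_along(mapq)
  o <- order(-mapq[cand], chrom[cand], pos[cand])
  cand[o[1]]
}

# reference span of a CIGAR (M/D/N/=/X consume reference)
cigarRefSpan <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Fill mate fields from the mate's primary alignment
#'
#' Computes MRNM, MPOS and ISIZE for a record given its mate's primary
#' alignment: MRNM is `"="` on the same chromosome, otherwise the mate's
#' chromosome; MPOS is the mate's 1-based primary position; ISIZE is the
#' signed template length (rightmost aligned end minus leftmost aligned start
#' plus one), positive on the leftmost record and negative on the rightmost,
#' and 0 when the two records sit on different chromosomes. An unmapped mate
#' gives `"*"`, 0, 0.
#'
#' @param chrom,pos,span chromosome, 1-based position and reference span of
#'   the record itself.
#' @param mateChrom,matePos,mateSpan the same for the mate's primary
#'   alignment, or `NA` when the mate is unmapped or absent.
#' @return list with `mrnm`, `mpos`, `isize`.
#' @export
fillMateFields <- function(chrom, pos, span, mateChrom, matePos, mateSpan) {
  if (is.na(mateChrom))
    return(list(mrnm = "*", mpos = 0L, isize = 0L))
  if (!identical(chrom, mateChrom))
    return(list(mrnm = mateChrom, mpos = as.integer(matePos), isize = 0L))
  left <- min(pos, matePos)
  right <- max(pos + span - 1L, matePos + mateSpan - 1L)
  tl <- right - left + 1L
  sgn <- if (pos > matePos) -1L else 1L   # leftmost record carries the + sign
  list(mrnm = "=", mpos = as.integer(matePos), isize = as.integer(sgn * tl))
}

# parse "<clone>_<F|R>[_copy]" read names; returns NA fields when unparseable
parseReadName <- function(qname) {
  m <- regmatches(qname, regexec("^(.+)_([FR])(?:_[0-9]+)?$", qname))
  clone <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, character(1))
  dir <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, character(1))
  list(clone = clone, direction = dir)
}

#' Reconstruct FLAG and mate fields of a SAM file
#'
#' Two-pass reprocessing of alignment records whose names encode clone and
#' direction (`<clone>_<F|R>[_copy]`). Pass one indexes, per read, its
#' mappings and primary alignment (mapping quality > 40, see
#' [selectPrimary()]) and, per clone/direction group, its exemplar read
#' ([selectExemplar()]). Pass two rewrites every FLAG from scratch with
#' [computeFlag()] and fills MRNM/MPOS/ISIZE from the mate's primary
#' alignment ([fillMateFields()]); the mate of a read is the exemplar of the
#' opposite direction of its clone (falling back to the best-quality read
#' when the opposite group has no exemplar). Record count, sequence and CIGAR
#' are never changed, and the procedure is idempotent.
#'
#' Records with unparseable names pass through untouched and are counted in
#' the report attribute (`attr(x, "repairReport")`).
#'
#' @param sam a [SamSet-class] (e.g. from [emitAlignments()] or [readSam()]).
#' @return a repaired [SamSet-class]; `attr(, "repairReport")` holds counts.
#' @export
repairSam <- function(sam) {
  rec <- as.data.table(samRecords(sam))
  if (nrow(rec) == 0) return(SamSet(samHeader(sam), rec))
  nm <- parseReadName(rec$qname)
  rec[, `:=`(clone = nm$clone, direction = nm$direction)]
  parseable <- !is.na(rec$clone)

  # per-read (qname) summary: mapping records, primary index, length, mean qual
  rec[, rowid := .I]
  rd <- rec[parseable, {
    mapped <- bitwAnd(flag, 4L) == 0L
    pri <- if (any(mapped)) {
      mi <- which(mapped)
      mi[selectPrimary(mapq[mi], rname[mi], pos[mi])]
    } else NA_integer_
    .(clone = clone[1], direction = direction[1],
      len = nchar(seq[1]),
      meanQ = mean(as.integer(charToRaw(qual[1])) - 33),
      anyMapped = any(mapped),
      priRow = if (is.na(pri)) NA_integer_ else rowid[pri],
      priChrom = if (is.na(pri)) NA_character_ else rname[pri],
      priPos = if (is.na(pri)) NA_integer_ else as.integer(pos[pri]),
      priSpan = if (is.na(pri)) NA_integer_ else cigarRefSpan(cigar[pri]))
  }, by = qname]

  # exemplar per clone/direction group
  rd[, exemplar := {
    i <- selectExemplar(len, meanQ, qname)
    v <- rep(FALSE, .N)
    if (!is.na(i)) v[i] <- TRUE
    v
  }, by = .(clone, direction)]

  # mate read per clone/direction: exemplar of the opposite direction,
  # falling back to the best mean quality when no exemplar exists
  rd[, mateKey := paste0(clone, "/", ifelse(direction == "F", "R", "F"))]
  grp <- rd[, {
    i <- selectExemplar(len, meanQ, qname)
    if (is.na(i)) i <- order(-meanQ, qname)[1]
    .(mateName = qname[i], mateMapped = anyMapped[i],
      mateChrom = priChrom[i], matePos = priPos[i], mateSpan = priSpan[i])
  }, by = .(clone, direction)]
  grp[, key := paste0(clone, "/", direction)]
  mate <- grp[match(rd$mateKey, grp$key)]
  rd[, `:=`(mateUsed = !is.na(mate$mateName), mateMapped = mate$mateMapped,
            mateChrom = mate$mateChrom, matePos = mate$matePos,
            mateSpan = mate$mateSpan)]

  # pass 2: rewrite FLAG and mate fields
  info <- rd[match(rec$qname, rd$qname)]
  nf <- rec$flag
  mr <- rec$rnext; mp <- rec$pnext; tl <- rec$tlen
  for (i in which(parseable)) {
    mapped <- bitwAnd(rec$flag[i], 4L) == 0L
    reverse <- bitwAnd(rec$flag[i], 16L) != 0L
    isPrimary <- !mapped || identical(info$priRow[i], rec$rowid[i])
    nf[i] <- computeFlag(
      mapped = mapped, reverse = reverse, direction = info$direction[i],
      exemplar = info$exemplar[i], primary = isPrimary,
      mateUsed = info$mateUsed[i],
      mateMapped = isTRUE(info$mateUsed[i]) && isTRUE(info$mateMapped[i]))
    if (info$mateUsed[i] && isTRUE(info$mateMapped[i]) && mapped) {
      mf <- fillMateFields(rec$rname[i], as.integer(rec$pos[i]),
                           cigarRefSpan(rec$cigar[i]),
                           info$mateChrom[i], info$matePos[i], info$mateSpan[i])
      mr[i] <- mf$mrnm; mp[i] <- mf$mpos; tl[i] <- mf$isize
    } else {
      mr[i] <- "*"; mp[i] <- 0L; tl[i] <- 0L
    }
  }
  out <- data.table::copy(rec)
  out[, `:=`(flag = nf, rnext = mr, pnext = mp, tlen = tl,
             clone = NULL, direction = NULL, rowid = NULL)]
  res <- SamSet(samHeader(sam), out)
  attr(res, "repairReport") <- c(records = nrow(rec),
                                 unparseable = sum(!parseable),
                                 reads = nrow(rd),
                                 duplicates = sum(!rd$exemplar))
  res
}
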