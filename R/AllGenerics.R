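#' @include AllClasses.R
NULL

#' Accessors for TruthSet, DepthHistogram and AuditSummary
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x a [TruthSet-class], [DepthHistogram-class] or
#'   [AuditSummary-class] object, as appropriate.
#' @return the slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("consensusB", function(x) standardGeneric("consensusB"))
#' @rdname accessors
#' @export
setGeneric("refErrors", function(x) standardGeneric("refErrors"))
#' @rdname accessors
#' @export
setGeneric("bContribs", function(x) standardGeneric("bContribs"))
#' @rdname accessors
#' @export
setGeneric("hetSites", function(x) standardGeneric("hetSites"))
#' @rdname accessors
#' @export
setGeneric("depthCounts", function(x) standardGeneric("depthCounts"))
#' @rdname accessors
#' @export
setGeneric("nCounts", function(x) standardGeneric("nCounts"))
#' @rdname accessors
#' @export
setGeneric("nonNLength", function(x) standardGeneric("nonNLength"))
#' @rdname accessors
#' @export
setGeneric("auditCounts", function(x) standardGeneric("auditCounts"))

#' @rdname accessors
#' @export
setGeneric("sangerReads", function(x) standardGeneric("sangerReads"))
#' @rdname accessors
#' @export
setGeneric("vectorSidecar", function(x) standardGeneric("vectorSidecar"))
#' @rdname accessors
#' @export
setGeneric("readPairs", function(x) standardGeneric("readPairs"))
#' @rdname accessors
#' @export
setGeneric("samHeader", function(x) standardGeneric("samHeader"))
#' @rdname accessors
#' @export
setGeneric("samRecords", function(x) standardGeneric("samRecords"))

#' @rdname accessors
#' @export
setMethod("refSequences", "TruthSet", function(x) x@reference)
#' @rdname accessors
#' @export
setMethod("haplotypes", "TruthSet", function(x) list(A1 = x@haplotypeA1, A2 = x@haplotypeA2))
#' @rdname accessors
#' @export
setMethod("consensusB", "TruthSet", function(x) x@consensusB)
#' @rdname accessors
#' @export
setMethod("refErrors", "TruthSet", function(x) x@refErrors)
#' @rdname accessors
#' @export
setMethod("bContribs", "TruthSet", function(x) x@bContribs)
#' @rdname accessors
#' @export
setMethod("hetSites", "TruthSet", function(x) x@hetSites)

#' @rdname accessors
#' @export
setMethod("depthCounts", "DepthHistogram", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("nCounts", "DepthHistogram", function(x) x@nCounts)
#' @rdname accessors
#' @export
setMethod("nonNLength", "DepthHistogram", function(x) x@nonNLength)

#' @rdname accessors
#' @export
setMethod("sangerReads", "SangerReadSet", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("vectorSidecar", "SangerReadSet", function(x) x@sidecar)
#' @rdname accessors
#' @export
setMethod("readPairs", "ShortReadSet", function(x) list(r1 = x@r1, r2 = x@r2))
#' @rdname accessors
#' @export
setMethod("samHeader", "SamSet", function(x) x@header)
#' @rdname accessors
#' @export
setMethod("samRecords", "SamSet", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("auditCounts", "AuditSummary", function(x) {
  c(total = x@total, het = x@het, hom = x@hom,
    hetPct = x@hetPct, homPct = x@homPct,
    refUndetected = x@refUndetected, attributable = x@attributable,
    unexplained = x@unexplained, skipped = x@skipped)
})
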