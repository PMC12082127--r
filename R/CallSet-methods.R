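#' Construct a CallSet
#'
#' Low-level constructor; the usual entry points are
#' \code{\link{readCallerVcf}} and the synthetic-fixture generators.
#'
#' @param calls \code{GRanges} with the metadata columns required for
#'   \code{callClass} (see \code{\linkS4class{CallSet}}).
#' @param caller Caller identifier.
#' @param callClass One of \code{"smallvariant"}, \code{"sv"},
#'   \code{"cnv"}, \code{"mixed"}.
#' @param provenance Optional list of ingest metadata.
#' @return A \code{\linkS4class{CallSet}}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1000),
#'   ref = "A", alt = "T", vtype = "SNV", genotype = "het",
#'   vaf = 0.48, quality = 30, size_change = 0L)
#' CallSet(gr, caller = "clair3", callClass = "smallvariant")
#' @export
CallSet <- function(calls, caller, callClass, provenance = list()) {
  methods::new("CallSet", calls = calls, caller = caller,
               callClass = callClass, provenance = provenance)
}

#' Accessors for CallSet
#'
#' @param x A \code{\linkS4class{CallSet}}.
#' @return \code{callerId}: the caller identifier; \code{callClass}: the
#'   record class; \code{calls}: the underlying \code{GRanges};
#'   \code{provenance}: the ingest metadata list; \code{length}: the
#'   number of records.
#' @name CallSet-accessors
#' @aliases callerId callClass calls provenance
NULL

#' @rdname CallSet-accessors
#' @export
setMethod("callerId", "CallSet", function(x) x@caller)

#' @rdname CallSet-accessors
#' @export
setMethod("callClass", "CallSet", function(x) x@callClass)

#' @rdname CallSet-accessors
#' @export
setMethod("calls", "CallSet", function(x) x@calls)

#' @rdname CallSet-accessors
#' @export
setMethod("provenance", "CallSet", function(x) x@provenance)

#' @rdname CallSet-accessors
#' @param ... Unused.
#' @export
setMethod("length", "CallSet", function(x) length(x@calls))

#' @describeIn CallSet-accessors Subset records, preserving metadata.
#' @param i Index vector.
#' @param j,drop Unused.
#' @export
setMethod("[", "CallSet", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, calls = x@calls[i])
})

setMethod("show", "CallSet", function(object) {
  cat("CallSet of ", length(object), " record(s) [", object@callClass,
      "] from caller '", object@caller, "'\n", sep = "")
  if (length(object)) {
    tab <- switch(object@callClass,
      smallvariant = table(S4Vectors::mcols(object@calls)$vtype),
      sv = table(S4Vectors::mcols(object@calls)$svtype),
      cnv = table(S4Vectors::mcols(object@calls)$copy_state),
      mixed = table(S4Vectors::mcols(object@calls)$class))
    cat("  ", paste(names(tab), as.integer(tab), sep = ":",
                    collapse = "  "), "\n", sep = "")
  }
  q <- object@provenance$quarantined
  if (!is.null(q) && nrow(q))
    cat("  ", nrow(q), " record(s) quarantined at ingest\n", sep = "")
  invisible(NULL)
})

## Replace the record GRanges, keeping caller/class/provenance.
.replaceCalls <- function(x, gr) methods::initialize(x, calls = gr)

## Size of a record in bp: |size_change| for small variants, svlen for SVs
## (NA for BND), segment width for CNVs.
.callSizes <- function(x) {
  mc <- S4Vectors::mcols(x@calls)
  switch(x@callClass,
    smallvariant = abs(mc$size_change),
    sv = mc$svlen,
    cnv = BiocGenerics::width(x@calls),
    mixed = ifelse(mc$class == "smallvariant", abs(mc$size_change),
                   ifelse(mc$class == "cnv", BiocGenerics::width(x@calls),
                          mc$svlen)))
}

## svtype-like label used by the rules matrix and the merge step.
.callTypes <- function(x) {
  mc <- S4Vectors::mcols(x@calls)
  switch(x@callClass,
    smallvariant = as.character(mc$vtype),
    sv = as.character(mc$svtype),
    cnv = as.character(mc$copy_state),
    mixed = as.character(mc$typelab))
}
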