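#' @rdname CallSet-accessors
#' @export
setGeneric("callerId", function(x) standardGeneric("callerId"))

#' @rdname CallSet-accessors
#' @export
setGeneric("callClass", function(x) standardGeneric("callClass"))

#' @rdname CallSet-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CallSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname GenePanel-accessors
#' @export
setGeneric("exons", function(x, ...) standardGeneric("exons"))

#' @rdname GenePanel-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname GenePanel-accessors
#' @export
setGeneric("geneSpans", function(x, ...) standardGeneric("geneSpans"))

#' @rdname ConcordanceReport-class
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname FunnelReport-class
#' @export
setGeneric("funnelStages", function(x) standardGeneric("funnelStages"))
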