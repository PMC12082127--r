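## Caller dialect registry.
##
## Each supported caller writes VCF with its own conventions: which INFO
## keys encode SV type/length/end, where allele depths or VAFs live,
## whether symbolic ALTs are used, and whether undetermined rearrangements
## are emitted as generic breakpoints. The registry captures those
## conventions; every reader/writer goes through it. Key maps are
## best-effort defaults and can be overridden record-by-record via
## `callerDialect()`.

.DIALECT_FIELDS <- c("caller", "class", "svtype_key", "svlen_key",
                     "end_key", "support_key", "vaf_key", "q0_key",
                     "pn_key", "pval_key", "binsize_key", "symbolic_alt",
                     "generic_bnd", "ad_format")

.defaultDialects <- function() {
  list(
    clair3 = list(caller = "clair3", class = "smallvariant",
                  ad_format = "AD", vaf_key = "AF"),
    nanovar = list(caller = "nanovar", class = "sv", svtype_key = "SVTYPE",
                   svlen_key = "SVLEN", end_key = "END",
                   support_key = "SR", symbolic_alt = TRUE,
                   generic_bnd = TRUE),
    debreak = list(caller = "debreak", class = "sv", svtype_key = "SVTYPE",
                   svlen_key = "SVLEN", end_key = "END",
                   support_key = "SUPPREAD", symbolic_alt = TRUE,
                   generic_bnd = FALSE),
    sniffles = list(caller = "sniffles", class = "sv",
                    svtype_key = "SVTYPE", svlen_key = "SVLEN",
                    end_key = "END", support_key = "SUPPORT",
                    symbolic_alt = TRUE, generic_bnd = FALSE),
    cnvpytor = list(caller = "cnvpytor", class = "cnv",
                    svtype_key = "SVTYPE", end_key = "END",
                    q0_key = "natQ0", pn_key = "pN", pval_key = "pVal",
                    binsize_key = "BINS", symbolic_alt = TRUE),
    qdnaseq = list(caller = "qdnaseq", class = "cnv",
                   svtype_key = "SVTYPE", end_key = "END",
                   binsize_key = "BINSIZE", symbolic_alt = TRUE),
    paraphase = list(caller = "paraphase", class = "smallvariant",
                     vaf_key = "VAF", ad_format = NULL),
    unified = list(caller = "unified", class = "mixed",
                   svtype_key = "SVTYPE", svlen_key = "SVLEN",
                   end_key = "END", support_key = "SUPPORT",
                   vaf_key = "VAF", q0_key = "Q0", pn_key = "PN",
                   pval_key = "PVAL", binsize_key = "BINSIZE",
                   symbolic_alt = TRUE, generic_bnd = FALSE,
                   ad_format = NULL)
  )
}

.dialectRegistry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- .defaultDialects()
    reg
  }
})

#' Look up or customise a caller dialect
#'
#' Returns the INFO-key map and conventions for a registered caller,
#' optionally overriding individual fields (the published key maps are
#' best-effort defaults — real deployments should pin them in the run
#' configuration).
#'
#' @param caller Caller identifier (one of \code{clair3}, \code{nanovar},
#'   \code{debreak}, \code{sniffles}, \code{cnvpytor}, \code{qdnaseq},
#'   \code{paraphase}, \code{unified}).
#' @param ... Named fields to override, e.g. \code{svlen_key = "SVLENGTH"}.
#' @return A dialect list with fields \code{caller}, \code{class} and the
#'   key-map entries.
#' @examples
#' callerDialect("debreak")$support_key
#' callerDialect("debreak", support_key = "RE")$support_key
#' @export
callerDialect <- function(caller, ...) {
  reg <- .dialectRegistry()
  if (!(caller %in% names(reg)))
    stop("unregistered caller: ", caller,
         " (known: ", paste(names(reg), collapse = ", "), ")")
  d <- reg[[caller]]
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .DIALECT_FIELDS)
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Registered caller identifiers
#' @return Character vector of caller ids with a registered dialect.
#' @examples registeredCallers()
#' @export
registeredCallers <- function() names(.dialectRegistry())
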