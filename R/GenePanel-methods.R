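#' Construct a GenePanel from an exon GRanges
#'
#' Groups exons by gene symbol, sorts them, merges overlapping exons of the
#' same gene (with a warning), and derives the per-gene span table.
#'
#' @param exons \code{GRanges} with metadata column \code{symbol}; an
#'   optional \code{strand} is taken from the GRanges strand; an optional
#'   logical metadata column \code{phenotype_associated} defaults to
#'   \code{TRUE} (a panel file \emph{is} the phenotype list).
#' @return A \code{\linkS4class{GenePanel}}.
#' @examples
#' ex <- GenomicRanges::GRanges("chr16",
#'   IRanges::IRanges(c(2100001, 2100501), c(2100200, 2100700)),
#'   symbol = "PKD1")
#' GenePanel(ex)
#' @export
GenePanel <- function(exons) {
  mc <- S4Vectors::mcols(exons)
  if (!("symbol" %in% colnames(mc)))
    stop("exons must carry a 'symbol' metadata column")
  if (!("phenotype_associated" %in% colnames(mc)))
    S4Vectors::mcols(exons)$phenotype_associated <-
      rep(TRUE, length(exons))
  ## per-gene: sort and merge overlapping exons
  out <- list(); rows <- list()
  for (sym in unique(S4Vectors::mcols(exons)$symbol)) {
    ex <- exons[S4Vectors::mcols(exons)$symbol == sym]
    contigs <- unique(as.character(GenomeInfoDb::seqnames(ex)))
    if (length(contigs) > 1L)
      stop("gene ", sym, " has exons on multiple contigs")
    ex <- BiocGenerics::sort(ex, ignore.strand = TRUE)
    red <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
    if (length(red) < length(ex)) {
      warning("overlapping exons merged for gene ", sym)
      S4Vectors::mcols(red)$symbol <- sym
      S4Vectors::mcols(red)$phenotype_associated <-
        S4Vectors::mcols(ex)$phenotype_associated[1L]
      BiocGenerics::strand(red) <- BiocGenerics::strand(ex)[1L]
      ex <- red
    }
    out[[sym]] <- ex
    rows[[sym]] <- data.frame(
      symbol = sym, contig = contigs,
      strand = as.character(BiocGenerics::strand(ex))[1L],
      phenotype_associated =
        isTRUE(S4Vectors::mcols(ex)$phenotype_associated[1L]),
      gene_start = min(BiocGenerics::start(ex)),
      gene_end = max(BiocGenerics::end(ex)),
      n_exons = length(ex), stringsAsFactors = FALSE)
  }
  exons <- if (length(out)) .bindGRanges(unname(out)) else
    GenomicRanges::GRanges(symbol = character())
  genes <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(symbol = character(), contig = character(),
               strand = character(), phenotype_associated = logical(),
               gene_start = integer(), gene_end = integer(),
               n_exons = integer())
  methods::new("GenePanel", exons = exons, genes = genes)
}

#' Accessors for GenePanel
#'
#' @param x A \code{\linkS4class{GenePanel}}.
#' @param symbol Optional gene symbol to restrict \code{exons} to one gene.
#' @param phenotypeOnly For \code{geneSpans}: keep phenotype-associated
#'   genes only.
#' @param ... Unused.
#' @return \code{exons}: exon \code{GRanges}; \code{geneTable}: per-gene
#'   \code{data.frame}; \code{geneSpans}: \code{GRanges} of gene spans
#'   (first to last exon) with \code{symbol} and
#'   \code{phenotype_associated}; \code{length}: gene count.
#' @name GenePanel-accessors
#' @aliases exons geneTable geneSpans
NULL

#' @rdname GenePanel-accessors
#' @export
setMethod("exons", "GenePanel", function(x, symbol = NULL, ...) {
  if (is.null(symbol)) return(x@exons)
  x@exons[S4Vectors::mcols(x@exons)$symbol == symbol]
})

#' @rdname GenePanel-accessors
#' @export
setMethod("geneTable", "GenePanel", function(x) x@genes)

#' @rdname GenePanel-accessors
#' @export
setMethod("geneSpans", "GenePanel", function(x, phenotypeOnly = FALSE, ...) {
  g <- x@genes
  if (phenotypeOnly) g <- g[g$phenotype_associated, , drop = FALSE]
  if (!nrow(g))
    return(GenomicRanges::GRanges(symbol = character(),
                                  phenotype_associated = logical()))
  GenomicRanges::GRanges(g$contig,
    IRanges::IRanges(g$gene_start, g$gene_end),
    symbol = g$symbol, phenotype_associated = g$phenotype_associated)
})

#' @rdname GenePanel-accessors
#' @export
setMethod("length", "GenePanel", function(x) nrow(x@genes))

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel of", nrow(object@genes), "gene(s),",
      length(object@exons), "exon(s);",
      sum(object@genes$phenotype_associated), "phenotype-associated\n")
  invisible(NULL)
})

#' Read an exon BED file into a GenePanel
#'
#' The BED file (0-based half-open; converted on import) must have at least
#' four columns with the gene symbol in column 4 and one row per exon. All
#' genes read from a panel file are flagged phenotype-associated: the file
#' is the phenotype gene list.
#'
#' @param path Path to a BED4+ file.
#' @param genome Named contig-length vector used to normalize and validate
#'   contig names; \code{NULL} disables validation.
#' @return A \code{\linkS4class{GenePanel}}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr16\t2100000\t2100200\tPKD1",
#'              "chr16\t2100500\t2100700\tPKD1",
#'              "chr11\t67800000\t67800150\tTCIRG1"), bed)
#' panel <- readGeneBed(bed)
#' geneTable(panel)
#' @export
readGeneBed <- function(path, genome = genomeContigs()) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(GenePanel(GenomicRanges::GRanges(
    symbol = character())))
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$name) ||
      any(is.na(S4Vectors::mcols(gr)$name)))
    stop("BED file must have >= 4 columns with the gene symbol in column 4")
  if (!length(gr)) return(GenePanel(GenomicRanges::GRanges(
    symbol = character())))
  contigs <- normalizeContig(as.character(GenomeInfoDb::seqnames(gr)),
                             genome)
  ex <- GenomicRanges::GRanges(contigs,
    IRanges::IRanges(BiocGenerics::start(gr), BiocGenerics::end(gr)),
    strand = BiocGenerics::strand(gr),
    symbol = S4Vectors::mcols(gr)$name,
    phenotype_associated = TRUE)
  GenePanel(ex)
}
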