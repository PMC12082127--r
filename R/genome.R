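## Genome build registry and contig-name normalization.
## All coordinates in the package are hg19/GRCh37 unless a caller supplies
## its own genome model (a named vector of contig lengths).

.HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566,
  chrM = 16571
)

.AUTOSOMES <- paste0("chr", 1:22)
.SEX_CHROMS <- c("chrX", "chrY")

#' Contig lengths for a genome build
#'
#' Returns the named vector of contig lengths used as the default genome
#' model. Only hg19/GRCh37 primary contigs are built in; any named integer
#' vector can be passed wherever a genome model is accepted.
#'
#' @param build Genome build identifier; only \code{"hg19"} is built in.
#' @return Named numeric vector of contig lengths, "chr"-prefixed names.
#' @examples
#' genomeContigs()[c("chr1", "chrX")]
#' @export
genomeContigs <- function(build = "hg19") {
  if (!identical(build, "hg19"))
    stop("unknown genome build: ", build)
  .HG19_LENGTHS
}

#' Normalize contig names to "chr"-prefixed form
#'
#' Caller dialects disagree on contig naming ("1" vs "chr1", "MT" vs
#' "chrM"); all comparisons in the package are done after normalization.
#'
#' @param x Character vector of contig names.
#' @param genome Named vector of contig lengths defining the allowed set,
#'   or \code{NULL} to skip membership validation.
#' @return Character vector of normalized names.
#' @examples
#' normalizeContig(c("1", "chrX", "MT"))
#' @export
normalizeContig <- function(x, genome = genomeContigs()) {
  x <- as.character(x)
  x[x %in% c("MT", "M", "chrMT")] <- "chrM"
  bare <- !startsWith(x, "chr")
  x[bare] <- paste0("chr", x[bare])
  if (!is.null(genome)) {
    bad <- unique(x[!(x %in% names(genome))])
    if (length(bad))
      stop("contig(s) not in genome model: ", paste(bad, collapse = ", "))
  }
  x
}

.isAutosome <- function(contig) contig %in% .AUTOSOMES
.isSexChrom <- function(contig) contig %in% .SEX_CHROMS

.seqinfoFromGenome <- function(genome = genomeContigs()) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}
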