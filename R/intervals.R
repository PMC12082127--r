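## Interval arithmetic on 1-based closed GRanges. These are the primitives
## behind every intersection filter and the cross-caller merge.

.asGRange1 <- function(x) {
  if (!methods::is(x, "GRanges") || length(x) != 1L)
    stop("expected a length-1 GRanges")
  x
}

#' Overlap length of two genomic intervals
#'
#' Number of bases shared by two intervals; zero when the contigs differ
#' or the intervals are disjoint.
#'
#' @param a,b Length-1 \code{GRanges}.
#' @return Non-negative integer overlap in bp.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
  a <- .asGRange1(a); b <- .asGRange1(b)
  if (as.character(GenomeInfoDb::seqnames(a)) !=
      as.character(GenomeInfoDb::seqnames(b)))
    return(0L)
  ov <- min(BiocGenerics::end(a), BiocGenerics::end(b)) -
        max(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  max(0L, as.integer(ov))
}

#' Reciprocal overlap of two genomic intervals
#'
#' \code{min(ov/len(a), ov/len(b))} where \code{ov} is the shared base
#' count — the symmetric criterion used to decide whether two callers
#' reported the same structural variant.
#'
#' @param a,b Length-1 \code{GRanges}.
#' @return Fraction in \code{[0,1]}.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 250))
#' reciprocalOverlap(a, b)  # 0.25
#' @export
reciprocalOverlap <- function(a, b) {
  ov <- overlapLength(a, b)
  if (ov == 0L) return(0)
  min(ov / BiocGenerics::width(a), ov / BiocGenerics::width(b))
}

## Vectorized reciprocal overlap for a Hits object over one GRanges.
.reciprocalOverlapHits <- function(gr, hits) {
  q <- gr[S4Vectors::queryHits(hits)]
  s <- gr[S4Vectors::subjectHits(hits)]
  ov <- pmax(0L, pmin(BiocGenerics::end(q), BiocGenerics::end(s)) -
                  pmax(BiocGenerics::start(q), BiocGenerics::start(s)) + 1L)
  same <- as.character(GenomeInfoDb::seqnames(q)) ==
          as.character(GenomeInfoDb::seqnames(s))
  ov[!same] <- 0L
  pmin(ov / BiocGenerics::width(q), ov / BiocGenerics::width(s))
}
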