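## Truth-set comparison and validation statistics: exact matching,
## sensitivity/specificity, Wilson score intervals, stratified
## concordance and the haplotype-caller output filter.

.smallKeyFrame <- function(x) {
  gr <- calls(x)
  mc <- S4Vectors::mcols(gr)
  if (callClass(x) == "mixed") {
    idx <- which(mc$class == "smallvariant")
    gr <- gr[idx]; mc <- mc[idx, , drop = FALSE]
  } else if (callClass(x) != "smallvariant")
    stop("exact matching is defined for small-variant records")
  data.frame(contig = as.character(GenomeInfoDb::seqnames(gr)),
             pos = BiocGenerics::start(gr),
             ref = as.character(mc$ref), alt = as.character(mc$alt),
             stringsAsFactors = FALSE)
}

#' Exact truth-set matching on CHROM/POS/REF/ALT
#'
#' A query record matches a truth record iff the normalized contig, the
#' 1-based position, the REF string and the ALT string are all equal
#' (genotype-blind); each truth record matches at most one query record.
#' Multiallelic rows must already be split (\code{\link{readCallerVcf}}
#' does this).
#'
#' @param query,truth \code{\linkS4class{CallSet}}s of small variants.
#' @return A \code{\linkS4class{MatchResult}}.
#' @examples
#' gr <- function(pos, ref, alt) GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(pos, pos + nchar(ref) - 1L), ref = ref, alt = alt,
#'   vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "DELINS"),
#'   genotype = "het", vaf = 0.5, quality = 30,
#'   size_change = nchar(alt) - nchar(ref))
#' q <- CallSet(c(gr(100, "A", "T"), gr(200, "C", "G")), "clair3",
#'              "smallvariant")
#' t <- CallSet(c(gr(100, "A", "T"), gr(200, "C", "A")), "truth",
#'              "smallvariant")
#' exactMatch(q, t)
#' @export
exactMatch <- function(query, truth) {
  qd <- .smallKeyFrame(query)
  td <- .smallKeyFrame(truth)
  qk <- do.call(paste, c(qd, sep = "\r"))
  tk <- do.call(paste, c(td, sep = "\r"))
  avail <- split(seq_along(qk), qk)
  used <- integer(0)
  truthMatch <- rep(NA_integer_, length(tk))
  for (i in seq_along(tk)) {
    cand <- avail[[tk[i]]]
    if (length(cand)) {
      truthMatch[i] <- cand[1L]
      avail[[tk[i]]] <- cand[-1L]
    }
  }
  hit <- !is.na(truthMatch)
  matched <- cbind(td[hit, , drop = FALSE],
                   data.frame(query_idx = truthMatch[hit],
                              truth_idx = which(hit)))
  missed <- td[!hit, , drop = FALSE]
  extra <- qd[setdiff(seq_along(qk), truthMatch[hit]), , drop = FALSE]
  rownames(matched) <- rownames(missed) <- rownames(extra) <- NULL
  methods::new("MatchResult", matched = matched, missed = missed,
               extra = extra, nQuery = length(qk), nTruth = length(tk))
}

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult: ", nrow(object@matched), " matched / ",
      object@nTruth, " truth; ", nrow(object@extra),
      " extra query call(s)\n", sep = "")
  invisible(NULL)
})

#' Sensitivity and specificity from a match result
#'
#' Sensitivity is matched/truth. Specificity needs a denominator of
#' evaluated negative positions: it is computed as
#' \code{1 - extra / (region_bp - truth)}, i.e. false calls over the
#' evaluated bases that are not truth sites. The choice of \code{regionBp}
#' (for an exome-restricted comparison, the exonic base count) is
#' reported alongside because any specificity claim is
#' denominator-dependent.
#'
#' @param m A \code{\linkS4class{MatchResult}}.
#' @param regionBp Total evaluated bases; must be at least the truth
#'   count.
#' @return Named list: \code{sensitivity}, \code{specificity},
#'   \code{region_bp}.
#' @examples
#' ## 99 of 100 truth variants matched, 3 extra calls over 1 Mb
#' m <- methods::new("MatchResult",
#'   matched = data.frame(contig = rep("chr1", 99), pos = 1:99,
#'     ref = "A", alt = "T", query_idx = 1:99, truth_idx = 1:99),
#'   missed = data.frame(contig = "chr1", pos = 100, ref = "A",
#'     alt = "T"),
#'   extra = data.frame(contig = rep("chr1", 3), pos = 201:203,
#'     ref = "A", alt = "T"),
#'   nQuery = 102L, nTruth = 100L)
#' sensitivitySpecificity(m, 1e6)
#' @export
sensitivitySpecificity <- function(m, regionBp) {
  if (regionBp < m@nTruth)
    stop("regionBp must be at least the truth count")
  list(sensitivity = if (m@nTruth) nrow(m@matched) / m@nTruth else
         NA_real_,
       specificity = 1 - nrow(m@extra) / (regionBp - m@nTruth),
       region_bp = regionBp)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided interval obtained by inverting the normal score test:
#' center \eqn{(\hat p + z^2/2n)/(1 + z^2/n)}, half-width
#' \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}, clipped to
#' \code{[0,1]}. Unlike the Wald interval it behaves sensibly at
#' \eqn{\hat p = 0} or \eqn{1}, which is why it is the standard choice
#' for reporting detection concordance on small clinical validation
#' panels.
#'
#' @param k Successes (vectorized).
#' @param n Trials, \code{n >= 1}.
#' @param confidence Two-sided confidence level, default 0.95.
#' @return A matrix with columns \code{low}, \code{high} (single
#'   \code{(k, n)} input gives a named length-2 vector).
#' @examples
#' wilsonInterval(25, 26)   # 0.811 - 0.9932
#' wilsonInterval(166, 167) # 0.9669 - 0.9989
#' @export
wilsonInterval <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(0, center - hw)
  high <- pmin(1, center + hw)
  if (length(low) == 1L) return(c(low = low, high = high))
  cbind(low = low, high = high)
}

#' Stratified detection concordance with Wilson intervals
#'
#' One row per stratum (variant type) plus an overall row pooled from the
#' summed counts, each with its detection proportion and Wilson interval.
#'
#' @param counts Named list (or data.frame with columns \code{k},
#'   \code{n}) giving detected/total per stratum, e.g.
#'   \code{list(SNV = c(80, 80), Indel = c(25, 26))}.
#' @param confidence Confidence level.
#' @return A \code{\linkS4class{ConcordanceReport}}.
#' @examples
#' rep <- stratifiedConcordance(list(SNV = c(80, 80), Indel = c(25, 26),
#'                                   SV = c(32, 32), Repeat = c(29, 29)))
#' reportTable(rep)
#' @export
stratifiedConcordance <- function(counts, confidence = 0.95) {
  if (is.data.frame(counts)) {
    strata <- if (!is.null(counts$stratum)) counts$stratum else
      rownames(counts)
    k <- counts$k; n <- counts$n
  } else {
    if (!length(counts)) stop("empty stratum map")
    strata <- names(counts)
    k <- vapply(counts, `[`, numeric(1), 1L)
    n <- vapply(counts, `[`, numeric(1), 2L)
  }
  if (!length(strata)) stop("empty stratum map")
  if (any(n < 1)) stop("all stratum totals must be >= 1")
  if (any(k > n)) stop("detected count cannot exceed total")
  ci <- wilsonInterval(k, n, confidence)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1,
                                     dimnames = list(NULL,
                                                     c("low", "high")))
  tb <- data.frame(stratum = strata, k = k, n = n, proportion = k / n,
                   ci_low = ci[, "low"], ci_high = ci[, "high"],
                   stringsAsFactors = FALSE)
  ktot <- sum(k); ntot <- sum(n)
  citot <- wilsonInterval(ktot, ntot, confidence)
  tb <- rbind(tb, data.frame(stratum = "Overall", k = ktot, n = ntot,
                             proportion = ktot / ntot,
                             ci_low = citot["low"],
                             ci_high = citot["high"]))
  rownames(tb) <- NULL
  methods::new("ConcordanceReport", table = tb, confidence = confidence)
}

#' @rdname ConcordanceReport-class
#' @param x A \code{\linkS4class{ConcordanceReport}}.
#' @export
setMethod("reportTable", "ConcordanceReport", function(x) x@table)

#' ConcordanceReport accessors
#' @name ConcordanceReport-class
#' @aliases reportTable
NULL

setMethod("show", "ConcordanceReport", function(object) {
  cat("Concordance by stratum (", object@confidence * 100,
      "% Wilson CI)\n", sep = "")
  tb <- object@table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s %4d/%-4d  %.4f  (%.4f-%.4f)\n", tb$stratum[i],
                tb$k[i], tb$n[i], tb$proportion[i], tb$ci_low[i],
                tb$ci_high[i]))
  invisible(NULL)
})

#' Write a concordance report as TSV
#' @param x A \code{\linkS4class{ConcordanceReport}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeConcordanceReport <- function(x, path) {
  utils::write.table(reportTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count-weighted aggregate sensitivity
#'
#' Pools per-type sensitivities into one number weighted by the per-type
#' truth counts: \eqn{\sum_i s_i n_i / \sum_i n_i}.
#'
#' @param perType Named list of \code{c(sensitivity, count)} pairs, e.g.
#'   \code{list(SNV = c(0.9891, 25514), indel = c(0.9781, 1070))}.
#' @return Aggregate sensitivity as a fraction.
#' @examples
#' weightedOverallSensitivity(list(SNV = c(0.9891, 25514),
#'                                 indel = c(0.9781, 1070)))
#' @export
weightedOverallSensitivity <- function(perType) {
  if (!length(perType)) stop("empty per-type map")
  s <- vapply(perType, `[`, numeric(1), 1L)
  n <- vapply(perType, `[`, numeric(1), 2L)
  if (any(n < 1)) stop("counts must be >= 1")
  sum(s * n) / sum(n)
}

#' Filter haplotype-caller output by VAF and quality
#'
#' Haplotype-resolved calls (e.g. for genes with homologous pseudogenes)
#' are assessed only above strict VAF and quality floors; records missing
#' either annotation are dropped with a warning.
#'
#' @param x A \code{\linkS4class{CallSet}} whose records carry \code{vaf}
#'   and \code{quality}.
#' @param minVaf Strict VAF floor (keep \code{vaf > minVaf}), default 0.2.
#' @param minQuality Strict quality floor (keep
#'   \code{quality > minQuality}), default 1.
#' @return The filtered \code{CallSet}.
#' @export
filterHaplotypeCalls <- function(x, minVaf = 0.2, minQuality = 1) {
  mc <- S4Vectors::mcols(calls(x))
  if (!all(c("vaf", "quality") %in% colnames(mc)))
    stop("records must carry vaf and quality")
  miss <- is.na(mc$vaf) | is.na(mc$quality)
  if (any(miss))
    warning(sum(miss), " record(s) missing vaf or quality were dropped")
  keep <- !miss & mc$vaf > minVaf & mc$quality > minQuality
  x[which(keep)]
}
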