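## Independent oracles and small fixture builders shared by the tests.
## Oracles deliberately use a different algorithm from the implementation
## they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## Base-by-base overlap count of two (contig, start, end) intervals
## (1-based closed) — brute force.
bruteOverlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq.int(s1, e1), seq.int(s2, e2)))
}

## Wilson interval endpoints by numerically inverting the score test:
## the endpoints are the p solving (phat - p)^2 = z^2 p(1-p)/n.
wilsonByRootfinding <- function(k, n, confidence = 0.95) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  lo <- if (phat == 0) 0 else
    uniroot(f, c(1e-12, phat), tol = 1e-12)$root
  hi <- if (phat == 1) 1 else
    uniroot(f, c(phat, 1 - 1e-12), tol = 1e-12)$root
  if (phat == 0) hi <- uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  if (phat == 1) lo <- uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low = lo, high = hi)
}

## Tract decomposition by dynamic programming minimizing non-motif bases;
## ties broken toward consuming a motif. Returns the minimal number of
## non-motif bases (the greedy scan should achieve the same on
## unambiguous tracts).
dpNonMotifBases <- function(seq, motifs) {
  k <- nchar(motifs[1])
  n <- nchar(seq)
  cost <- rep(Inf, n + 1L)
  cost[n + 1L] <- 0
  for (i in n:1) {
    cost[i] <- cost[i + 1L] + 1
    if (i + k - 1L <= n && substr(seq, i, i + k - 1L) %in% motifs)
      cost[i] <- min(cost[i], cost[i + k])
  }
  cost[1L]
}

## Optimal 1-D split of values into two clusters by exhaustive threshold
## search (minimizing within-cluster sum of squares); returns the two
## cluster medians, sorted.
twoClusterMediansOracle <- function(v) {
  sv <- sort(v)
  n <- length(sv)
  best <- NULL; bestSS <- Inf
  for (cut in 1:(n - 1)) {
    a <- sv[1:cut]; b <- sv[(cut + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < bestSS) { bestSS <- ss; best <- cut }
  }
  sort(c(median(sv[1:best]), median(sv[(best + 1):n])))
}

## N50 by brute force: try every distinct length as candidate L.
n50Brute <- function(lengths) {
  tot <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands)
    if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  min(lengths)
}

## --- fixture builders -------------------------------------------------

smallCallGr <- function(contig, pos, ref, alt, genotype = "het",
                        vaf = 0.5, quality = 30) {
  vtype <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
    ifelse(nchar(ref) < nchar(alt), "INS",
      ifelse(nchar(alt) < nchar(ref), "DEL", "DELINS")))
  GRanges(contig, IRanges(pos, pos + nchar(ref) - 1L), ref = ref,
          alt = alt, vtype = vtype, genotype = genotype, vaf = vaf,
          quality = quality,
          size_change = nchar(alt) - nchar(ref))
}

smallCallSet <- function(caller, contig, pos, ref, alt, ...) {
  gr <- do.call(c, mapply(smallCallGr, contig, pos, ref, alt, ...,
                          SIMPLIFY = FALSE, USE.NAMES = FALSE))
  CallSet(gr, caller, "smallvariant")
}

svCallGr <- function(contig, start, svtype, len, quality = 30,
                     mate_contig = NA_character_,
                     mate_pos = NA_integer_) {
  w <- if (svtype %in% c("INS", "BND")) 1L else len
  GRanges(contig, IRanges(start, start + w - 1L), svtype = svtype,
          svlen = if (svtype == "BND") NA_integer_ else as.integer(len),
          quality = quality, generic_flag = FALSE,
          mate_contig = mate_contig, mate_pos = mate_pos)
}

svCallSet <- function(caller, ...) {
  gr <- suppressWarnings(do.call(c, list(...)))
  CallSet(gr, caller, "sv")
}

cnvCallGr <- function(contig, start, nbins, copy_state, q0 = 0.1,
                      p_n = 0.1, p_value = 1e-4, bin_size = 1000L,
                      quality = 30) {
  GRanges(contig, IRanges(start, start + nbins * bin_size - 1L),
          copy_state = copy_state, q0 = q0, p_n = p_n,
          p_value = p_value, bin_size = bin_size, quality = quality)
}

cnvCallSet <- function(caller, ...)
  CallSet(suppressWarnings(do.call(c, list(...))), caller, "cnv")

## Minimal gene panel: one gene with evenly spaced exons.
toyPanel <- function(symbol = "GENE1", contig = "chr1", start = 10000,
                     nExons = 10, exonWidth = 150, intron = 1000,
                     phenotype = TRUE) {
  starts <- start + (0:(nExons - 1)) * (exonWidth + intron)
  GenePanel(GRanges(contig, IRanges(starts, width = exonWidth),
                    symbol = symbol, phenotype_associated = phenotype))
}

mergePanels <- function(...) {
  exs <- lapply(list(...), exons)
  GenePanel(lrtriage:::.bindGRanges(exs))
}
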