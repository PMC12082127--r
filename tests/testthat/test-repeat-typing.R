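test_that("decomposeTract tiles the sequence with greedy motif runs", {
  d <- decomposeTract("CAGCAGCAGCATCAGCAG", c("CAG", "CAT"))
  expect_identical(d$motif, c("CAG", "CAT", "CAG"))
  expect_identical(d$copies, c(3L, 1L, 2L))
  ## a pure tract is a single run with no non-motif bases
  d2 <- decomposeTract(strrep("AAGGG", 5), "AAGGG")
  expect_equal(nrow(d2), 1L)
  expect_identical(d2$copies, 5L)
  ## no motif at all: everything is non-motif
  d3 <- decomposeTract("TTTT", "CAG")
  expect_identical(d3$kind, "nonmotif")
  expect_identical(d3$width, 4L)
  expect_error(decomposeTract("ACGT", c("CAG", "AAGGG")),
               "unequal length")
})

test_that("decomposition reassembles byte-for-byte and matches the DP oracle", {
  set.seed(31)
  motifs <- c("CAG", "CAT")
  for (i in 1:200) {
    ## random mosaic of motif units and noise bases
    parts <- replicate(sample(1:8, 1), {
      if (runif(1) < 0.7) strrep(sample(motifs, 1), sample(1:10, 1))
      else paste(sample(c("A", "C", "G", "T"), sample(1:5, 1),
                        replace = TRUE), collapse = "")
    })
    seq <- paste(parts, collapse = "")
    d <- decomposeTract(seq, motifs)
    ## tiling: reassembly reproduces the input exactly
    expect_identical(paste(d$seq, collapse = ""), seq)
    expect_equal(sum(d$width), nchar(seq))
    ## offsets chain
    expect_identical(d$start, cumsum(c(1L, d$width))[seq_len(nrow(d))])
    ## the greedy scan wastes no more bases than the DP optimum allows
    ## on these unambiguous motif alphabets
    greedyWaste <- sum(d$width[d$kind == "nonmotif"])
    expect_equal(greedyWaste, dpNonMotifBases(seq, motifs))
  }
})

test_that("readCopyNumber sums runs of the requested motif class", {
  loc <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
                     pathogenicMotifs = "AAGGG")
  rd <- repeatRead(paste0(strrep("AAAAG", 3), strrep("AAGGG", 4)), loc)
  expect_equal(readCopyNumber(rd, "pathogenic", loc), 4L)
  expect_equal(readCopyNumber(rd, "reference", loc), 3L)
  expect_equal(readCopyNumber(rd, "any"), 7L)
  pure <- repeatRead(strrep("CAG", 30), c("CAG"))
  expect_equal(readCopyNumber(pure), 30L)
  none <- repeatRead("TTTTTT", c("CAG"))
  expect_equal(readCopyNumber(none), 0L)
})

test_that("genotypeLocus clusters reads into two alleles deterministically", {
  loc <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
                     pathogenicMotifs = "AAGGG")
  set.seed(13)
  low <- round(rnorm(10, 30, 1))
  high <- round(rnorm(10, 450, 5))
  seqs <- c(vapply(low, function(k) strrep("AAAAG", k), character(1)),
            vapply(high, function(k) strrep("AAGGG", k), character(1)))
  gt <- genotypeLocus(seqs, loc)
  expect_equal(gt$allele1@copies, median(low))
  expect_equal(gt$allele2@copies, median(high))
  expect_identical(gt$allele1@dominantMotif, "AAAAG")
  expect_identical(gt$allele2@dominantMotif, "AAGGG")
  expect_identical(gt$allele2@classification, "pathogenic")
  ## cluster medians agree with the exhaustive-threshold oracle
  oracle <- twoClusterMediansOracle(c(low, high))
  expect_equal(c(gt$allele1@copies, gt$allele2@copies), oracle)
  ## tight unimodal reads merge into a homozygous call
  homo <- vapply(round(rnorm(20, 20, 0.5)),
                 function(k) strrep("AAAAG", k), character(1))
  gth <- genotypeLocus(homo, loc)
  expect_equal(gth$allele1@copies, gth$allele2@copies)
  expect_equal(gth$allele1@supportingReads, 20L)
  ## below the spanning-read floor is an error naming the locus
  expect_error(genotypeLocus(seqs[1:3], loc), "RFC1")
})

test_that("classifyAllele requires both motif conversion and expansion", {
  loc <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
                     pathogenicMotifs = "AAGGG",
                     normalRange = c(11, 200),
                     pathogenicThreshold = 400)
  expect_identical(classifyAllele(450, loc, "AAGGG"), "pathogenic")
  expect_identical(classifyAllele(100, loc, "AAAAG"), "normal")
  ## converted but not expanded: intermediate, not pathogenic
  expect_identical(classifyAllele(100, loc, "AAGGG"), "intermediate")
  ## expanded but not converted: flagged as non-pathogenic expansion
  expect_identical(classifyAllele(450, loc, "AAAAG"),
                   "expanded_nonpathogenic_motif")
  ## the truth table is total: every (motif, copies) cell maps to one class
  for (motif in c("AAAAG", "AAGGG", "CAGAA"))
    for (copies in c(1, 11, 200, 201, 400, 401, 5000)) {
      cls <- classifyAllele(copies, loc, motif)
      expect_true(cls %in% c("normal", "intermediate",
                             "expanded_nonpathogenic_motif",
                             "pathogenic"))
    }
})

test_that("detectInterruptions finds divergent units inside the tract", {
  loc <- repeatLocus("ATXN1", "chr6", 16327636, 16327722, "CAG",
                     pathogenicMotifs = "CAG",
                     interruptionMotifs = "CAT",
                     normalRange = c(6, 35), pathogenicThreshold = 38)
  ## wild-type allele with two protective CAT interruptions
  wt <- repeatRead(paste0(strrep("CAG", 12), "CAT", strrep("CAG", 12),
                          "CAT", strrep("CAG", 5)), loc)
  ints <- detectInterruptions(wt, loc)
  expect_equal(nrow(ints), 2L)
  expect_identical(ints$motif, c("CAT", "CAT"))
  ## an uninterrupted expanded allele
  exp <- repeatRead(strrep("CAG", 45), loc)
  expect_equal(nrow(detectInterruptions(exp, loc)), 0L)
  ## degenerate: a CAT-only tract is all interruption
  catOnly <- repeatRead(strrep("CAT", 7), loc)
  expect_equal(sum(detectInterruptions(catOnly, loc)$copies), 7L)
})

test_that("adding one motif unit per read shifts the genotype by one", {
  loc <- repeatLocus("HTT", "chr4", 3076604, 3076660, "CAG",
                     pathogenicMotifs = "CAG", normalRange = c(6, 26),
                     pathogenicThreshold = 39)
  base <- c(rep(20, 6), rep(44, 6))
  mk <- function(copies) vapply(copies, function(k) strrep("CAG", k),
                                character(1))
  g0 <- genotypeLocus(mk(base), loc)
  g1 <- genotypeLocus(mk(base + 1), loc)
  expect_equal(g1$allele1@copies, g0$allele1@copies + 1)
  expect_equal(g1$allele2@copies, g0$allele2@copies + 1)
})
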