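test_that("the truth-set generator honours the roster and is deterministic", {
  cfg <- simulationConfig(seed = 5, roster = c(snv = 80, indel = 26,
                                               sv = 32, cnv = 0,
                                               repeats = 29),
                          nGenes = 60)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  t1 <- simulateTruthSet(cfg, dir = d1)
  t2 <- simulateTruthSet(cfg, dir = d2)
  ## the clinical roster: 138 sequence/SV records + 29 repeat loci
  expect_equal(length(t1$calls), 138L)
  expect_equal(length(t1$repeatLoci), 29L)
  mc <- mcols(calls(t1$calls))
  expect_equal(sum(mc$class == "smallvariant" & mc$vtype == "SNV"), 80L)
  expect_equal(sum(mc$class == "smallvariant" & mc$vtype != "SNV"), 26L)
  expect_equal(sum(mc$class == "sv"), 32L)
  ## indel sizes stay in the 1-36 bp clinical band
  sizes <- abs(mc$size_change[mc$class == "smallvariant"])
  expect_true(all(sizes[sizes > 0] >= 1 & sizes[sizes > 0] <= 36))
  ## identical config + seed => byte-identical files
  expect_identical(readLines(t1$paths$truth_vcf),
                   readLines(t2$paths$truth_vcf))
  expect_identical(readLines(t1$paths$gene_bed),
                   readLines(t2$paths$gene_bed))
  ## planted variants never sit within 1 kb of each other
  gr <- calls(t1$calls)
  for (ct in unique(as.character(seqnames(gr)))) {
    p <- sort(start(gr[seqnames(gr) == ct]))
    if (length(p) > 1) expect_true(all(diff(p) >= 1000))
  }
})

test_that("an empty roster produces a header-only truth VCF", {
  cfg <- simulationConfig(seed = 2, roster = c(snv = 0, indel = 0,
                                               sv = 0, cnv = 0,
                                               repeats = 0),
                          nGenes = 5)
  d <- file.path(tempdir(), "simEmpty")
  t0 <- simulateTruthSet(cfg, dir = d)
  expect_equal(length(t0$calls), 0L)
  expect_true(all(startsWith(readLines(t0$paths$truth_vcf), "#")))
})

test_that("emulateCaller reproduces exact k-of-n detection", {
  gr <- do.call(c, lapply(seq_len(29), function(i)
    svCallGr("chr1", 1e6 + i * 50000, "DEL", 5000)))
  planted <- CallSet(gr, "truth", "sv")
  prof <- callerProfile("nanovar", detectCounts = 27)
  det <- emulateCaller(planted, prof, seed = 1)
  expect_equal(length(det), 27L)
  expect_equal(length(det) / length(planted), 27 / 29)
  expect_equal(round(100 * length(det) / 29, 1), 93.1)
  ## detected records keep their planted coordinates untouched
  expect_true(all(start(calls(det)) %in% start(gr)))
  ## k > n is rejected
  expect_error(emulateCaller(planted, callerProfile(
    "nanovar", detectCounts = 30), seed = 1), "exceeds")
})

test_that("perfect and zero-sensitivity profiles behave as limits", {
  gr <- do.call(c, lapply(1:10, function(i)
    svCallGr("chr2", 1e6 + i * 40000, "DUP", 3000)))
  planted <- CallSet(gr, "truth", "sv")
  perfect <- emulateCaller(planted, callerProfile("debreak"), seed = 3)
  expect_equal(sort(start(calls(perfect))), sort(start(gr)))
  nothing <- emulateCaller(planted, callerProfile("debreak",
                                                  detection = 0,
                                                  falsePerMb = 0.01),
                           seed = 3)
  ## only false calls remain, none at planted positions
  expect_false(any(start(calls(nothing)) %in% start(gr)))
})

test_that("emulated detection rates converge to the profile sensitivity", {
  n <- 10000
  gr <- GRanges("chr1", IRanges(seq(1e6, by = 2000, length.out = n),
                                width = 1000),
                svtype = "DEL", svlen = 1000L, quality = 30,
                generic_flag = FALSE, mate_contig = NA_character_,
                mate_pos = NA_integer_)
  planted <- CallSet(gr, "truth", "sv")
  p <- 0.931
  det <- emulateCaller(planted, callerProfile("nanovar",
                                              detection = p),
                       seed = 17)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(length(det) / n - p), 3 * se)
})

test_that("simulated repeat reads honour genotype, noise and determinism", {
  loc <- repeatLocus("ATXN1", "chr6", 16327636, 16327722, "CAG",
                     pathogenicMotifs = "CAG",
                     interruptionMotifs = "CAT",
                     normalRange = c(6, 35), pathogenicThreshold = 38)
  ## noise-free: exact read lengths, depth reads per allele
  reads <- simulateRepeatReads(loc, c(30, 45), depth = 10, noiseCV = 0,
                               seed = 4)
  expect_equal(length(reads), 20L)
  expect_setequal(unique(BiocGenerics::width(reads)), c(90L, 135L))
  ## decomposition recovers the planted motif classes
  loc2 <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
                      pathogenicMotifs = "AAGGG")
  reads2 <- simulateRepeatReads(loc2,
    list(list(copies = 100, motif = "AAAAG"),
         list(copies = 450, motif = "AAGGG")), depth = 15, seed = 8)
  gt <- genotypeLocus(reads2, loc2)
  expect_identical(gt$allele1@dominantMotif, "AAAAG")
  expect_identical(gt$allele2@dominantMotif, "AAGGG")
  expect_identical(gt$allele2@classification, "pathogenic")
  ## same seed twice: identical FASTA
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  simulateRepeatReads(loc, c(30, 45), depth = 5, seed = 9, path = f1)
  simulateRepeatReads(loc, c(30, 45), depth = 5, seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  ## interruption units are substituted where specified
  reads3 <- simulateRepeatReads(loc,
    list(list(copies = 30, motif = "CAG",
              interruptions = list(list(after = 12, motif = "CAT"))),
         list(copies = 45, motif = "CAG")), depth = 4, noiseCV = 0,
    seed = 2)
  rd <- repeatRead(as.character(reads3[[1]]), loc)
  ints <- detectInterruptions(rd, loc)
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$start, 12 * 3 + 1)
})

test_that("caller emulation through dialect files round-trips", {
  cfg <- simulationConfig(seed = 27, roster = c(snv = 6, indel = 3,
                                                sv = 5, cnv = 2,
                                                repeats = 0),
                          nGenes = 12)
  truth <- simulateTruthSet(cfg)
  for (caller in c("clair3", "nanovar", "debreak", "cnvpytor")) {
    f <- tempfile(fileext = ".vcf")
    mem <- emulateCaller(truth, callerProfile(caller), seed = 27,
                         path = f)
    back <- readCallerVcf(f, caller = caller)
    expect_equal(length(back), length(mem), info = caller)
    expect_identical(sort(start(calls(back))), sort(start(calls(mem))),
                     info = caller)
  }
})
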