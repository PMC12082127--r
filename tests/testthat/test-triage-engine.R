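test_that("per-caller size restriction follows the declared windows", {
  pol <- routingPolicy()
  ## primary SV caller drops sub-100 bp calls, bridging caller keeps them
  d80 <- svCallSet("debreak", svCallGr("chr1", 1e6, "DEL", 80))
  expect_equal(length(restrictByCaller(d80, pol)), 0L)
  n75 <- svCallSet("nanovar", svCallGr("chr1", 1e6, "DEL", 75))
  expect_equal(length(restrictByCaller(n75, pol)), 1L)
  n150 <- svCallSet("nanovar", svCallGr("chr1", 1e6, "DEL", 150))
  expect_equal(length(restrictByCaller(n150, pol)), 0L)
  ## enumerate sizes 1..200 against the declared ranges for each role
  for (size in 1:200) {
    sv <- svCallGr("chr1", 1e6, "DEL", size)
    expect_equal(length(restrictByCaller(svCallSet("nanovar", sv), pol)),
                 as.integer(size >= 50 && size < 100), info = size)
    expect_equal(length(restrictByCaller(svCallSet("debreak", sv), pol)),
                 as.integer(size >= 100), info = size)
    sm <- smallCallSet("clair3", "chr1", 1e6,
                       strrep("A", size + 1), "A")
    expect_equal(length(restrictByCaller(sm, pol)),
                 as.integer(size < 50), info = size)
  }
  ## BND (no length) passes the breakpoint callers unconditionally
  bnd <- svCallSet("nanovar", svCallGr("chr1", 1e6, "BND", NA,
                                       mate_contig = "chr2",
                                       mate_pos = 5e6L))
  expect_equal(length(restrictByCaller(bnd, pol)), 1L)
  expect_error(restrictByCaller(svCallSet("mystery", svCallGr(
    "chr1", 1e6, "DEL", 200)), pol), "not registered")
})

test_that("depth-segment filtering partitions chromosomes and applies Q0/p_N/p", {
  pol <- routingPolicy()
  segs <- cnvCallSet("cnvpytor",
    cnvCallGr("chrX", 1e6 + 1, 10, "loss", q0 = 0.6, p_n = 0.1,
              p_value = 1e-4),                       # fails Q0 < 0.5
    cnvCallGr("chr7", 1e6 + 1, 10, "loss"),          # wrong chromosome
    cnvCallGr("chrX", 5e6 + 1, 10, "loss", q0 = 0.1, p_n = 0.2,
              p_value = 1e-4),                       # passes all three
    cnvCallGr("chrX", 9e6 + 1, 10, "gain", q0 = 0.1, p_n = 0.2,
              p_value = 0.01))                       # fails p < 0.001
  out <- filterDepthSegments(segs, pol)
  expect_equal(length(out), 1L)
  expect_equal(start(calls(out)), 5e6 + 1)
  ## boundary values are excluded (strict inequalities)
  atThr <- cnvCallSet("cnvpytor",
    cnvCallGr("chrX", 1e6 + 1, 10, "loss", q0 = 0.5, p_n = 0.1,
              p_value = 1e-4))
  expect_equal(length(filterDepthSegments(atThr, pol)), 0L)
  ## autosome caller keeps autosomes only
  auto <- cnvCallSet("qdnaseq",
    cnvCallGr("chr7", 1e6 + 1, 10, "loss"),
    cnvCallGr("chrX", 1e6 + 1, 10, "loss"))
  expect_equal(as.character(seqnames(calls(filterDepthSegments(
    auto, pol)))), "chr7")
  ## missing annotations are quarantined, not silently dropped
  nas <- cnvCallSet("cnvpytor",
    cnvCallGr("chrX", 1e6 + 1, 10, "loss", q0 = NA_real_))
  out2 <- filterDepthSegments(nas, pol)
  expect_equal(length(out2), 0L)
  expect_equal(nrow(provenance(out2)$quarantined), 1L)
})

test_that("gene impact classification covers the documented cases", {
  panel <- toyPanel(nExons = 10)        # exons every 1150 bp from 10000
  ex <- exons(panel, "GENE1")
  gs <- min(start(ex)); ge <- max(end(ex))
  ## inversion spanning exons 3-5 of a 10-exon gene advances
  inv <- GRanges("chr1", IRanges(start(ex)[3] - 10, end(ex)[5] + 10),
                 svtype = "INV")
  expect_identical(classifyGeneImpact(inv, ex),
                   "partial_coding_disruption")
  ## complete gene inversion with intergenic breakpoints is excluded
  invAll <- GRanges("chr1", IRanges(gs - 5000, ge + 5000),
                    svtype = "INV")
  expect_identical(classifyGeneImpact(invAll, ex),
                   "whole_gene_contained")
  ## insertion 49 bases from an exon boundary is near-splice
  ins <- GRanges("chr1", IRanges(end(ex)[1] + 49, end(ex)[1] + 49),
                 svtype = "INS")
  expect_identical(classifyGeneImpact(ins, ex), "intronic_near_splice")
  ## and one deep in the intron is not
  deep <- GRanges("chr1", IRanges(end(ex)[1] + 500, end(ex)[1] + 500),
                  svtype = "INS")
  expect_identical(classifyGeneImpact(deep, ex), "intronic_deep")
  ## deletion with no overlap is intergenic
  del <- GRanges("chr1", IRanges(ge + 10000, ge + 10300),
                 svtype = "DEL")
  expect_identical(classifyGeneImpact(del, ex), "intergenic")
  ## exon-overlapping deletion disrupts
  delEx <- GRanges("chr1", IRanges(start(ex)[2], end(ex)[2]),
                   svtype = "DEL")
  expect_identical(classifyGeneImpact(delEx, ex), "exonic_disrupting")
  ## BND with a breakend inside the gene span
  bnd <- GRanges("chr1", IRanges(start(ex)[4], start(ex)[4]),
                 svtype = "BND", mate_contig = "chr9",
                 mate_pos = 1e6L)
  expect_identical(classifyGeneImpact(bnd, ex), "breakpoint_in_gene")
  expect_error(classifyGeneImpact(del, ex[0]), "zero exons")
})

test_that("mechanistic filter keeps/drops by the rules matrix", {
  panel <- toyPanel(nExons = 10)
  ex <- exons(panel, "GENE1")
  sets <- svCallSet("debreak",
    svCallGr("chr1", start(ex)[2], "DEL", 200),          # exonic: keep
    svCallGr("chr1", min(start(ex)) - 5000, "INV",
             diff(range(c(start(ex), end(ex)))) + 10000), # whole gene INV
    svCallGr("chr1", max(end(ex)) + 50000, "DEL", 300))   # intergenic
  out <- mechanisticFilter(sets, panel)
  expect_equal(length(out), 1L)
  expect_equal(start(calls(out)), start(ex)[2])
  expect_identical(mcols(calls(out))$genes, "GENE1")
  ## a whole-gene DEL (dosage loss) is kept by the default matrix
  delAll <- svCallSet("debreak",
    svCallGr("chr1", min(start(ex)) - 5000, "DEL",
             diff(range(c(start(ex), end(ex)))) + 10000))
  expect_equal(length(mechanisticFilter(delAll, panel)), 1L)
  ## incomplete rules matrix is a configuration error
  expect_error(mechanisticFilter(sets, panel,
                                 rules = defaultImpactRules()[, 1:3]),
               "configuration error")
  ## the default matrix covers the whole (type, impact) space
  m <- defaultImpactRules()
  expect_true(all(c("exonic_disrupting", "whole_gene_contained",
                    "intergenic") %in% colnames(m)))
  expect_false(m["INV", "whole_gene_contained"])
  expect_true(m["DEL", "whole_gene_contained"])
  expect_true(all(m[, "exonic_disrupting"]))
  expect_false(any(m[, "intergenic"]))
})

test_that("phenotype-gene intersection keeps only panel-gene calls", {
  panel <- mergePanels(
    toyPanel("PANEL1", "chr1", 10000),
    toyPanel("OFFPANEL", "chr1", 10 ^ 6, phenotype = FALSE))
  inPanel <- svCallSet("debreak", svCallGr("chr1", 10000, "DEL", 200))
  offPanel <- svCallSet("debreak", svCallGr("chr1", 1e6, "DEL", 200))
  expect_equal(length(intersectPhenotypeGenes(inPanel, panel)), 1L)
  expect_equal(length(intersectPhenotypeGenes(offPanel, panel)), 0L)
  ## empty phenotype panel gives empty output for any input
  emptyPanel <- toyPanel("G", phenotype = FALSE)
  expect_equal(length(intersectPhenotypeGenes(inPanel, emptyPanel)), 0L)
})

test_that("logic rules are ordered declarative predicates", {
  big <- svCallSet("debreak", svCallGr("chr1", 1e6, "DEL", 1e7),
                   svCallGr("chr1", 5e7, "DEL", 1000))
  out <- applyLogicRules(big, list(list(name = "del_cap",
                                        type = "max_size",
                                        svtype = "DEL", value = 5e6)))
  expect_equal(length(out), 1L)
  expect_equal(mcols(calls(out))$svlen, 1000L)
  ## empty rule list is the identity
  expect_equal(length(applyLogicRules(big, list())), 2L)
  ## min caller support on a merged set
  merged <- mergeConcordantCalls(list(
    svCallSet("nanovar", svCallGr("chr1", 1e6, "DEL", 10000)),
    svCallSet("debreak", svCallGr("chr1", 1e6 + 200, "DEL", 10000),
              svCallGr("chr2", 1e6, "DEL", 5000))))
  out2 <- applyLogicRules(merged, list(list(name = "supp",
                                            type = "min_support",
                                            value = 2)))
  expect_equal(length(out2), 1L)
  expect_equal(mcols(calls(out2))$support, 2L)
  expect_error(validateLogicRules(list(list(name = "x",
                                            type = "frobnicate"))),
               "configuration error")
})

test_that("cross-caller merging follows single-linkage reciprocal overlap", {
  ## same 10 kb DEL from two callers at ~95% reciprocal overlap
  a <- svCallSet("nanovar", svCallGr("chr1", 100000, "DEL", 10000,
                                     quality = 20))
  b <- svCallSet("debreak", svCallGr("chr1", 100500, "DEL", 10000,
                                     quality = 50))
  m <- mergeConcordantCalls(list(a, b))
  expect_equal(length(m), 1L)
  expect_equal(mcols(calls(m))$support, 2L)
  expect_identical(mcols(calls(m))$callers, "debreak,nanovar")
  ## representative is the highest-quality member
  expect_equal(start(calls(m)), 100500L)
  ## two DELs at ~10% reciprocal overlap stay separate
  c2 <- svCallSet("debreak", svCallGr("chr1", 109000, "DEL", 10000))
  m2 <- mergeConcordantCalls(list(a, c2))
  expect_equal(length(m2), 2L)
  ## a single CallSet passes through unchanged
  m3 <- mergeConcordantCalls(list(a))
  expect_equal(length(m3), 1L)
  ## idempotence
  m4 <- mergeConcordantCalls(m)
  expect_equal(length(m4), length(m))
  ## small variants merge only on exact identity
  s1 <- smallCallSet("clair3", "chr1", c(500, 600), c("A", "C"),
                     c("T", "G"))
  s2 <- smallCallSet("paraphase", "chr1", c(500, 600), c("A", "C"),
                     c("T", "A"))
  ms <- mergeConcordantCalls(list(s1, s2))
  expect_equal(length(ms), 3L)  # one exact duplicate merged
})

test_that("merging agrees with a brute-force single-linkage oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    starts <- sample(seq(1e5, 2e5, by = 1000), n)
    lens <- sample(2000:20000, n, replace = TRUE)
    callers <- sample(c("nanovar", "debreak", "sniffles"), n,
                      replace = TRUE)
    sets <- lapply(unique(callers), function(cl) {
      idx <- which(callers == cl)
      gr <- do.call(c, lapply(idx, function(i)
        svCallGr("chr1", starts[i], "DEL", lens[i])))
      svCallSet(cl, gr)
    })
    m <- mergeConcordantCalls(sets, minReciprocal = 0.5)
    ## oracle: adjacency by pairwise reciprocal overlap across callers,
    ## connected components by repeated expansion
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gi <- GRanges("chr1", IRanges(starts[i], starts[i] + lens[i] - 1))
      gj <- GRanges("chr1", IRanges(starts[j], starts[j] + lens[j] - 1))
      adj[i, j] <- adj[j, i] <-
        callers[i] != callers[j] &&
        reciprocalOverlap(gi, gj) >= 0.5
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in 1:n) for (j in 1:n)
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      if (!changed) break
    }
    expect_equal(length(m), length(unique(comp)))
  }
})

test_that("the full cascade has a monotone funnel and loses no truth", {
  cfg <- simulationConfig(seed = 19, roster = c(snv = 12, indel = 6,
                                                sv = 10, cnv = 4,
                                                repeats = 0),
                          nGenes = 25, fracExonic = 1)
  truth <- simulateTruthSet(cfg)
  profiles <- list(callerProfile("clair3"), callerProfile("nanovar"),
                   callerProfile("debreak"), callerProfile("qdnaseq"),
                   callerProfile("cnvpytor"))
  sets <- lapply(profiles, function(p) emulateCaller(truth, p,
                                                     seed = 19))
  res <- runTriage(sets, truth$panel)
  st <- funnelStages(res$funnel)
  expect_true(all(st$n_out <= st$n_in))
  expect_true(all(st$n_in[-1] == st$n_out[-nrow(st)]))
  ## every planted call is exonic in a phenotype gene: nothing is lost
  expect_equal(st$n_out[nrow(st)], length(truth$calls))
  ## and the reviewed positions are exactly the planted ones
  expect_setequal(paste(seqnames(calls(res$calls)),
                        start(calls(res$calls))),
                  paste(seqnames(calls(truth$calls)),
                        start(calls(truth$calls))))
})

test_that("mechanistic and phenotype filters commute", {
  cfg <- simulationConfig(seed = 23, roster = c(snv = 8, indel = 4,
                                                sv = 8, cnv = 2,
                                                repeats = 0),
                          nGenes = 15, nDecoyGenes = 5,
                          fracExonic = 0.7)
  truth <- simulateTruthSet(cfg)
  x <- truth$calls
  a <- intersectPhenotypeGenes(mechanisticFilter(x, truth$panel),
                               truth$panel)
  b <- mechanisticFilter(intersectPhenotypeGenes(x, truth$panel),
                         truth$panel)
  key <- function(cs) sort(paste(seqnames(calls(cs)), start(calls(cs)),
                                 mcols(calls(cs))$typelab))
  expect_identical(key(a), key(b))
})

test_that("empty input produces an empty funnel", {
  sets <- list(CallSet(calls(svCallSet("debreak", svCallGr(
    "chr1", 1, "DEL", 100)))[0], "debreak", "sv"))
  panel <- toyPanel()
  res <- runTriage(sets, panel)
  expect_equal(length(res$calls), 0L)
  expect_true(all(funnelStages(res$funnel)$n_out == 0L))
})
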