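test_that("exactMatch pairs records on CHROM/POS/REF/ALT only", {
  q <- smallCallSet("clair3", "chr1", c(100, 200, 300),
                    c("A", "C", "G"), c("T", "T", "A"))
  t <- smallCallSet("truth", "chr1", c(100, 200, 400),
                    c("A", "C", "T"), c("T", "G", "C"))
  m <- exactMatch(q, t)
  expect_equal(nrow(m@matched), 1L)      # only chr1:100 A>T agrees
  expect_equal(nrow(m@missed), 2L)       # 200 C>G (alt differs) + 400
  expect_equal(nrow(m@extra), 2L)
  ## genotype-blind: het query matches hom truth
  q2 <- smallCallSet("clair3", "chr1", 100, "A", "T", genotype = "het")
  t2 <- smallCallSet("truth", "chr1", 100, "A", "T", genotype = "hom")
  expect_equal(nrow(exactMatch(q2, t2)@matched), 1L)
  ## swapping query and truth swaps missed and extra
  m2 <- exactMatch(t, q)
  expect_equal(nrow(m2@missed), nrow(m@extra))
  expect_equal(nrow(m2@extra), nrow(m@missed))
  ## bookkeeping invariants hold
  expect_equal(nrow(m@matched) + nrow(m@missed), m@nTruth)
  expect_equal(nrow(m@matched) + nrow(m@extra), m@nQuery)
})

test_that("sensitivity and specificity use the evaluated-region denominator", {
  q <- smallCallSet("clair3", "chr1", c(100, 200, 301, 302, 303),
                    rep("A", 5), rep("T", 5))
  t <- smallCallSet("truth", "chr1", c(100, 200), rep("A", 2),
                    rep("T", 2))
  m <- exactMatch(q, t)
  ss <- sensitivitySpecificity(m, regionBp = 1e6)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1 - 3 / (1e6 - 2))
  ## no extra calls: perfect specificity
  m0 <- exactMatch(t, t)
  expect_equal(sensitivitySpecificity(m0, 1e6)$specificity, 1)
  expect_error(sensitivitySpecificity(m, regionBp = 1),
               "at least the truth count")
})

test_that("wilsonInterval reproduces the published clinical-panel intervals", {
  ## six printed intervals from detection counts, at printed precision
  expect_equal(round(wilsonInterval(80, 80), 2), c(low = 0.95,
                                                   high = 1))
  expect_equal(round(wilsonInterval(25, 26)[["low"]], 3), 0.811)
  expect_equal(round(wilsonInterval(25, 26)[["high"]], 4), 0.9932)
  expect_equal(round(wilsonInterval(32, 32), 4), c(low = 0.8928,
                                                   high = 1))
  expect_equal(round(wilsonInterval(29, 29), 3), c(low = 0.883,
                                                   high = 1))
  expect_equal(round(wilsonInterval(166, 167), 4), c(low = 0.9669,
                                                     high = 0.9989))
  expect_equal(round(wilsonInterval(14, 14), 2), c(low = 0.78,
                                                   high = 1))
  ## boundary clipping
  expect_equal(wilsonInterval(0, 10)[["low"]], 0)
  expect_equal(wilsonInterval(10, 10)[["high"]], 1)
  expect_error(wilsonInterval(5, 0), "n must be")
  expect_error(wilsonInterval(11, 10), "0 <= k <= n")
})

test_that("wilsonInterval agrees with the score-equation root-finding oracle", {
  for (n in c(1, 5, 26, 80, 167, 1000)) {
    for (k in unique(round(c(0, 1, n %/% 3, n - 1, n)))) {
      if (k < 0 || k > n) next
      got <- wilsonInterval(k, n)
      want <- wilsonByRootfinding(k, n)
      expect_equal(got[["low"]], want[["low"]], tolerance = 1e-9)
      expect_equal(got[["high"]], want[["high"]], tolerance = 1e-9)
    }
  }
})

test_that("wilsonInterval contains the point estimate and narrows with n", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- wilsonInterval(k, n)
    expect_lte(ci[["low"]], k / n)
    expect_gte(ci[["high"]], k / n)
  }
  ## width decreases monotonically in n at fixed k/n
  widths <- vapply(c(10, 20, 40, 80, 160, 320), function(n) {
    ci <- wilsonInterval(0.8 * n, n); ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("stratifiedConcordance pools counts into the overall row", {
  rep1 <- stratifiedConcordance(list(A = c(5, 10), B = c(5, 10)))
  tb <- reportTable(rep1)
  expect_equal(tb$proportion[tb$stratum == "Overall"], 0.5)
  expect_equal(tb$k[tb$stratum == "Overall"], 10)
  ## a single stratum's overall equals the stratum itself
  rep2 <- stratifiedConcordance(list(only = c(1, 1)))
  tb2 <- reportTable(rep2)
  expect_equal(tb2$proportion, c(1, 1))
  expect_error(stratifiedConcordance(list()), "empty")
  expect_error(stratifiedConcordance(list(A = c(2, 0))), ">= 1")
  ## report invariants: low <= p <= high everywhere
  expect_true(all(tb$ci_low <= tb$proportion &
                    tb$proportion <= tb$ci_high))
})

test_that("weightedOverallSensitivity is the count-weighted mean", {
  expect_equal(weightedOverallSensitivity(list(a = c(0.9, 10),
                                               b = c(0.7, 10))), 0.8)
  expect_equal(weightedOverallSensitivity(list(only = c(0.42, 7))),
               0.42)
  ## the published aggregate: SNV and indel sensitivities pooled by count
  agg <- weightedOverallSensitivity(list(SNV = c(0.9891, 25514),
                                         indel = c(0.9781, 1070)))
  expect_equal(round(100 * agg, 2), 98.87)
  expect_error(weightedOverallSensitivity(list()), "empty")
})

test_that("haplotype-call filtering applies strict VAF and quality floors", {
  mk <- function(vaf, quality) smallCallSet("paraphase", "chr7",
    seq(100, by = 1000, length.out = length(vaf)),
    rep("A", length(vaf)), rep("T", length(vaf)), vaf = vaf,
    quality = quality)
  x <- mk(c(0.15, 0.5, 0.5, 0.2, 0.21), c(5, 0.5, 2, 5, 1))
  out <- filterHaplotypeCalls(x)
  ## only vaf > 0.2 AND quality > 1 survive (both strict)
  expect_equal(length(out), 1L)
  expect_equal(mcols(calls(out))$vaf, 0.5)
  expect_equal(mcols(calls(out))$quality, 2)
  ## records missing annotations drop with a warning
  y <- mk(c(NA, 0.5), c(5, 5))
  expect_warning(out2 <- filterHaplotypeCalls(y), "missing")
  expect_equal(length(out2), 1L)
})
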