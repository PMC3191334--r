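mkCalls <- function(mat, pool = NULL, generation = NULL) {
  md <- NULL
  if (!is.null(pool) || !is.null(generation))
    md <- data.frame(line_id = rownames(mat),
                     pool = pool %||% "other",
                     generation = generation %||% "F7",
                     stringsAsFactors = FALSE)
  GenotypeCalls(mat, md)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("missing-data cleaning removes columns strictly above 5%", {
  set.seed(1)
  m <- matrix("AA", 100, 3,
              dimnames = list(sprintf("L%03d", 1:100), c("s1", "s2", "s3")))
  m[1:6, "s2"] <- NA          # 6% > 5% -> removed
  m[1:5, "s3"] <- NA          # exactly 5% -> kept
  cleaned <- cleanSnps(mkCalls(m))
  expect_identical(colnames(genotypeMatrix(cleaned)), c("s1", "s3"))
})

test_that("allele frequencies follow the allele-count formula", {
  m <- matrix(c(rep("AA", 3), rep("AB", 4), rep("BB", 3)), ncol = 1,
              dimnames = list(sprintf("L%02d", 1:10), "s1"))
  gc <- mkCalls(m)
  expect_identical(alleleFrequency(gc, "s1"), 0.5)   # (6+4)/20
  m2 <- matrix("AA", 5, 1, dimnames = list(sprintf("L%d", 1:5), "s1"))
  expect_identical(alleleFrequency(mkCalls(m2), "s1"), 1)
  m3 <- matrix("AB", 5, 1, dimnames = list(sprintf("L%d", 1:5), "s1"))
  expect_identical(alleleFrequency(mkCalls(m3), "s1"), 0.5)
  m4 <- matrix(NA_character_, 5, 1,
               dimnames = list(sprintf("L%d", 1:5), "s1"))
  expect_error(alleleFrequency(mkCalls(m4), "s1"), "missing")

  # invariant under line reordering; label swap maps f -> 1 - f
  set.seed(4)
  calls <- sample(c("AA", "AB", "BB"), 30, replace = TRUE)
  m5 <- matrix(calls, ncol = 1,
               dimnames = list(sprintf("L%02d", 1:30), "s1"))
  f <- alleleFrequency(mkCalls(m5), "s1")
  perm <- sample(30)
  expect_identical(alleleFrequency(mkCalls(m5[perm, , drop = FALSE]),
                                   "s1"), f)
  swapped <- chartr("AB", "BA", calls)
  swapped[calls == "AB"] <- "AB"
  m6 <- matrix(swapped, ncol = 1, dimnames = dimnames(m5))
  expect_equal(alleleFrequency(mkCalls(m6), "s1"), 1 - f)
})

test_that("histogram bins are left-open right-closed with 0 in bin one", {
  expect_identical(unname(frequencyHistogram(0)[1]), 1L)
  expect_identical(unname(frequencyHistogram(1)[10]), 1L)
  h <- frequencyHistogram(0.1)
  expect_identical(unname(h[1]), 1L)          # 0.1 <= right border
  expect_identical(sum(h), 1L)
  expect_error(frequencyHistogram(1.2), "\\[0, 1\\]")
  set.seed(6)
  x <- runif(500)
  expect_identical(sum(frequencyHistogram(x)), 500L)
})

test_that("residual heterozygosity is the AB fraction of assayed loci", {
  m <- matrix("AA", 2, 3145,
              dimnames = list(c("Lo7", "x"), sprintf("s%d", 1:3145)))
  m["Lo7", 1:141] <- "AB"
  gc <- mkCalls(m)
  expect_equal(residualHeterozygosity(gc, "Lo7"), 141 / 3145)
  expect_identical(residualHeterozygosity(gc, "x"), 0)
})

test_that("selfing expectation halves per generation and parses labels", {
  expect_equal(expectedHeterozygosity("F7"), 1 / 64)
  expect_equal(expectedHeterozygosity("F6:9"), 1 / 32)
  expect_equal(expectedHeterozygosity("F_7_"), 1 / 64)
  expect_identical(expectedHeterozygosity("F1"), 1)
  expect_error(expectedHeterozygosity("G7"), "parse")
  expect_error(expectedHeterozygosity("F0"), ">= 1")
  for (g in 1:10)
    expect_equal(expectedHeterozygosity(sprintf("F%d", g + 1)),
                 expectedHeterozygosity(sprintf("F%d", g)) / 2)
})

test_that("the exact binomial excess test matches tail summation", {
  r <- testExcessHeterozygosity(3, 10, 0.5)
  expect_equal(r$p.value, 968 / 1024)
  expect_identical(r$stars, "")
  r2 <- testExcessHeterozygosity(141, 3145, 1 / 64)
  expect_lt(r2$p.value, 0.001)
  expect_identical(r2$stars, "***")
  # null-consistent observation is never starred
  r3 <- testExcessHeterozygosity(50, 100, 0.5)
  expect_gt(r3$p.value, 0.4)
  expect_identical(r3$stars, "")
  expect_error(testExcessHeterozygosity(11, 10, 0.5), "nHet")
  expect_error(testExcessHeterozygosity(1, 10, 1), "expectedP")
  # spot agreement with the explicit pmf oracle
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    k <- sample(0:n, 1)
    p <- sample(c(0.015625, 0.1, 0.5), 1)
    expect_equal(testExcessHeterozygosity(k, n, p)$p.value,
                 binomTailOracle(k, n, p))
  }
})

test_that("pool summaries average lines and spot monomorphic SNPs", {
  m <- matrix("AA", 4, 100,
              dimnames = list(c("a", "b", "c", "d"),
                              sprintf("s%03d", 1:100)))
  m["a", 1:4] <- "AB"    # 4% of 100
  m["b", 1:6] <- "AB"    # 6%
  m["c", 7:56] <- "BB"   # polymorphic within pollen pool? both lines c,d
  gc <- mkCalls(m, pool = c("seed", "seed", "pollen", "pollen"))
  ps <- poolSummary(gc)
  expect_equal(ps$mean_heterozygosity[ps$pool == "seed"], 0.05)
  # pollen pool: s007..s056 split AA/BB -> polymorphic; rest monomorphic
  expect_equal(ps$monomorphic_fraction[ps$pool == "pollen"], 0.5)
  expect_equal(ps$mean_heterozygosity[ps$pool == "pollen"], 0)
})

test_that("the per-line report reproduces the genotyped-panel table", {
  counts <- utils::read.delim(
    system.file("extdata", "rye5k_line_counts.tsv",
                package = "TranscriptMarkers"))
  rep <- heterozygosityReport(counts)
  expect_identical(rep$observed_pct, c(4.5, 4.1, 4.7, 4.8, 4.4))
  expect_identical(rep$expected_pct, c(1.6, 1.6, 1.6, 1.6, 3.1))
  expect_true(all(rep$p_value < 0.05))
  expect_true(all(rep$stars != ""))
})
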