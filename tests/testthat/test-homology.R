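hitRow <- function(q, s, id, len, ev, bits, qstart = 1, qend = qstart + len - 1,
                   sstart = 1, send = len) {
  paste(q, s, id, len, 0, 0, qstart, qend, sstart, send,
        format(ev, scientific = TRUE), bits, sep = "\t")
}

test_that("tabular hits parse, tolerate extra columns, reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hitRow("q1", "s1", 85.5, 120, 1e-30, 200),
               paste0(hitRow("q2", "s2", 71.0, 40, 1e-5, 50),
                      "\textra\tcols")), f)
  h <- readHitsTable(f)
  expect_identical(nrow(h), 2L)
  expect_identical(h$percent_identity, c(85.5, 71.0))
  writeLines(c(hitRow("q1", "s1", 85.5, 120, 1e-30, 200),
               "q2\ts2\tonly\tfour"), f)
  expect_error(readHitsTable(f), "line 2")
  writeLines("q1\ts1\tNOTNUM\t120\t0\t0\t1\t120\t1\t120\t1e-30\t200", f)
  expect_error(readHitsTable(f), "line 1")
})

test_that("identity/length filtering and best-hit selection follow the rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hitRow("q1", "s1", 65, 100, 1e-30, 120),  # identity fail
               hitRow("q2", "s1", 75, 40, 1e-10, 80),
               hitRow("q2", "s2", 75, 40, 1e-12, 95),    # better bits
               hitRow("q3", "s1", 90, 25, 1e-10, 60),    # length fail
               hitRow("q4", "s1", 80, 50, 1e-8, 70),
               hitRow("q4", "s2", 80, 50, 1e-11, 70)),   # tie -> min e
             f)
  h <- readHitsTable(f)
  out <- filterHits(h)
  expect_identical(out$query_id, c("q2", "q4"))
  expect_identical(out$subject_id, c("s2", "s2"))
  # idempotence
  expect_identical(filterHits(out), out)
  # without best-hit collapsing both q2 hits survive
  expect_identical(nrow(filterHits(h, bestHitOnly = FALSE)), 4L)

  expect_identical(overlapPercentage(10, 0), 0)
  expect_identical(overlapPercentage(10, 10), 100)
  expect_error(overlapPercentage(10, 11), "exceed")
  expect_error(overlapPercentage(0, 0), ">= 1")
})

test_that("contamination screening discards on e-value plus coverage", {
  cs <- ContigSet(c(big = randomSeq(1000), other = randomSeq(500)),
                  lineTags = "Lo7")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hitRow("big", "chloroplast", 95, 500, 1e-30, 400,
                      qstart = 100, qend = 599),
               hitRow("other", "chloroplast", 95, 40, 1e-30, 80,
                      qstart = 1, qend = 40)), f)
  hits <- readHitsTable(f)
  res <- contaminationScreen(cs, hits)
  expect_identical(contigIds(res$discarded), "big")    # 500/1000 >= 10%
  expect_identical(contigIds(res$kept), "other")       # 40/500 = 8% < 10%
  # weak e-value never discards
  hits2 <- hits; hits2$e_value <- 1e-10
  res2 <- contaminationScreen(cs, hits2)
  expect_length(contigIds(res2$discarded), 0L)
  # partition is exhaustive
  expect_identical(sort(c(contigIds(res$kept), contigIds(res$discarded))),
                   c("big", "other"))
  hits$query_id[1] <- "ghost"
  expect_error(contaminationScreen(cs, hits), "ghost")
})

test_that("window densities follow the midpoint rule and N masking", {
  # no hits: all windows zero
  d0 <- windowDensity(data.frame(subject_id = character(0),
                                 sstart = integer(0), send = integer(0)),
                      c(bd1 = 2e6))
  expect_identical(nrow(d0), 16L)       # floor((2e6-5e5)/1e5)+1
  expect_true(all(d0$hit_count == 0L))

  # one 300 bp hit at 250 kb on a 1 Mb chromosome
  h1 <- data.frame(subject_id = "bd1", sstart = 250001L, send = 250300L)
  d1 <- windowDensity(h1, c(bd1 = 1e6))
  hitw <- d1[d1$hit_count > 0, ]
  expect_identical(hitw$window_start, c(0, 1e5, 2e5))
  expect_identical(unique(hitw$density_per_mb), 2)

  # conservation under non-overlapping tiling, no mask
  set.seed(33)
  n <- 200L
  st <- sample(1:(2e6 - 400), n)
  hh <- data.frame(subject_id = "bd1", sstart = st, send = st + 299L)
  dt <- windowDensity(hh, c(bd1 = 2e6), window = 5e5, shift = 5e5)
  expect_identical(sum(dt$hit_count), n)

  # fully N-masked window reports zero despite hits
  mask <- data.frame(chrom = "bd1", start = 0L, end = 5e5)
  dm <- windowDensity(hh, c(bd1 = 2e6), nMask = mask,
                      window = 5e5, shift = 5e5)
  expect_identical(dm$hit_count[1], 0L)
  expect_identical(dm$density_per_mb[1], 0)
  expect_gt(dm$n_fraction[1], 0.6)
  expect_identical(dm$hit_count[-1], dt$hit_count[-1])

  # union coverage never exceeds 100% even with stacked hits
  dup <- rbind(hh, hh, hh)
  dd <- windowDensity(dup, c(bd1 = 2e6), window = 5e5, shift = 5e5)
  expect_true(all(dd$bp_coverage_percent <= 100))

  expect_error(windowDensity(h1, c(bd1 = 1e6), shift = 0), "positive")
  expect_error(windowDensity(
    data.frame(subject_id = "bd1", sstart = 1L, send = 2e6 + 1),
    c(bd1 = 2e6)), "bounds")
})

test_that("density matrices have one row per track, one column per window", {
  h <- data.frame(subject_id = "bd1", sstart = 100001L, send = 100300L)
  d <- windowDensity(h, c(bd1 = 1.1e6))
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- exportDensityMatrix(d, f)
  expect_identical(dim(m), c(1L, 7L))   # floor((1.1e6-5e5)/1e5)+1
  d2 <- windowDensity(h, c(bd1 = 2e6))
  m2 <- exportDensityMatrix(d2, f)
  expect_identical(ncol(m2), 16L)
  tab <- utils::read.delim(f)
  expect_identical(nrow(tab), 1L)
  # empty input still writes a header-only file
  empty <- d2[0, ]
  exportDensityMatrix(empty, f)
  expect_identical(length(readLines(f)), 1L)
})
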