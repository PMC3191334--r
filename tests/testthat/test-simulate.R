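test_that("every generator is byte-deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 101, nTranscripts = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulateStudy(cfg, dir = d1)
  s2 <- simulateStudy(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "reference.fasta")),
                   readLines(file.path(d2, "reference.fasta")))
  expect_identical(readLines(file.path(d1, "truth.sam")),
                   readLines(file.path(d2, "truth.sam")))
  expect_identical(readLines(file.path(d1, "fastq", "Lo7.fastq")),
                   readLines(file.path(d2, "fastq", "Lo7.fastq")))
  expect_identical(s1$lineData$snpTruth, s2$lineData$snpTruth)
})

test_that("zero rates give identical lines and exact-substring reads", {
  cfg <- simulationConfig(seed = 5, nTranscripts = 4, snpRate = 0,
                          indelProb = 0)
  ref <- simulateReference(cfg)
  ld <- deriveLineVariants(ref, cfg)
  refChr <- as.character(contigSeqs(ref$contigs))
  for (l in cfg$lineIds)
    expect_identical(unname(ld$lineSeqs[[l]]), unname(refChr))
  expect_identical(nrow(ld$snpTruth), 0L)
  reads <- simulateReads(ld, ref, cfg)
  expect_true(all(grepl("^[0-9]+M$", reads$cigar)))
  for (i in sample(nrow(reads), 25)) {
    r <- reads[i, ]
    expect_identical(r$seq, substr(refChr[[r$contig_id]], r$pos,
                                   r$pos + nchar(r$seq) - 1L))
  }
})

test_that("per-column depth is near the configured coverage in the interior", {
  cfg <- simulationConfig(seed = 23, nTranscripts = 4)
  sim <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  writeTruthSam(sim$reads, sim$reference, sam, lineIds = cfg$lineIds)
  lineOf <- setNames(cfg$lineIds, cfg$lineIds)
  for (id in contigIds(sim$reference$contigs)[1:2]) {
    L <- Biostrings::width(contigSeqs(sim$reference$contigs)[id])
    pu <- buildPileup(sam, list(id = id, length = L), lineOf)
    interior <- 100:(L - 100)
    meanDepth <- mean(pileupDepth(pu)[interior]) / length(cfg$lineIds)
    expect_gt(meanDepth, 0.8 * cfg$coverage)
    expect_lt(meanDepth, 1.35 * cfg$coverage)
  }
})

test_that("planted SSRs are recovered totally and exactly at zero error", {
  cfg <- simulationConfig(seed = 47, nTranscripts = 30)
  ref <- simulateReference(cfg)
  expect_gt(nrow(ref$ssrTruth), 0L)
  seqs <- as.character(contigSeqs(ref$contigs))
  found <- do.call(rbind, lapply(names(seqs), function(id)
    findSSRs(seqs[[id]], contigId = id)))
  expect_identical(found$contig_id, ref$ssrTruth$contig_id)
  expect_identical(found$start, ref$ssrTruth$start)
  expect_identical(found$unit, ref$ssrTruth$unit)
  expect_identical(found$repeat_count, ref$ssrTruth$repeat_count)
})

test_that("genotype-matrix simulation honours its planted parameters", {
  g0 <- simulateGenotypeMatrix(300, missingRate = 0, seed = 3,
                               panel = within(defaultPanelInfo(),
                                              het_rate <- 0))
  expect_identical(sum(genotypeMatrix(g0$calls) == "AB"), 0L)

  gm <- simulateGenotypeMatrix(2000, missingRate = 0.02, seed = 3)
  m <- genotypeMatrix(gm$calls)
  panel <- gm$truth$panel
  for (i in sample(nrow(panel), 10)) {
    h <- residualHeterozygosity(gm$calls, panel$line_id[i])
    p <- panel$het_rate[i]
    n <- sum(!is.na(m[panel$line_id[i], ]))
    expect_lt(abs(h - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
  # missing-data cleaning removes roughly the binomial-expected columns
  miss <- colMeans(is.na(m))
  kept <- ncol(genotypeMatrix(cleanSnps(gm$calls)))
  expect_identical(kept, sum(miss <= 0.05))
  expected_removed <- 2000 * pbinom(0.05 * 59, 59, 0.02,
                                    lower.tail = FALSE)
  expect_lt(abs((2000 - kept) - expected_removed),
            4 * sqrt(expected_removed) + 25)

  # pool summary recovers the planted pool means within sampling error
  ps <- poolSummary(gm$calls)
  expect_lt(abs(ps$mean_heterozygosity[ps$pool == "pollen"] - 0.115),
            0.01)
  expect_lt(abs(ps$mean_heterozygosity[ps$pool == "seed"] - 0.055),
            0.01)
})

test_that("with 454-style errors, artefact candidates stay near their causes", {
  cfg <- simulationConfig(seed = 71, nTranscripts = 10,
                          homopolymerErrorRate = 0.3,
                          readStartErrorRate = 0.02)
  sim <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  writeTruthSam(sim$reads, sim$reference, sam, lineIds = cfg$lineIds)
  res <- discoverSnps(sam, sim$reference$contigs)
  truthKey <- with(sim$lineData$snpTruth, paste(contig_id, pos))
  cand <- res$candidates
  false <- cand[!paste(cand$contig_id, cand$pos) %in% truthKey, ,
                drop = FALSE]
  if (nrow(false)) {
    seqs <- contigSeqs(sim$reference$contigs)
    nearCause <- vapply(seq_len(nrow(false)), function(i) {
      # within 5 bp of a homopolymer run, 10 bp of a read start,
      # or adjacent to error-induced indel evidence
      false$dist_homopolymer[i] <= 5 || false$dist_indel[i] <= 5 ||
        any(abs(sim$reads$pos[sim$reads$contig_id ==
                                false$contig_id[i]] - 1 +
                  10 - false$pos[i]) <= 10)
    }, TRUE)
    expect_true(all(nearCause))
  }
  succeed()
})
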