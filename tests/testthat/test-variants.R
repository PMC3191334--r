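test_that("a clean biallelic column is called homozygous in both lines", {
  L <- 200L
  cnt <- list(Lo7 = countsMatrix(L, list("A", 100, 5)),
              Lo225 = countsMatrix(L, list("G", 100, 5)))
  cand <- detectVariants(makePileup(cnt))
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$pos, 99L)
  expect_identical(cand$allele_a, "A")
  expect_identical(cand$allele_b, "G")
  expect_identical(cand$call_Lo7, "A")
  expect_identical(cand$call_Lo225, "G")
})

test_that("a sub-threshold minor fraction is not a second allele", {
  L <- 200L
  # Lo7 has A:5 G:1 (1/6 < 0.2); Lo225 G:5 -> G supported via Lo225 only
  cnt <- list(Lo7 = countsMatrix(L, list("A", 100, 5), list("G", 100, 1)),
              Lo225 = countsMatrix(L, list("G", 100, 5)))
  cand <- detectVariants(makePileup(cnt))
  expect_identical(cand$n_alleles, 2L)
  expect_identical(cand$call_Lo7, "A")    # 5/6 >= 0.8 majority
  # without Lo225, G has no line with >= 2 reads: no candidate at all
  cand2 <- detectVariants(makePileup(cnt["Lo7"]))
  expect_identical(nrow(cand2), 0L)
})

test_that("the filter ladder flags distance and polymorphism failures", {
  L <- 400L
  seqc <- {
    set.seed(3)
    s <- randomSeq(L)
    # remove accidental homopolymer runs, then plant one A x 6 at 200
    while (nrow(homopolymerRuns(s, 4)) > 0) s <- randomSeq(L)
    paste0(substr(s, 1, 199), "AAAAAA", substr(s, 206, L))
  }
  mk <- function(pos) {
    cnt <- list(Lo7 = countsMatrix(L, list("C", pos + 1, 5)),
                Lo225 = countsMatrix(L, list("G", pos + 1, 5)))
    detectVariants(makePileup(cnt))
  }
  fc <- filterConfig()

  near_end <- filterCandidates(mk(30L), seqc, config = fc)
  expect_match(near_end$filter_flags, "near_contig_end")
  expect_false(near_end$pass)

  near_hp <- filterCandidates(mk(207L), seqc, config = fc)  # 3 bp right of run
  expect_identical(near_hp$dist_homopolymer, 3)
  expect_match(near_hp$filter_flags, "near_homopolymer")

  near_indel <- filterCandidates(mk(150L), seqc, indelCols = 120L,
                                 config = fc)
  expect_identical(near_indel$dist_indel, 30)
  expect_match(near_indel$filter_flags, "near_indel")

  clean <- filterCandidates(mk(120L), seqc, config = fc)
  expect_identical(clean$filter_flags, "")
  expect_true(clean$pass)

  # tri-allelic column
  cnt3 <- list(Lo7 = countsMatrix(L, list("A", 121, 5)),
               Lo152 = countsMatrix(L, list("C", 121, 5)),
               Lo225 = countsMatrix(L, list("G", 121, 5)))
  tri <- filterCandidates(detectVariants(makePileup(cnt3)), seqc,
                          config = fc)
  expect_match(tri$filter_flags, "not_biallelic")

  # both parents same homozygote: not parent polymorphic
  cntSame <- list(Lo7 = countsMatrix(L, list("A", 121, 5)),
                  Lo225 = countsMatrix(L, list("A", 121, 5)),
                  P87 = countsMatrix(L, list("A", 121, 2),
                                     list("G", 121, 3)))
  same <- filterCandidates(detectVariants(makePileup(cntSame)), seqc,
                           config = fc)
  expect_match(same$filter_flags, "not_parent_polymorphic")
})

test_that("loosening any threshold never shrinks the pass set", {
  cfg <- simulationConfig(seed = 13, nTranscripts = 8)
  sim <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  writeTruthSam(sim$reads, sim$reference, sam, lineIds = cfg$lineIds)
  strict <- discoverSnps(sam, sim$reference$contigs)
  passStrict <- with(strict$candidates[strict$candidates$pass, ],
                     paste(contig_id, pos))
  for (loose in list(filterConfig(minDistHomopolymer = 2L),
                     filterConfig(minDistIndel = 10L),
                     filterConfig(minDistContigEnd = 20L))) {
    res <- discoverSnps(sam, sim$reference$contigs, config = loose)
    passLoose <- with(res$candidates[res$candidates$pass, ],
                      paste(contig_id, pos))
    expect_true(all(passStrict %in% passLoose))
  }
})

test_that("probe contexts have canonical allele order and exact length", {
  s <- paste(rep("ACGT", 50), collapse = "")          # 200 bp
  cand <- data.frame(pos = 100L, allele_a = "G", allele_b = "A")
  ctx <- probeContext(cand, s, flank = 60L)
  expect_identical(nchar(ctx), 125L)
  expect_match(ctx, "\\[A/G\\]")
  expect_identical(substr(ctx, 61, 65), "[A/G]")
  # candidate exactly 61 bp from the end still has a 60 bp flank
  edge <- data.frame(pos = nchar(s) - 62L, allele_a = "A",
                     allele_b = "C")
  expect_identical(nchar(probeContext(edge, s, 60L)), 125L)
  near <- data.frame(pos = 30L, allele_a = "A", allele_b = "C")
  expect_error(probeContext(near, s, 60L), "insufficient")
})

test_that("written VCF re-parses to the same candidate set", {
  cfg <- simulationConfig(seed = 17, nTranscripts = 6)
  sim <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "t.sam")
  writeTruthSam(sim$reads, sim$reference, sam, lineIds = cfg$lineIds)
  res <- discoverSnps(sam, sim$reference$contigs)
  vcf <- file.path(dir, "cand.vcf")
  writeSnpVcf(res$candidates, sim$reference$contigs, vcf)
  v <- suppressWarnings(VariantAnnotation::readVcf(vcf))
  rr <- SummarizedExperiment::rowRanges(v)
  expect_identical(length(v), nrow(res$candidates))
  expect_identical(unname(BiocGenerics::start(rr)),
                   res$candidates$pos + 1L)
  expect_identical(as.character(GenomeInfoDb::seqnames(rr)),
                   res$candidates$contig_id)
  filt <- VariantAnnotation::filt(v)
  expect_identical(filt == "PASS", res$candidates$pass)
  expect_identical(VariantAnnotation::info(v)$DE,
                   as.integer(res$candidates$dist_contig_end))
  # REF must be one of the two alleles on error-free data
  ref <- as.character(VariantAnnotation::ref(v))
  expect_true(all(ref == res$candidates$allele_a |
                    ref == res$candidates$allele_b))
})

test_that("read-start-only minor support is flagged when enabled", {
  L <- 300L
  cnt <- list(Lo7 = countsMatrix(L, list("A", 150, 6)),
              Lo225 = countsMatrix(L, list("A", 150, 4),
                                   list("G", 150, 2)))
  pu <- makePileup(cnt)
  # all minor-allele (G) evidence sits in the early-window tally
  pu@earlyCounts$Lo225["G", 150] <- 2L
  set.seed(8)
  s <- randomSeq(L)
  while (nrow(homopolymerRuns(s, 4)) > 0) s <- randomSeq(L)
  cand <- detectVariants(pu, filterConfig(dropReadStartOnly = TRUE))
  expect_true(cand$minor_early_only)
  out <- filterCandidates(cand, s,
                          config = filterConfig(dropReadStartOnly = TRUE))
  expect_match(out$filter_flags, "read_start_support")
  out2 <- filterCandidates(cand, s, config = filterConfig())
  expect_false(grepl("read_start_support", out2$filter_flags))
})
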