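#' Simulation configuration
#'
#' Bundles the parameters of the study simulator: a five-line winter
#' rye-style panel sequenced at modest 454 depth. Defaults emulate the
#' scale of the emulated study design: five inbred lines, reads with a
#' median length around 216 bp, about 5x per-line coverage, transcripts
#' of 300-3,000 bp, and two mapping-population parent pairs.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param nTranscripts Number of reference transcripts (default 200).
#' @param lengthRange Transcript length range in bp (default 300-3000).
#' @param lineIds Inbred line ids (default Lo7, Lo152, Lo225, P87, P105).
#' @param parentPairs Mapping-population parent pairs (default
#'   Lo7 x Lo225 and P87 x P105).
#' @param snpRate Per-bp probability of planting a SNP (default 0.002,
#'   about one SNP per 500 bp of transcript, a typical divergence
#'   between inbred crop lines).
#' @param ssrProb Probability that a transcript carries one planted SSR
#'   (default 0.3).
#' @param ssrUnits Candidate SSR units sampled for planting.
#' @param indelProb Probability that a transcript carries one planted
#'   1-3 bp indel segregating between lines (default 0.3).
#' @param readLengthMean,readLengthSd Read length distribution
#'   (defaults 216 and 20 bp, truncated to 150-280).
#' @param coverage Target per-line coverage (default 5).
#' @param homopolymerErrorRate Per-run probability of a +/-1 bp
#'   homopolymer length miscall per read (default 0 = error-free).
#' @param readStartErrorRate Per-base substitution-error probability in
#'   the first 10 read bases (default 0).
#' @return List of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nTranscripts = 200L,
                             lengthRange = c(300L, 3000L),
                             lineIds = c("Lo7", "Lo152", "Lo225",
                                         "P87", "P105"),
                             parentPairs = list(c("Lo7", "Lo225"),
                                                c("P87", "P105")),
                             snpRate = 0.002,
                             ssrProb = 0.3,
                             ssrUnits = c("AC", "AG", "AAG", "AGG",
                                          "ACG", "AAAG", "AATC",
                                          "AACAG", "AACAGC"),
                             indelProb = 0.3,
                             readLengthMean = 216,
                             readLengthSd = 20,
                             coverage = 5,
                             homopolymerErrorRate = 0,
                             readStartErrorRate = 0) {
  stopifnot(seed == as.integer(seed), nTranscripts >= 1L,
            lengthRange[1L] >= 100L, lengthRange[2L] >= lengthRange[1L],
            length(lineIds) >= 1L, snpRate >= 0, snpRate <= 1,
            ssrProb >= 0, ssrProb <= 1, indelProb >= 0, indelProb <= 1,
            coverage > 0,
            homopolymerErrorRate >= 0, homopolymerErrorRate <= 1,
            readStartErrorRate >= 0, readStartErrorRate <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

randDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate reference transcripts with planted SSRs
#'
#' Generates random transcripts and plants at most one perfect SSR per
#' transcript (unit and repeat count sampled from the configuration,
#' count at or above the reporting threshold). Each transcript is
#' rejection-sampled until its SSR content equals exactly the planted
#' truth, so the truth table is exhaustive: no background repeat above
#' threshold confounds recovery statistics. Deterministic under the
#' configuration seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{contigs} (a \code{\link{ContigSet}} tagged with
#'   all lines) and \code{ssrTruth} (\code{data.frame}: contig_id,
#'   start, end, unit, repeat_count).
#' @export
simulateReference <- function(config) {
  set.seed(config$seed)
  minRep <- defaultMinRepeats()
  n <- config$nTranscripts
  seqs <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    L <- sample(config$lengthRange[1L]:config$lengthRange[2L], 1L)
    plant <- stats::runif(1) < config$ssrProb
    unit <- count <- pos <- NULL
    if (plant) {
      unit <- sample(config$ssrUnits, 1L)
      k <- nchar(unit)
      if (k * (minRep[[as.character(k)]] + 3L) + 140L > L)
        plant <- FALSE
    }
    if (plant) {
      count <- minRep[[as.character(k)]] + sample(0:3, 1L)
      span <- k * count
      if (span + 4L > L - 120L) count <- minRep[[as.character(k)]]
      span <- k * count
      pos <- sample(60:(L - span - 60L), 1L)     # 0-based start
    }
    repeat {
      s <- randDNA(L)
      if (plant) {
        rep_str <- strrep(unit, count)
        # break the repeat at both boundaries
        lb <- setdiff(c("A", "C", "G", "T"),
                      substr(unit, k, k))[1L]
        rb <- setdiff(c("A", "C", "G", "T"), substr(unit, 1L, 1L))[1L]
        s <- paste0(substr(s, 1L, pos - 1L), lb, rep_str, rb,
                    substr(s, pos + span + 2L, L))
      }
      found <- findSSRs(s, minRep, contigId = sprintf("tr%04d", i))
      okay <- if (plant) {
        nrow(found) == 1L && found$start == pos &&
          found$unit == unit && found$repeat_count == count
      } else nrow(found) == 0L
      if (okay) break
    }
    seqs[i] <- s
    if (plant)
      truth[[length(truth) + 1L]] <- data.frame(
        contig_id = sprintf("tr%04d", i), start = pos,
        end = pos + k * count, unit = unit, repeat_count = count,
        stringsAsFactors = FALSE)
  }
  names(seqs) <- sprintf("tr%04d", seq_len(n))
  ssrTruth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), unit = character(0),
               repeat_count = integer(0), stringsAsFactors = FALSE)
  list(contigs = ContigSet(seqs, lineTags = config$lineIds),
       ssrTruth = ssrTruth)
}

#' Plant per-line variants on the reference
#'
#' Plants bi-allelic substitution SNPs (each line homozygous for the
#' reference or alternate allele, both alleles carried by at least one
#' line) and at most one 1-3 bp insertion or deletion per transcript,
#' carried by a random non-empty subset of lines. Indel spans never
#' overlap SNP positions, so every planted SNP stays observable. The
#' truth table records per-line genotypes, parent-polymorphism status
#' for the configured pairs, the three filter distances (computed from
#' the reference homopolymer runs, the planted indel columns and the
#' contig ends) and the expected pass/fail label under the default
#' \code{\link{filterConfig}} thresholds.
#'
#' @param reference Output of \code{\link{simulateReference}}.
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{lineSeqs} (named list line -> named character
#'   vector of transcript sequences), \code{variants} (nested list
#'   transcript -> line -> variant table used for read alignment),
#'   \code{snpTruth} and \code{indelTruth} data frames.
#' @export
deriveLineVariants <- function(reference, config) {
  set.seed(config$seed + 1L)
  contigs <- reference$contigs
  ids <- contigIds(contigs)
  seqs <- as.character(contigSeqs(contigs))
  lines <- config$lineIds
  fc <- filterConfig(parentPairs = config$parentPairs)
  snpT <- list(); indelT <- list()
  variants <- list()
  for (id in ids) {
    s <- seqs[[id]]
    L <- nchar(s)
    nSnp <- stats::rbinom(1L, L, config$snpRate)
    x <- strsplit(s, "")[[1L]]
    used <- integer(0)
    snps <- list()
    for (k in seq_len(nSnp)) {
      for (try in 1:50) {
        p <- sample(0:(L - 1L), 1L)
        if (p %in% used) next
        ref <- x[p + 1L]
        used <- c(used, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        repeat {
          g <- stats::rbinom(length(lines), 1L, 0.5)
          if (any(g == 0L) && any(g == 1L)) break
        }
        names(g) <- lines
        snps[[length(snps) + 1L]] <-
          list(pos = p, ref = ref, alt = alt, geno = g)
        break
      }
    }
    indel <- NULL
    if (stats::runif(1) < config$indelProb) {
      len <- sample(1:3, 1L)
      type <- sample(c("del", "ins"), 1L)
      snpPos <- vapply(snps, `[[`, 0, "pos")
      # keep indels > 70 bp from transcript ends so that at default
      # coverage every carrier line has >= 2 spanning reads and the
      # indel column is always recoverable from the pileup
      for (try in 1:50) {
        p <- sample(70:(L - 73L - len), 1L)
        spanCols <- if (type == "del") p:(p + len - 1L) else p
        if (length(intersect(spanCols, snpPos)) == 0L &&
            length(intersect(spanCols, snpPos + 1L)) == 0L &&
            length(intersect(spanCols, snpPos - 1L)) == 0L) {
          repeat {
            carriers <- lines[stats::rbinom(length(lines), 1L, 0.5) == 1L]
            if (length(carriers) >= 1L) break
          }
          ins_seq <- if (type == "ins") randDNA(len) else ""
          indel <- list(pos = p, len = len, type = type,
                        carriers = carriers, ins_seq = ins_seq)
          break
        }
      }
    }
    variants[[id]] <- list(snps = snps, indel = indel)
    # ---- truth bookkeeping ----
    runs <- homopolymerRuns(s, fc$homopolymerMinLen)
    indelCols <- if (is.null(indel)) integer(0) else {
      if (indel$type == "del") indel$pos:(indel$pos + indel$len - 1L)
      else indel$pos - 1L      # ins evidence lands left of the point
    }
    for (sv in snps) {
      p <- sv$pos
      dh <- distToFeature(p, runs$start, runs$start + runs$length)
      di <- distToFeature(p, indelCols, indelCols + 1L)
      de <- min(p, L - 1L - p)
      polym <- any(vapply(config$parentPairs, function(pp)
        sv$geno[pp[1L]] != sv$geno[pp[2L]], TRUE))
      pass <- dh >= fc$minDistHomopolymer && di >= fc$minDistIndel &&
        de >= fc$minDistContigEnd && polym
      snpT[[length(snpT) + 1L]] <- data.frame(
        contig_id = id, pos = p, ref = sv$ref, alt = sv$alt,
        t(sv$geno),
        dist_homopolymer = dh, dist_indel = di, dist_contig_end = de,
        parent_polymorphic = polym, expected_pass = pass,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    if (!is.null(indel))
      indelT[[length(indelT) + 1L]] <- data.frame(
        contig_id = id, pos = indel$pos, length = indel$len,
        type = indel$type,
        carriers = paste(indel$carriers, collapse = ","),
        stringsAsFactors = FALSE)
  }
  # build line sequences
  lineSeqs <- lapply(lines, function(l) {
    out <- vapply(ids, function(id) {
      s <- seqs[[id]]
      x <- strsplit(s, "")[[1L]]
      for (sv in variants[[id]]$snps)
        if (sv$geno[l] == 1L) x[sv$pos + 1L] <- sv$alt
      s2 <- paste(x, collapse = "")
      ind <- variants[[id]]$indel
      if (!is.null(ind) && l %in% ind$carriers) {
        if (ind$type == "del")
          s2 <- paste0(substr(s2, 1L, ind$pos),
                       substr(s2, ind$pos + ind$len + 1L, nchar(s2)))
        else
          s2 <- paste0(substr(s2, 1L, ind$pos), ind$ins_seq,
                       substr(s2, ind$pos + 1L, nchar(s2)))
      }
      s2
    }, "")
    names(out) <- ids
    out
  })
  names(lineSeqs) <- lines
  emptySnp <- data.frame(contig_id = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         stringsAsFactors = FALSE)
  list(lineSeqs = lineSeqs, variants = variants,
       snpTruth = if (length(snpT)) do.call(rbind, snpT) else emptySnp,
       indelTruth = if (length(indelT)) do.call(rbind, indelT) else
         data.frame(contig_id = character(0), pos = integer(0),
                    length = integer(0), type = character(0),
                    carriers = character(0), stringsAsFactors = FALSE))
}

# alignment blocks of one line's transcript against the reference:
# data.frame(op, ref_start, line_start, len), 0-based starts.
lineAlignmentBlocks <- function(Lref, lineVariants, lineId) {
  ind <- lineVariants$indel
  events <- list()
  if (!is.null(ind) && lineId %in% ind$carriers)
    events[[1L]] <- ind
  curR <- 0L; curQ <- 0L
  blocks <- list()
  addM <- function(len) {
    if (len > 0L)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        op = "M", ref_start = curR, line_start = curQ, len = len,
        stringsAsFactors = FALSE)
  }
  for (ev in events) {
    if (ev$type == "del") {
      m <- ev$pos - curR
      addM(m); curR <- curR + m; curQ <- curQ + m
      blocks[[length(blocks) + 1L]] <- data.frame(
        op = "D", ref_start = curR, line_start = NA_integer_,
        len = ev$len, stringsAsFactors = FALSE)
      curR <- curR + ev$len
    } else {
      m <- ev$pos - curR
      addM(m); curR <- curR + m; curQ <- curQ + m
      blocks[[length(blocks) + 1L]] <- data.frame(
        op = "I", ref_start = curR, line_start = curQ, len = ev$len,
        stringsAsFactors = FALSE)
      curQ <- curQ + ev$len
    }
  }
  addM(Lref - curR)
  do.call(rbind, blocks)
}

# CIGAR + 1-based ref pos for a read covering line coords [a, b) —
# start/end adjusted into M blocks; returns NULL for degenerate reads
readCigarFromBlocks <- function(blocks, a, b) {
  qb <- blocks[blocks$op != "D", , drop = FALSE]
  qb$line_end <- qb$line_start + qb$len
  # clip read start/end into M blocks
  startBlock <- which(qb$line_start <= a & a < qb$line_end)
  if (!length(startBlock)) return(NULL)
  if (qb$op[startBlock] == "I") {
    a <- qb$line_end[startBlock]
    startBlock <- startBlock + 1L
    if (startBlock > nrow(qb) || a >= b) return(NULL)
  }
  endBlock <- which(qb$line_start < b & b <= qb$line_end)
  if (!length(endBlock)) return(NULL)
  if (qb$op[endBlock] == "I") {
    b <- qb$line_start[endBlock]
    endBlock <- endBlock - 1L
    if (endBlock < startBlock || a >= b) return(NULL)
  }
  # walk original blocks in order, emitting ops
  ops <- character(0); lens <- integer(0)
  refPos <- NA_integer_
  started <- FALSE
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    if (blk$op == "D") {
      if (started) { ops <- c(ops, "D"); lens <- c(lens, blk$len) }
      next
    }
    le <- blk$line_start + blk$len
    if (le <= a) next
    if (blk$line_start >= b) break
    s <- max(a, blk$line_start); e <- min(b, le)
    if (e <= s) next
    if (!started) {
      if (blk$op != "M") return(NULL)
      refPos <- blk$ref_start + (s - blk$line_start)
      started <- TRUE
    }
    ops <- c(ops, blk$op); lens <- c(lens, e - s)
  }
  # trim trailing D
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (!length(ops)) return(NULL)
  list(cigar = paste0(lens, ops, collapse = ""),
       pos = refPos + 1L, start = a, end = b)
}

#' Simulate 454-style reads with a truth alignment
#'
#' Draws reads per line and transcript with a jittered systematic start
#' layout that guarantees at least two overlapping reads at every
#' position more than ~60 bp from a transcript end at the default
#' coverage (two end-anchored reads plus evenly spread interior
#' starts), read lengths from a truncated normal (median about 216 bp).
#' True CIGARs are derived from the planted variants. The optional
#' error model introduces substitution errors in the first 10 read
#' bases and +/-1 bp miscalls inside homopolymer runs of length >= 4,
#' the two dominant 454 error modes.
#'
#' @param lineData Output of \code{\link{deriveLineVariants}}.
#' @param reference Output of \code{\link{simulateReference}}.
#' @param config A \code{\link{simulationConfig}}.
#' @return \code{data.frame} of reads: \code{qname}, \code{line},
#'   \code{contig_id}, \code{pos} (1-based), \code{cigar}, \code{seq}.
#' @export
simulateReads <- function(lineData, reference, config) {
  set.seed(config$seed + 2L)
  ids <- contigIds(reference$contigs)
  refLens <- stats::setNames(Biostrings::width(contigSeqs(
    reference$contigs)), ids)
  out <- list()
  for (l in config$lineIds) {
    for (id in ids) {
      s <- lineData$lineSeqs[[l]][[id]]
      Lq <- nchar(s)
      blocks <- lineAlignmentBlocks(refLens[[id]],
                                    lineData$variants[[id]], l)
      nReads <- max(2L, ceiling(config$coverage * Lq /
                                  config$readLengthMean))
      lens <- pmin(pmax(round(stats::rnorm(nReads + 2L,
                                           config$readLengthMean,
                                           config$readLengthSd)),
                        150L), 280L)
      lens <- pmin(lens, Lq)
      # two anchored reads + jittered systematic interior starts
      starts <- integer(nReads + 2L)
      starts[1L] <- 0L
      starts[2L] <- Lq - lens[2L]
      if (nReads > 0L) {
        spread <- seq(0L, Lq - 1L, length.out = nReads + 2L)
        spread <- spread[-c(1L, nReads + 2L)]
        jit <- round(stats::runif(nReads, -0.25, 0.25) *
                       (Lq / (nReads + 1L)))
        st <- pmin(pmax(round(spread) + jit, 0L), Lq - 1L)
        starts[3:(nReads + 2L)] <- pmin(st, Lq - lens[3:(nReads + 2L)])
        starts <- pmax(starts, 0L)
      }
      for (r in seq_along(starts)) {
        a <- starts[r]; b <- min(a + lens[r], Lq)
        cg <- readCigarFromBlocks(blocks, a, b)
        if (is.null(cg)) next
        rseq <- substr(s, cg$start + 1L, cg$end)
        er <- applyReadErrors(rseq, cg$cigar, config)
        out[[length(out) + 1L]] <- data.frame(
          qname = sprintf("%s_%s_r%03d", l, id, r), line = l,
          contig_id = id, pos = cg$pos, cigar = er$cigar, seq = er$seq,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# optional 454-style error model on one read
applyReadErrors <- function(rseq, cigar, config) {
  if (config$readStartErrorRate > 0) {
    x <- strsplit(rseq, "")[[1L]]
    k <- min(10L, length(x))
    err <- stats::runif(k) < config$readStartErrorRate
    for (i in which(err))
      x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
    rseq <- paste(x, collapse = "")
  }
  if (config$homopolymerErrorRate > 0) {
    runs <- homopolymerRuns(rseq, 4L)
    # only alter runs wholly inside a single M op of a plain cigar
    if (nrow(runs) && grepl("^[0-9]+M$", cigar)) {
      for (i in seq_len(nrow(runs))) {
        if (stats::runif(1) >= config$homopolymerErrorRate) next
        st <- runs$start[i]; len <- runs$length[i]
        over <- stats::runif(1) < 0.5
        Lr <- nchar(rseq)
        if (st + len >= Lr || st + len < 2L) next   # run touching an end
        if (over) {
          rseq <- paste0(substr(rseq, 1L, st + len),
                         runs$base[i],
                         substr(rseq, st + len + 1L, Lr))
          cigar <- paste0(st + len, "M1I", Lr - st - len, "M")
        } else {
          rseq <- paste0(substr(rseq, 1L, st + len - 1L),
                         substr(rseq, st + len + 1L, Lr))
          cigar <- paste0(st + len - 1L, "M1D", Lr - st - len, "M")
        }
        break   # at most one homopolymer error per read
      }
    }
  }
  list(seq = rseq, cigar = cigar)
}

#' Write simulated reads as SAM and per-line FASTQ
#'
#' @param reads Read table from \code{\link{simulateReads}}.
#' @param reference Output of \code{\link{simulateReference}}.
#' @param samPath Output SAM path.
#' @param fastqDir Optional directory for per-line FASTQ files.
#' @param lineIds Line ids for read groups.
#' @return \code{samPath}, invisibly.
#' @export
writeTruthSam <- function(reads, reference, samPath, fastqDir = NULL,
                          lineIds = unique(reads$line)) {
  ids <- contigIds(reference$contigs)
  lens <- Biostrings::width(contigSeqs(reference$contigs))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ids, lens),
           sprintf("@RG\tID:%s\tSM:%s", lineIds, lineIds))
  rec <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                 reads$qname, reads$contig_id, reads$pos, reads$cigar,
                 reads$seq, strrep("I", nchar(reads$seq)), reads$line)
  writeLines(c(hdr, rec), samPath)
  if (!is.null(fastqDir)) {
    dir.create(fastqDir, showWarnings = FALSE, recursive = TRUE)
    for (l in lineIds) {
      rr <- reads[reads$line == l, , drop = FALSE]
      fq <- file.path(fastqDir, paste0(l, ".fastq"))
      writeLines(paste0("@", rr$qname, "\n", rr$seq, "\n+\n",
                        strrep("I", nchar(rr$seq))), fq)
    }
  }
  invisible(samPath)
}

#' Default 59-line genotyping panel
#'
#' The five sequenced lines plus 27 seed-pool lines (five selfing
#' steps, planted residual heterozygosity 5.5\%) and 27 pollen-pool
#' lines (two to three selfing steps, planted 11.5\%), mirroring the
#' two-heterotic-pool design of hybrid rye breeding panels.
#'
#' @return \code{data.frame}: \code{line_id}, \code{pool},
#'   \code{generation}, \code{het_rate}.
#' @export
defaultPanelInfo <- function() {
  seq5 <- data.frame(
    line_id = c("Lo7", "Lo152", "Lo225", "P87", "P105"),
    pool = c("seed", "seed", "pollen", "other", "other"),
    generation = c("F7", "F7", "F7", "F7:10", "F6:9"),
    het_rate = c(0.045, 0.041, 0.047, 0.048, 0.044),
    stringsAsFactors = FALSE)
  seed <- data.frame(
    line_id = sprintf("S%02d", 1:27), pool = "seed", generation = "F6",
    het_rate = 0.055, stringsAsFactors = FALSE)
  pollen <- data.frame(
    line_id = sprintf("P%02d", 1:27), pool = "pollen",
    generation = "F3", het_rate = 0.115, stringsAsFactors = FALSE)
  rbind(seq5, seed, pollen)
}

#' Simulate a genotype-call matrix
#'
#' Draws per-SNP allele frequencies uniformly on 0.1-0.9 and per-line
#' calls: heterozygous with the line's planted residual-heterozygosity
#' rate, otherwise homozygous AA with probability equal to the A-allele
#' frequency; calls are masked missing at \code{missingRate}.
#'
#' @param nSnps Number of SNP assays.
#' @param panel Panel description (default \code{\link{defaultPanelInfo}}).
#' @param missingRate Per-call missing probability (default 0.02).
#' @param seed Integer seed.
#' @return List: \code{calls} (a \code{\link{GenotypeCalls}}),
#'   \code{truth} (list with \code{freqs} and the \code{panel}).
#' @export
simulateGenotypeMatrix <- function(nSnps, panel = defaultPanelInfo(),
                                   missingRate = 0.02, seed = 1L) {
  stopifnot(missingRate >= 0, missingRate <= 1,
            all(panel$het_rate >= 0 & panel$het_rate <= 1))
  set.seed(seed)
  nL <- nrow(panel)
  freqs <- stats::runif(nSnps, 0.1, 0.9)
  m <- matrix(NA_character_, nL, nSnps,
              dimnames = list(panel$line_id,
                              sprintf("snp%05d", seq_len(nSnps))))
  for (i in seq_len(nL)) {
    het <- stats::runif(nSnps) < panel$het_rate[i]
    hom <- stats::runif(nSnps) < freqs
    m[i, ] <- ifelse(het, "AB", ifelse(hom, "AA", "BB"))
  }
  if (missingRate > 0)
    m[matrix(stats::runif(length(m)) < missingRate, nL)] <- NA_character_
  calls <- GenotypeCalls(m, panel[, c("line_id", "pool", "generation")])
  list(calls = calls, truth = list(freqs = freqs, panel = panel))
}

#' Run the full study simulation
#'
#' Convenience orchestrator: reference with planted SSRs, per-line
#' variants, reads with truth SAM, and (optionally) files written to a
#' directory (reference FASTA + provenance, per-line FASTA, FASTQ,
#' truth SAM, truth TSVs).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param dir Optional output directory.
#' @return List with \code{reference}, \code{lineData}, \code{reads},
#'   and (when \code{dir} given) \code{paths}.
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  reference <- simulateReference(config)
  lineData <- deriveLineVariants(reference, config)
  reads <- simulateReads(lineData, reference, config)
  res <- list(reference = reference, lineData = lineData, reads = reads)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "reference.fasta")
    writeContigs(reference$contigs, fa)
    sam <- file.path(dir, "truth.sam")
    writeTruthSam(reads, reference, sam,
                  fastqDir = file.path(dir, "fastq"),
                  lineIds = config$lineIds)
    utils::write.table(lineData$snpTruth,
                       file.path(dir, "snp_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lineData$indelTruth,
                       file.path(dir, "indel_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(reference$ssrTruth,
                       file.path(dir, "ssr_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$paths <- list(fasta = fa, sam = sam)
  }
  res
}
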