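#' Candidate-filter configuration
#'
#' Bundles the thresholds of the SNP selection ladder. The distance
#' criteria follow the probe-design requirements: a usable SNP must lie
#' strictly more than 5 bp from any homopolymer run, more than 60 bp
#' from the nearest indel column and more than 60 bp from either contig
#' end, and must be bi-allelic and polymorphic between the parents of at
#' least one configured mapping-population pair.
#'
#' @param minDistHomopolymer Minimum distance to a homopolymer run in bp
#'   (default 6, i.e. strictly > 5).
#' @param minDistIndel Minimum distance to an indel column (default 61,
#'   strictly > 60).
#' @param minDistContigEnd Minimum distance to either contig end
#'   (default 61, strictly > 60).
#' @param parentPairs List of length-2 character vectors of line ids;
#'   default \code{list(c("Lo7","Lo225"), c("P87","P105"))}.
#' @param minReadsPerLineAllele Reads required within one line for an
#'   allele to count as supported (default 2).
#' @param maxMinorReadFraction Within-line fraction below which a
#'   second base is treated as noise (default 0.2). The major-allele
#'   threshold \code{1 - maxMinorReadFraction} is compared with
#'   \code{>=}, the minor threshold with \code{>}.
#' @param homopolymerMinLen Minimum run length scanned for the distance
#'   criterion (default 4).
#' @param dropReadStartOnly If \code{TRUE}, flag candidates whose minor
#'   allele is supported only by read-start evidence (default
#'   \code{FALSE}); automatable proxy for manual inspection.
#' @return A list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(minDistHomopolymer = 6L,
                         minDistIndel = 61L,
                         minDistContigEnd = 61L,
                         parentPairs = list(c("Lo7", "Lo225"),
                                            c("P87", "P105")),
                         minReadsPerLineAllele = 2L,
                         maxMinorReadFraction = 0.2,
                         homopolymerMinLen = 4L,
                         dropReadStartOnly = FALSE) {
  stopifnot(minDistHomopolymer > 0L, minDistIndel > 0L,
            minDistContigEnd > 0L, minReadsPerLineAllele > 0L,
            maxMinorReadFraction > 0, maxMinorReadFraction < 0.5)
  structure(list(minDistHomopolymer = as.integer(minDistHomopolymer),
                 minDistIndel = as.integer(minDistIndel),
                 minDistContigEnd = as.integer(minDistContigEnd),
                 parentPairs = parentPairs,
                 minReadsPerLineAllele = as.integer(minReadsPerLineAllele),
                 maxMinorReadFraction = maxMinorReadFraction,
                 homopolymerMinLen = as.integer(homopolymerMinLen),
                 dropReadStartOnly = isTRUE(dropReadStartOnly)),
            class = "FilterConfig")
}

BASES <- c("A", "C", "G", "T")

# per-line call at one column given counts named by base
callLine <- function(cnt, alleles, minReads, maxMinor) {
  tot <- sum(cnt)
  if (tot == 0L) return(list(call = "no-call", reads = 0L))
  f <- cnt / tot
  sup <- BASES[f > maxMinor & cnt >= minReads]
  major <- BASES[which.max(cnt)]
  if (f[major] >= 1 - maxMinor && cnt[major] >= minReads &&
      major %in% alleles)
    return(list(call = major, reads = unname(cnt[major])))
  if (length(sup) == 2L && all(sup %in% alleles))
    return(list(call = "het", reads = sum(cnt[sup])))
  list(call = "no-call", reads = 0L)
}

#' Detect bi-allelic variant candidates from a pileup
#'
#' A column becomes a candidate when at least two distinct bases each
#' have, in at least one line, at least
#' \code{config$minReadsPerLineAllele} supporting reads. This is a
#' transparent count-threshold caller: per-line genotypes are assigned
#' from within-line read fractions (see \code{\link{filterConfig}}),
#' with the two best-supported bases reported as alleles A/B in
#' alphabetical order. Filter flags are populated later by
#' \code{\link{filterCandidates}}.
#'
#' @param pileup A \code{\link{Pileup}}.
#' @param config A \code{\link{filterConfig}}.
#' @return \code{data.frame}: \code{contig_id}, \code{pos} (0-based),
#'   \code{allele_a}, \code{allele_b}, \code{n_alleles}, one
#'   \code{call_<line>} and \code{reads_<line>} column per line, plus a
#'   \code{minor_early_only} logical column (read-start proxy input).
#' @export
detectVariants <- function(pileup, config = filterConfig()) {
  cnts <- pileupCounts(pileup)
  lines <- names(cnts)
  L <- ncol(cnts[[1L]])
  minReads <- config$minReadsPerLineAllele
  # lines x 4 x L support: does any line give >= minReads for the base?
  baseArr <- vapply(cnts, function(m) m[1:4, , drop = FALSE],
                    matrix(0L, 4L, L))           # 4 x L x nlines
  dimnames(baseArr) <- list(BASES, NULL, lines)
  supported <- apply(baseArr >= minReads, c(1, 2), any)   # 4 x L
  nSupp <- colSums(supported)
  candCols <- which(nSupp >= 2L)
  if (!length(candCols)) return(emptyCandidateFrame(lines))
  rows <- lapply(candCols, function(j) {
    perLine <- baseArr[, j, , drop = TRUE]       # 4 x nlines (or vector)
    if (is.null(dim(perLine)))
      perLine <- matrix(perLine, nrow = 4L,
                        dimnames = list(BASES, lines))
    rownames(perLine) <- BASES
    totals <- rowSums(perLine)
    sup <- BASES[supported[, j]]
    ord <- sup[order(-totals[sup], sup)]
    alleles <- sort(ord[1:2])
    calls <- lapply(lines, function(l)
      callLine(stats::setNames(perLine[, l], BASES), alleles,
               minReads, config$maxMinorReadFraction))
    names(calls) <- lines
    # minor allele = lesser total support among the two alleles
    minor <- alleles[which.min(totals[alleles])]
    earlyTot <- sum(vapply(lines, function(l)
      pileup@earlyCounts[[l]][minor, j], 0L))
    minorEarlyOnly <- earlyTot >= totals[minor] && totals[minor] > 0
    row <- data.frame(contig_id = pileup@contigId, pos = j - 1L,
                      allele_a = alleles[1L], allele_b = alleles[2L],
                      n_alleles = length(sup),
                      minor_early_only = minorEarlyOnly,
                      stringsAsFactors = FALSE)
    for (l in lines) {
      row[[paste0("call_", l)]] <- calls[[l]]$call
      row[[paste0("reads_", l)]] <- calls[[l]]$reads
    }
    row
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

emptyCandidateFrame <- function(lines) {
  res <- data.frame(contig_id = character(0), pos = integer(0),
                    allele_a = character(0), allele_b = character(0),
                    n_alleles = integer(0), minor_early_only = logical(0),
                    stringsAsFactors = FALSE)
  for (l in lines) {
    res[[paste0("call_", l)]] <- character(0)
    res[[paste0("reads_", l)]] <- integer(0)
  }
  res
}

distToFeature <- function(p, starts, ends) {
  # ends exclusive; distance from column p to nearest feature base,
  # 0 when p lies inside a feature
  if (!length(starts)) return(Inf)
  d <- pmax(starts - p, p - (ends - 1L), 0L)
  min(d)
}

#' Apply the SNP selection-criteria ladder
#'
#' Annotates each candidate with its distance to the nearest
#' homopolymer run, indel column and contig end, and sets filter flags:
#' \code{not_biallelic}, \code{not_parent_polymorphic} (no configured
#' parent pair has opposite homozygous calls), \code{near_homopolymer},
#' \code{near_indel}, \code{near_contig_end}, and (when
#' \code{config$dropReadStartOnly}) \code{read_start_support}. A
#' candidate passes when its flag set is empty. All distance
#' comparisons are strict, per the \code{> 5} / \code{> 60} /
#' \code{> 60} bp criteria.
#'
#' @param candidates From \code{\link{detectVariants}}.
#' @param contigSeq The contig sequence (character or \code{DNAString}).
#' @param indelCols 0-based indel column positions, e.g. from
#'   \code{\link{indelColumns}}.
#' @param config A \code{\link{filterConfig}}.
#' @param runs Optional precomputed \code{\link{homopolymerRuns}} output.
#' @return The candidates with added columns \code{dist_homopolymer},
#'   \code{dist_indel}, \code{dist_contig_end}, \code{filter_flags}
#'   (semicolon-joined; \code{""} = pass) and logical \code{pass}.
#' @export
filterCandidates <- function(candidates, contigSeq, indelCols = integer(0),
                             config = filterConfig(), runs = NULL) {
  if (is.null(runs))
    runs <- homopolymerRuns(contigSeq, config$homopolymerMinLen)
  L <- nchar(as.character(contigSeq))
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$dist_homopolymer <- candidates$dist_indel <-
      candidates$dist_contig_end <- numeric(0)
    candidates$filter_flags <- character(0)
    candidates$pass <- logical(0)
    return(candidates)
  }
  lines <- sub("^call_", "", grep("^call_", names(candidates), value = TRUE))
  dh <- vapply(candidates$pos, distToFeature,
               0, starts = runs$start, ends = runs$start + runs$length)
  di <- vapply(candidates$pos, distToFeature,
               0, starts = indelCols, ends = indelCols + 1L)
  de <- pmin(candidates$pos, L - 1L - candidates$pos)
  flags <- vector("list", n)
  for (i in seq_len(n)) {
    f <- character(0)
    if (candidates$n_alleles[i] != 2L) f <- c(f, "not_biallelic")
    polym <- FALSE
    for (pp in config$parentPairs) {
      if (!all(paste0("call_", pp) %in% names(candidates))) next
      c1 <- candidates[[paste0("call_", pp[1L])]][i]
      c2 <- candidates[[paste0("call_", pp[2L])]][i]
      if (c1 %in% BASES && c2 %in% BASES && c1 != c2) polym <- TRUE
    }
    if (!polym) f <- c(f, "not_parent_polymorphic")
    if (dh[i] < config$minDistHomopolymer) f <- c(f, "near_homopolymer")
    if (di[i] < config$minDistIndel) f <- c(f, "near_indel")
    if (de[i] < config$minDistContigEnd) f <- c(f, "near_contig_end")
    if (config$dropReadStartOnly && isTRUE(candidates$minor_early_only[i]))
      f <- c(f, "read_start_support")
    flags[[i]] <- f
  }
  candidates$dist_homopolymer <- dh
  candidates$dist_indel <- di
  candidates$dist_contig_end <- de
  candidates$filter_flags <- vapply(flags, paste, "", collapse = ";")
  candidates$pass <- candidates$filter_flags == ""
  candidates
}

#' Flag candidates with conflicting within-line haplotype phase
#'
#' Automatable proxy for manual haplotype inspection: for every pair of
#' candidate columns on the same contig that share reads within one
#' line, the observed allele combinations are tallied. An inbred line
#' contributes at most two haplotypes, so three or more combinations
#' each supported by \code{minReads} reads indicate assembly of
#' paralogous copies; both candidates are flagged
#' \code{phase_conflict}.
#'
#' @param candidates Candidate \code{data.frame} (one contig).
#' @param alignments \code{GAlignments} (with \code{RG}, \code{seq}
#'   tags) or a SAM/BAM path for that contig.
#' @param lineOf Read-group to line map (named character vector).
#' @param minReads Reads per combination required to call it real
#'   (default 2).
#' @return The candidates with a logical \code{phase_conflict} column
#'   (and the flag appended to \code{filter_flags} where present).
#' @export
flagPhaseConflicts <- function(candidates, alignments, lineOf,
                               minReads = 2L) {
  candidates$phase_conflict <- rep(FALSE, nrow(candidates))
  if (nrow(candidates) < 2L) return(candidates)
  cid <- candidates$contig_id[1L]
  if (is.character(alignments))
    alignments <- readContigAlignments(alignments, cid)
  galn <- alignments
  mc <- S4Vectors::mcols(galn)
  lines <- unname(lineOf[as.character(mc$RG)])
  cig <- GenomicAlignments::cigar(galn)
  pos <- GenomicAlignments::start(galn)
  mops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = mops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = mops)
  alnIdx <- rep(seq_along(galn), S4Vectors::elementNROWS(refR))
  refU <- unlist(refR, use.names = FALSE)
  qryU <- unlist(qryR, use.names = FALSE)
  w <- IRanges::width(refU)
  refpos <- sequence(w, from = IRanges::start(refU)) - 1L   # 0-based
  qpos <- sequence(w, from = IRanges::start(qryU))
  rIdx <- rep(alnIdx, w)
  want <- refpos %in% candidates$pos
  if (!any(want)) return(candidates)
  seqc <- as.character(mc$seq)
  base <- substr(seqc[rIdx[want]], qpos[want], qpos[want])
  obs <- data.frame(read = rIdx[want], line = lines[rIdx[want]],
                    pos = refpos[want], base = base,
                    stringsAsFactors = FALSE)
  cp <- sort(unique(candidates$pos))
  for (l in unique(obs$line)) {
    ol <- obs[obs$line == l, , drop = FALSE]
    for (i in seq_along(cp)[-length(cp)]) {
      for (j in (i + 1L):length(cp)) {
        b1 <- ol[ol$pos == cp[i], c("read", "base")]
        b2 <- ol[ol$pos == cp[j], c("read", "base")]
        m <- merge(b1, b2, by = "read")
        if (nrow(m) < 2L * minReads) next
        combos <- table(paste(m$base.x, m$base.y))
        if (sum(combos >= minReads) >= 3L) {
          hit <- candidates$pos %in% cp[c(i, j)]
          candidates$phase_conflict[hit] <- TRUE
        }
      }
    }
  }
  if ("filter_flags" %in% names(candidates)) {
    add <- candidates$phase_conflict
    candidates$filter_flags[add] <- ifelse(
      candidates$filter_flags[add] == "", "phase_conflict",
      paste0(candidates$filter_flags[add], ";phase_conflict"))
    if ("pass" %in% names(candidates))
      candidates$pass <- candidates$filter_flags == ""
  }
  candidates
}

#' Probe-design context string for a passing SNP
#'
#' Returns \code{flank} bp of left context, the alleles in alphabetical
#' order as \code{"[A/G]"}, and \code{flank} bp of right context; total
#' length \code{2 * flank + 5} for single-base alleles. The default
#' flank of 60 bp matches the contig-end distance criterion, so every
#' passing candidate has sufficient context by construction.
#'
#' @param candidate One row of the candidate \code{data.frame}.
#' @param contigSeq The contig sequence.
#' @param flank Flank length in bp (default 60).
#' @return Character context string.
#' @export
probeContext <- function(candidate, contigSeq, flank = 60L) {
  s <- as.character(contigSeq)
  p <- candidate$pos                       # 0-based
  L <- nchar(s)
  if (p - flank < 0L || p + flank > L - 1L)
    stop("insufficient flanking sequence for probe context at position ",
         p, " (flank ", flank, ", contig length ", L, ")")
  al <- sort(c(candidate$allele_a, candidate$allele_b))
  paste0(substr(s, p - flank + 1L, p),
         "[", al[1L], "/", al[2L], "]",
         substr(s, p + 2L, p + 1L + flank))
}

#' Write SNP candidates as VCF 4.2
#'
#' REF is the contig base at the SNP column; ALT the other allele(s).
#' The FILTER column carries the flag names (\code{PASS} when empty);
#' INFO carries the three distances (\code{DH}, \code{DI}, \code{DE})
#' and the per-line calls (\code{LC}). Positions are written 1-based.
#'
#' @param candidates Filtered candidate \code{data.frame}.
#' @param contigs \code{\link{ContigSet}} holding the reference contigs.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeSnpVcf <- function(candidates, contigs, path) {
  seqs <- contigSeqs(contigs)
  lines <- sub("^call_", "", grep("^call_", names(candidates), value = TRUE))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=TranscriptMarkers",
           sprintf("##contig=<ID=%s,length=%d>", contigIds(contigs),
                   Biostrings::width(seqs)),
           "##INFO=<ID=DH,Number=1,Type=Integer,Description=\"Distance to nearest homopolymer run (bp)\">",
           "##INFO=<ID=DI,Number=1,Type=Integer,Description=\"Distance to nearest indel column (bp)\">",
           "##INFO=<ID=DE,Number=1,Type=Integer,Description=\"Distance to nearest contig end (bp)\">",
           "##INFO=<ID=LC,Number=.,Type=String,Description=\"Per-line calls line:call\">",
           "##FILTER=<ID=not_biallelic,Description=\"More or fewer than two supported alleles\">",
           "##FILTER=<ID=not_parent_polymorphic,Description=\"No parent pair with opposite homozygous calls\">",
           "##FILTER=<ID=near_homopolymer,Description=\"Distance to homopolymer run not > 5 bp\">",
           "##FILTER=<ID=near_indel,Description=\"Distance to indel column not > 60 bp\">",
           "##FILTER=<ID=near_contig_end,Description=\"Distance to contig end not > 60 bp\">",
           "##FILTER=<ID=read_start_support,Description=\"Minor allele supported only by read starts\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  recs <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cid <- candidates$contig_id[i]
    p <- candidates$pos[i]
    ref <- substr(as.character(seqs[[cid]]), p + 1L, p + 1L)
    al <- c(candidates$allele_a[i], candidates$allele_b[i])
    alt <- setdiff(al, ref)
    if (length(alt) == 0L) alt <- "."
    lc <- paste(vapply(lines, function(l)
      paste0(l, ":", candidates[[paste0("call_", l)]][i]), ""),
      collapse = ",")
    fl <- candidates$filter_flags[i]
    recs[i] <- paste(cid, p + 1L, paste0("snp", i), ref,
                     paste(alt, collapse = ","), ".",
                     if (fl == "") "PASS" else gsub(";", ";", fl),
                     sprintf("DH=%d;DI=%d;DE=%d;LC=%s",
                             as.integer(min(candidates$dist_homopolymer[i],
                                            .Machine$integer.max)),
                             as.integer(min(candidates$dist_indel[i],
                                            .Machine$integer.max)),
                             candidates$dist_contig_end[i], lc),
                     sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the probe-design table for passing SNPs
#'
#' @param candidates Filtered candidates (only \code{pass} rows used).
#' @param contigs \code{\link{ContigSet}}.
#' @param path Output TSV.
#' @param flank Context flank in bp (default 60).
#' @return \code{path}, invisibly.
#' @export
writeProbeTable <- function(candidates, contigs, path, flank = 60L) {
  seqs <- contigSeqs(contigs)
  ok <- candidates[candidates$pass, , drop = FALSE]
  ctx <- vapply(seq_len(nrow(ok)), function(i)
    probeContext(ok[i, ], seqs[[ok$contig_id[i]]], flank), "")
  out <- data.frame(snp_id = sprintf("snp%04d", seq_len(nrow(ok))),
                    contig_id = ok$contig_id,
                    position = ok$pos + 1L,
                    alleles = paste(ok$allele_a, ok$allele_b, sep = "/"),
                    context = ctx,
                    go_terms = "",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
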