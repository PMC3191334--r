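#' Read alignment-search hits in 12-column tabular format
#'
#' Standard tabular dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Extra columns
#' are tolerated and ignored; malformed rows raise an error naming the
#' line number.
#'
#' @param path TSV path.
#' @return \code{data.frame} with the 12 standard columns, plus
#'   \code{.line} (input line number) for traceability.
#' @export
readHitsTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(emptyHitsFrame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("malformed hit row at line ", which(nf < 12L)[1L],
         ": expected >= 12 tab-separated fields, got ",
         nf[which(nf < 12L)[1L]])
  mat <- t(vapply(parts, function(p) p[1:12], character(12L)))
  df <- suppressWarnings(data.frame(
    query_id = mat[, 1L], subject_id = mat[, 2L],
    percent_identity = as.numeric(mat[, 3L]),
    alignment_length = as.integer(mat[, 4L]),
    mismatch = as.integer(mat[, 5L]), gapopen = as.integer(mat[, 6L]),
    qstart = as.integer(mat[, 7L]), qend = as.integer(mat[, 8L]),
    sstart = as.integer(mat[, 9L]), send = as.integer(mat[, 10L]),
    e_value = as.numeric(mat[, 11L]), bit_score = as.numeric(mat[, 12L]),
    stringsAsFactors = FALSE))
  bad <- which(is.na(df$percent_identity) | is.na(df$alignment_length) |
                 is.na(df$e_value) | is.na(df$bit_score))
  if (length(bad))
    stop("malformed hit row at line ", bad[1L],
         ": non-numeric value in a numeric field")
  df$.line <- seq_len(nrow(df))
  df
}

emptyHitsFrame <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), e_value = numeric(0),
             bit_score = numeric(0), .line = integer(0),
             stringsAsFactors = FALSE)
}

#' Filter homology hits by identity, length and best-hit rule
#'
#' Keeps hits with \code{percent_identity >= minIdentity} (default 70)
#' and \code{alignment_length >= minLength} (default 30 bp), the
#' conservative cut-off used when counting homologs between
#' assemblies. With \code{bestHitOnly} one hit per query survives:
#' maximum bit score, ties broken by minimum e-value, then input
#' order. The operation is idempotent.
#'
#' @param hits \code{data.frame} from \code{\link{readHitsTable}}.
#' @param minIdentity Identity threshold in percent (default 70).
#' @param minLength Alignment-length threshold in bp (default 30).
#' @param bestHitOnly Keep only the best hit per query (default TRUE).
#' @return Filtered \code{data.frame}.
#' @export
filterHits <- function(hits, minIdentity = 70, minLength = 30L,
                       bestHitOnly = TRUE) {
  keep <- hits$percent_identity >= minIdentity &
    hits$alignment_length >= minLength
  res <- hits[keep, , drop = FALSE]
  if (bestHitOnly && nrow(res) > 1L) {
    ord <- order(res$query_id, -res$bit_score, res$e_value,
                 seq_len(nrow(res)))
    res <- res[ord, , drop = FALSE]
    res <- res[!duplicated(res$query_id), , drop = FALSE]
    res <- res[order(match(res$query_id, hits$query_id)), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Percentage of queries with a counted hit
#'
#' @param querySetSize Number of query sequences (>= 1).
#' @param survivingBestHits Number of queries with a surviving best hit.
#' @return Percentage in \[0, 100\].
#' @export
overlapPercentage <- function(querySetSize, survivingBestHits) {
  if (querySetSize < 1L) stop("querySetSize must be >= 1")
  if (survivingBestHits > querySetSize)
    stop("surviving hits cannot exceed the query set size")
  100 * survivingBestHits / querySetSize
}

#' Screen contigs for contamination
#'
#' A contig is discarded when it has a significant hit against a
#' contaminant database (e-value <= \code{maxEvalue}, default 1e-20)
#' whose query span covers at least \code{minContigFraction} (default
#' 10\%) of the contig length. The partition (kept, discarded) is
#' exhaustive and disjoint; contigs without hits are kept.
#'
#' @param contigs A \code{\link{ContigSet}}.
#' @param hits Hits of the contigs against contaminant databases
#'   (queries = contig ids).
#' @param maxEvalue Significance threshold (default 1e-20).
#' @param minContigFraction Minimum covered fraction (default 0.10).
#' @return List with \code{ContigSet}s \code{kept} and \code{discarded}.
#' @export
contaminationScreen <- function(contigs, hits, maxEvalue = 1e-20,
                                minContigFraction = 0.10) {
  ids <- contigIds(contigs)
  lens <- stats::setNames(Biostrings::width(contigSeqs(contigs)), ids)
  unknown <- setdiff(unique(hits$query_id), ids)
  if (length(unknown))
    stop("hit query id(s) do not resolve to contigs: ",
         paste(unknown, collapse = ", "))
  span <- abs(hits$qend - hits$qstart) + 1L
  sig <- hits$e_value <= maxEvalue &
    span >= minContigFraction * lens[hits$query_id]
  bad <- unique(hits$query_id[sig])
  keep <- !(ids %in% bad)
  subsetContigs <- function(sel) {
    new("ContigSet",
        sequences = contigSeqs(contigs)[sel],
        lineTags = lineTags(contigs)[sel],
        assemblerTags = assemblerTags(contigs)[sel])
  }
  list(kept = subsetContigs(keep), discarded = subsetContigs(!keep))
}

#' Sliding-window hit density along reference chromosomes
#'
#' Slides a window (default 0.5 Mb, shift 0.1 Mb) along each reference
#' chromosome and reports, per window: the number of hits whose
#' subject-span midpoint falls in the window (so each hit counts once
#' per window position), the percent bp coverage of the window by the
#' union of hit spans, the N fraction from the assembly-gap mask, and
#' the hit density extrapolated to hits per Mb. Windows whose N
#' fraction exceeds \code{nThreshold} (default 60\%) have all densities
#' forced to zero. Only full windows are placed
#' (\code{floor((L - window)/shift) + 1} per chromosome; one truncated
#' window when the chromosome is shorter than the window).
#'
#' @param hits Hits with subject coordinates on the reference
#'   (\code{subject_id}, \code{sstart}, \code{send}, 1-based inclusive).
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param nMask Optional \code{data.frame} of N intervals (columns
#'   \code{chrom}, \code{start}, \code{end}; 0-based half-open, BED
#'   convention), sorted and non-overlapping per chromosome.
#' @param window Window size in bp (default 5e5).
#' @param shift Window shift in bp (default 1e5); must be positive.
#' @param nThreshold Maximum tolerated N fraction (default 0.6).
#' @return \code{data.frame}: \code{chromosome_id}, \code{window_start}
#'   (0-based), \code{window_size}, \code{shift}, \code{hit_count},
#'   \code{bp_coverage_percent}, \code{n_fraction}, \code{density_per_mb}.
#' @export
windowDensity <- function(hits, chromLengths, nMask = NULL,
                          window = 5e5, shift = 1e5, nThreshold = 0.6) {
  if (shift <= 0) stop("shift must be positive")
  bad <- hits$send > chromLengths[hits$subject_id] |
    hits$sstart < 1L
  bad[is.na(bad)] <- TRUE
  if (nrow(hits) && any(bad))
    stop("hit subject coordinates outside chromosome bounds")
  out <- lapply(names(chromLengths), function(ch) {
    L <- chromLengths[[ch]]
    nw <- if (L < window) 1L else floor((L - window) / shift) + 1L
    starts <- (seq_len(nw) - 1L) * shift
    ends <- pmin(starts + window, L)
    hh <- hits[hits$subject_id == ch, , drop = FALSE]
    # 0-based half-open hit spans
    hs <- pmin(hh$sstart, hh$send) - 1L
    he <- pmax(hh$sstart, hh$send)
    mid <- (hs + he) / 2
    hitIR <- IRanges::IRanges(start = hs + 1L, end = he)
    hitUnion <- IRanges::reduce(hitIR)
    maskIR <- NULL
    if (!is.null(nMask)) {
      mm <- nMask[nMask$chrom == ch, , drop = FALSE]
      if (nrow(mm))
        maskIR <- IRanges::IRanges(start = mm$start + 1L, end = mm$end)
    }
    cnt <- integer(nw); cov <- numeric(nw); nf <- numeric(nw)
    for (k in seq_len(nw)) {
      a <- starts[k]; b <- ends[k]
      wlen <- b - a
      cnt[k] <- sum(mid >= a & mid < b)
      wIR <- IRanges::IRanges(start = a + 1L, end = b)
      covbp <- sum(IRanges::width(IRanges::intersect(hitUnion, wIR)))
      cov[k] <- 100 * covbp / wlen
      if (!is.null(maskIR))
        nf[k] <- sum(IRanges::width(IRanges::intersect(maskIR, wIR))) /
          wlen
    }
    masked <- nf > nThreshold
    cnt[masked] <- 0L
    cov[masked] <- 0
    data.frame(chromosome_id = ch, window_start = starts,
               window_size = window, shift = shift, hit_count = cnt,
               bp_coverage_percent = cov, n_fraction = nf,
               density_per_mb = cnt * (1e6 / window),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a window-density matrix for heatmap rendering
#'
#' One row per chromosome (track), one column per window position;
#' cells are \code{density_per_mb}. Ragged chromosomes are padded with
#' NA. Written as TSV.
#'
#' @param densities Output of \code{\link{windowDensity}}.
#' @param path Output TSV path.
#' @param value Column to tabulate (default \code{"density_per_mb"}).
#' @return The matrix, invisibly.
#' @export
exportDensityMatrix <- function(densities, path,
                                value = "density_per_mb") {
  chroms <- unique(densities$chromosome_id)
  ncols <- if (length(chroms))
    max(table(factor(densities$chromosome_id, levels = chroms))) else 0L
  m <- matrix(NA_real_, nrow = length(chroms), ncol = ncols,
              dimnames = list(chroms,
                              if (ncols) paste0("w", seq_len(ncols))))
  for (ch in chroms) {
    v <- densities[[value]][densities$chromosome_id == ch]
    m[ch, seq_along(v)] <- v
  }
  df <- data.frame(track = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- data.frame(track = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}
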