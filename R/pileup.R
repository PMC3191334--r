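#' @importFrom GenomicAlignments readGAlignments cigar
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace qwidth
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom IRanges IRanges
NULL

# Load alignments for one contig from a SAM (or BAM) file, keeping the
# read group tag and the read sequence.
readContigAlignments <- function(samPath, contigId) {
  bam <- samPath
  if (grepl("\\.sam$", samPath, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(samPath, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    tag = "RG", what = c("seq", "qname", "flag"))
  galn <- GenomicAlignments::readGAlignments(bam, param = param)
  galn[as.character(GenomicAlignments::seqnames(galn)) == contigId]
}

#' Build a per-line pileup over one contig
#'
#' Tallies aligned read evidence column by column, separately per inbred
#' line: reads are assigned to lines through their read group (RG) tag
#' and the \code{lineOf} map. Matched bases increment the base rows;
#' deletion evidence is attributed to every deleted column and insertion
#' evidence to the column left of the insertion point. Base evidence
#' from the first \code{readStartWindow} bases of a read (in original
#' read orientation) is additionally tallied in \code{earlyCounts},
#' since 454 sequencing errors concentrate at read starts.
#'
#' @param alignments Path to a SAM/BAM file, or a \code{GAlignments}
#'   object with \code{RG} and \code{seq} metadata columns.
#' @param contig A single-contig \code{\link{ContigSet}} or a list with
#'   elements \code{id} and \code{length}.
#' @param lineOf Named character vector mapping read-group ids to line
#'   ids.
#' @param readStartWindow Leading read bases counted as "early"
#'   (default 10).
#' @return A \code{\link{Pileup}} object (one 6 x L count matrix per
#'   line that has any evidence; lines in \code{lineOf} order).
#' @export
buildPileup <- function(alignments, contig, lineOf, readStartWindow = 10L) {
  if (is(contig, "ContigSet")) {
    stopifnot(length(contigSeqs(contig)) == 1L)
    cid <- contigIds(contig)
    L <- Biostrings::width(contigSeqs(contig))[1L]
  } else {
    cid <- contig$id
    L <- as.integer(contig$length)
  }
  if (is.character(alignments))
    alignments <- readContigAlignments(alignments, cid)
  galn <- alignments
  mc <- S4Vectors::mcols(galn)
  rg <- as.character(mc$RG)
  unknown <- setdiff(unique(rg), names(lineOf))
  if (length(unknown))
    stop("read group(s) not in line map: ", paste(unknown, collapse = ", "))
  lines <- unname(lineOf[rg])
  lineLevels <- unique(unname(lineOf))
  emptyCounts <- function(nr) {
    m <- matrix(0L, nr, L)
    rownames(m) <- c("A", "C", "G", "T", "del", "ins")[seq_len(nr)]
    m
  }
  counts <- lapply(lineLevels, function(l) emptyCounts(6L))
  early <- lapply(lineLevels, function(l) emptyCounts(4L))
  names(counts) <- names(early) <- lineLevels
  if (length(galn) == 0L)
    return(new("Pileup", contigId = cid, counts = counts,
               earlyCounts = early,
               readStartWindow = as.integer(readStartWindow)))
  cig <- GenomicAlignments::cigar(galn)
  pos <- GenomicAlignments::start(galn)
  seqc <- as.character(mc$seq)
  qlen <- GenomicAlignments::qwidth(galn)
  minus <- as.character(GenomicAlignments::strand(galn)) == "-"

  mops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = mops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = mops)
  nOps <- S4Vectors::elementNROWS(refR)
  alnIdx <- rep(seq_along(galn), nOps)
  refU <- unlist(refR, use.names = FALSE)
  qryU <- unlist(qryR, use.names = FALSE)
  w <- IRanges::width(refU)
  keep <- w > 0L
  refU <- refU[keep]; qryU <- qryU[keep]
  alnIdx <- alnIdx[keep]; w <- w[keep]
  refpos <- sequence(w, from = IRanges::start(refU))
  qpos <- sequence(w, from = IRanges::start(qryU))
  baseIdx <- rep(alnIdx, w)
  bases <- unlist(strsplit(substring(seqc[alnIdx], IRanges::start(qryU),
                                     IRanges::end(qryU)), ""),
                  use.names = FALSE)
  lineVec <- lines[baseIdx]
  # early = within readStartWindow of the original read start
  qlenVec <- qlen[baseIdx]
  isEarly <- ifelse(minus[baseIdx],
                    qpos > qlenVec - readStartWindow,
                    qpos <= readStartWindow)
  code <- match(bases, c("A", "C", "G", "T"))
  ok <- !is.na(code) & refpos >= 1L & refpos <= L
  for (l in lineLevels) {
    sel <- ok & lineVec == l
    if (!any(sel)) next
    enc <- (refpos[sel] - 1L) * 4L + code[sel]
    tab <- tabulate(enc, nbins = 4L * L)
    counts[[l]][1:4, ] <- counts[[l]][1:4, ] + matrix(tab, nrow = 4L)
    sel2 <- sel & isEarly
    if (any(sel2)) {
      enc2 <- (refpos[sel2] - 1L) * 4L + code[sel2]
      early[[l]] <- early[[l]] +
        matrix(tabulate(enc2, nbins = 4L * L), nrow = 4L)
    }
  }
  # deletions: every deleted reference column
  delR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "D")
  dIdx <- rep(seq_along(galn), S4Vectors::elementNROWS(delR))
  delU <- unlist(delR, use.names = FALSE)
  if (length(delU)) {
    dw <- IRanges::width(delU)
    dpos <- sequence(dw, from = IRanges::start(delU))
    dline <- lines[rep(dIdx, dw)]
    for (l in lineLevels) {
      sel <- dline == l & dpos >= 1L & dpos <= L
      if (any(sel))
        counts[[l]]["del", ] <- counts[[l]]["del", ] +
          tabulate(dpos[sel], nbins = L)
    }
  }
  # insertions: zero-width range on reference space; attribute to the
  # column left of the insertion point
  insR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "I")
  iIdx <- rep(seq_along(galn), S4Vectors::elementNROWS(insR))
  insU <- unlist(insR, use.names = FALSE)
  if (length(insU)) {
    ipos <- IRanges::start(insU) - 1L
    iline <- lines[iIdx]
    for (l in lineLevels) {
      sel <- iline == l & ipos >= 1L & ipos <= L
      if (any(sel))
        counts[[l]]["ins", ] <- counts[[l]]["ins", ] +
          tabulate(ipos[sel], nbins = L)
    }
  }
  new("Pileup", contigId = cid, counts = counts, earlyCounts = early,
      readStartWindow = as.integer(readStartWindow))
}

#' Per-column total depth of a pileup
#'
#' @param pileup A \code{\link{Pileup}}.
#' @param what \code{"base"} (A/C/G/T evidence only, the default) or
#'   \code{"all"} (including del/ins evidence).
#' @return Integer vector of length contig-length.
#' @export
pileupDepth <- function(pileup, what = c("base", "all")) {
  what <- match.arg(what)
  rows <- if (what == "base") 1:4 else 1:6
  m <- Reduce(`+`, lapply(pileupCounts(pileup),
                          function(x) colSums(x[rows, , drop = FALSE])))
  as.integer(m)
}

#' Columns with indel evidence
#'
#' A column counts as an indel column when deletion evidence spans it or
#' insertion evidence is anchored at it by at least \code{minReads}
#' reads (summed over lines).
#'
#' @param pileup A \code{\link{Pileup}}.
#' @param minReads Minimum supporting reads (default 2).
#' @return Sorted integer vector of 0-based column positions.
#' @export
indelColumns <- function(pileup, minReads = 2L) {
  tot <- Reduce(`+`, lapply(pileupCounts(pileup), function(x)
    colSums(x[c("del", "ins"), , drop = FALSE])))
  which(tot >= minReads) - 1L
}
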