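#' Discover SNPs across a multi-line alignment
#'
#' End-to-end candidate discovery: builds per-line pileups for every
#' contig from the alignment file, detects bi-allelic candidates,
#' annotates the selection-criteria distances and filter flags, and
#' reports the funnel (candidates at each stage). This is the
#' programmatic equivalent of the \code{snp-discover} command.
#'
#' @param alignments SAM/BAM path, or a \code{GAlignments} object with
#'   \code{RG} and \code{seq} metadata.
#' @param contigs A \code{\link{ContigSet}}.
#' @param lineOf Named character vector mapping read groups to lines;
#'   defaults to identity over the read groups found.
#' @param config A \code{\link{filterConfig}}.
#' @param phaseCheck Also run \code{\link{flagPhaseConflicts}} per
#'   contig (default FALSE).
#' @return List: \code{candidates} (all contigs, with flags and
#'   \code{pass}), \code{funnel} (named counts: detected, per-flag
#'   failures, passing).
#' @export
discoverSnps <- function(alignments, contigs, lineOf = NULL,
                         config = filterConfig(), phaseCheck = FALSE) {
  if (is.character(alignments)) {
    path <- alignments
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      bam <- Rsamtools::asBam(path, destination = tempfile(),
                              overwrite = TRUE, indexDestination = TRUE)
    param <- Rsamtools::ScanBamParam(tag = "RG",
                                     what = c("seq", "qname", "flag"))
    alignments <- GenomicAlignments::readGAlignments(bam, param = param)
  }
  rg <- as.character(S4Vectors::mcols(alignments)$RG)
  if (is.null(lineOf)) {
    u <- sort(unique(rg))
    lineOf <- stats::setNames(u, u)
  }
  seqs <- contigSeqs(contigs)
  chrom <- as.character(GenomicAlignments::seqnames(alignments))
  perContig <- lapply(contigIds(contigs), function(id) {
    galn <- alignments[chrom == id]
    if (length(galn) == 0L) return(NULL)
    pu <- buildPileup(galn, list(id = id,
                                 length = Biostrings::width(seqs[id])),
                      lineOf)
    cand <- detectVariants(pu, config)
    if (nrow(cand) == 0L) return(NULL)
    cand <- filterCandidates(cand, as.character(seqs[[id]]),
                             indelCols = indelColumns(pu),
                             config = config)
    if (phaseCheck)
      cand <- flagPhaseConflicts(cand, galn, lineOf)
    cand
  })
  perContig <- perContig[!vapply(perContig, is.null, TRUE)]
  cand <- if (length(perContig)) do.call(rbind, perContig) else
    filterCandidates(emptyCandidateFrame(unname(lineOf)), "A",
                     config = config)
  flags <- c("not_biallelic", "not_parent_polymorphic",
             "near_homopolymer", "near_indel", "near_contig_end")
  funnel <- c(detected = nrow(cand),
              stats::setNames(vapply(flags, function(f)
                sum(grepl(f, cand$filter_flags, fixed = TRUE)), 0L),
                paste0("flag_", flags)),
              passing = sum(cand$pass))
  list(candidates = cand, funnel = funnel)
}
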