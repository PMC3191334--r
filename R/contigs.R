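#' Read contigs from FASTA with optional provenance
#'
#' Reads a FASTA file into a \code{\link{ContigSet}}. Sequences are
#' uppercased and U is mapped to T; characters outside \{A,C,G,T,N\} are
#' rejected. Provenance (contributing lines and assemblers) is taken from
#' \code{key=value} tokens in the description line
#' (\code{lines=Lo7,Lo225 assemblers=CLC,Mira}) or, preferably, from a
#' sidecar TSV with columns \code{contig_id}, \code{line_tag},
#' \code{assembler_tag}. When neither source mentions a contig,
#' \code{defaultLine} is used so the line-tag invariant holds.
#'
#' @param path FASTA file path.
#' @param provenance Optional path to the sidecar provenance TSV.
#' @param defaultLine Line tag applied to contigs without provenance
#'   (default \code{"unknown"}).
#' @return A \code{ContigSet}. An empty FASTA yields an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' readContigs(fa)
#' @export
readContigs <- function(path, provenance = NULL, defaultLine = "unknown") {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L)
    return(ContigSet(Biostrings::DNAStringSet(), lineTags = list()))
  # split id from description; keep first token as id
  full <- names(seqs)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  chars <- chartr("uU", "tT", toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    badline <- fastaRecordLine(path, which(bad)[1L])
    stop("invalid sequence character in record '", ids[which(bad)[1L]],
         "' (near line ", badline, "); allowed alphabet is {A,C,G,T,N}")
  }
  lt <- parseTagField(desc, "lines")
  at <- parseTagField(desc, "assemblers")
  if (!is.null(provenance)) {
    pv <- utils::read.delim(provenance, stringsAsFactors = FALSE)
    need <- c("contig_id", "line_tag", "assembler_tag")
    if (!all(need %in% names(pv)))
      stop("provenance TSV needs columns: ", paste(need, collapse = ", "))
    lt <- lapply(ids, function(i)
      unique(pv$line_tag[pv$contig_id == i & !is.na(pv$line_tag) &
                           pv$line_tag != ""]))
    at <- lapply(ids, function(i)
      unique(pv$assembler_tag[pv$contig_id == i & !is.na(pv$assembler_tag) &
                                pv$assembler_tag != ""]))
  }
  lt <- lapply(lt, function(x) if (length(x)) x else defaultLine)
  dna <- Biostrings::DNAStringSet(chars)
  names(dna) <- ids
  ContigSet(dna, lineTags = lt, assemblerTags = at)
}

# line number of the header of the i-th FASTA record (for error messages)
fastaRecordLine <- function(path, i) {
  hdr <- grep("^>", readLines(path, warn = FALSE))
  if (i <= length(hdr)) hdr[i] else NA_integer_
}

parseTagField <- function(desc, key) {
  pat <- paste0("(?:^|\\s)", key, "=([^\\s]+)")
  lapply(desc, function(d) {
    m <- regmatches(d, regexec(pat, d, perl = TRUE))[[1L]]
    if (length(m) < 2L) character(0) else strsplit(m[2L], ",")[[1L]]
  })
}

#' Write a ContigSet to FASTA (plus provenance sidecar)
#'
#' Writes normalised sequences; provenance goes to
#' \code{paste0(path, ".provenance.tsv")} unless \code{provenance=FALSE}.
#' \code{readContigs(writeContigs(x))} reproduces \code{x}.
#'
#' @param x A \code{ContigSet}.
#' @param path Output FASTA path.
#' @param provenance Logical: also write the sidecar TSV.
#' @return \code{path}, invisibly.
#' @export
writeContigs <- function(x, path, provenance = TRUE) {
  Biostrings::writeXStringSet(contigSeqs(x), path, width = 70L)
  if (provenance) {
    ids <- contigIds(x)
    lt <- lineTags(x)
    at <- assemblerTags(x)
    rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
      l <- lt[[i]]
      a <- at[[i]]
      n <- max(length(l), length(a), 1L)
      data.frame(contig_id = ids[i],
                 line_tag = rep_len(if (length(l)) l else NA_character_, n),
                 assembler_tag = rep_len(if (length(a)) a else
                   NA_character_, n),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, paste0(path, ".provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Find maximal homopolymer runs
#'
#' Scans a DNA sequence for maximal runs of a single base of at least
#' \code{minLen} bp. Homopolymer runs are the dominant 454 pyrosequencing
#' error mode, and SNP candidates are later required to lie more than a
#' configurable distance away from any run. N is never part of a run and
#' breaks runs.
#'
#' @param sequence DNA string (character or \code{DNAString}) over
#'   \{A,C,G,T,N\}.
#' @param minLen Minimum run length in bp (>= 2); default 4, the length at
#'   which 454 homopolymer miscalls become common.
#' @return \code{data.frame} with columns \code{base}, \code{start}
#'   (0-based), \code{length}, sorted by start.
#' @examples
#' homopolymerRuns("GGAAAAAG")
#' @export
homopolymerRuns <- function(sequence, minLen = 4L) {
  minLen <- as.integer(minLen)
  if (is.na(minLen) || minLen < 2L)
    stop("minLen must be an integer >= 2")
  s <- toupper(as.character(sequence))
  empty <- data.frame(base = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (nchar(s) == 0L) return(empty)
  if (grepl("[^ACGTN]", s))
    stop("sequence restricted to {A,C,G,T,N}")
  r <- rle(strsplit(s, "")[[1L]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based starts
  keep <- r$lengths >= minLen & r$values != "N"
  if (!any(keep)) return(empty)
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Classify contigs by assembler support
#'
#' A contig is \code{"accepted"} when its constituents include first-order
#' contigs from every required assembler, the agreement rule used to keep
#' only consensus sequences unlikely to be artefacts of a single assembly
#' algorithm.
#'
#' @param x A \code{ContigSet}.
#' @param requiredAssemblers Non-empty character vector, e.g.
#'   \code{c("CLC", "Mira", "Newbler")}.
#' @return Factor (levels \code{accepted}, \code{rejected}) named by
#'   contig id.
#' @export
classifyAssemblerSupport <- function(x, requiredAssemblers) {
  if (length(requiredAssemblers) == 0L)
    stop("requiredAssemblers must be non-empty")
  ok <- vapply(assemblerTags(x), function(tags)
    all(requiredAssemblers %in% tags), logical(1))
  structure(factor(ifelse(ok, "accepted", "rejected"),
                   levels = c("accepted", "rejected")),
            names = contigIds(x))
}

#' Classify contigs by line support
#'
#' Contigs supported by constituents from two or more inbred lines are
#' \code{"multi-line"}; those with evidence from exactly one line are
#' \code{"single-line"}. The two classes partition any contig set.
#'
#' @param x A \code{ContigSet}.
#' @return Factor (levels \code{multi-line}, \code{single-line}) named by
#'   contig id.
#' @export
classifyLineSupport <- function(x) {
  n <- vapply(lineTags(x), function(t) length(unique(t)), 1L)
  structure(factor(ifelse(n >= 2L, "multi-line", "single-line"),
                   levels = c("multi-line", "single-line")),
            names = contigIds(x))
}
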