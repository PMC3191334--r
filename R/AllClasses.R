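#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' ContigSet: assembled consensus sequences with line/assembler provenance
#'
#' A \code{ContigSet} holds the consensus contigs of a (multi-line)
#' transcriptome assembly together with the provenance of their
#' constituents: which inbred lines contributed reads, and which assemblers
#' contributed first-order contigs. Provenance drives the two
#' classification rules used when building a high-confidence assembly:
#' contigs are only trusted when all required assemblers agree, and contigs
#' are partitioned into multi-line (>= 2 lines) and single-line classes.
#'
#' @slot sequences A \code{\link[Biostrings]{DNAStringSet}} with unique,
#'   non-empty names; alphabet restricted to A, C, G, T, N.
#' @slot lineTags Named \code{list} (parallel to \code{sequences}) of
#'   character vectors: the inbred lines contributing constituents.
#' @slot assemblerTags Named \code{list} of character vectors: assemblers
#'   contributing first-order constituents (may be empty vectors when
#'   unknown).
#'
#' @seealso \code{\link{readContigs}}, \code{\link{classifyLineSupport}},
#'   \code{\link{classifyAssemblerSupport}}
#' @export
setClass("ContigSet",
  representation(
    sequences = "DNAStringSet",
    lineTags = "list",
    assemblerTags = "list"
  )
)

setValidity("ContigSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (length(object@sequences) > 0L) {
    if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
      msg <- c(msg, "all contigs must be named")
    if (anyDuplicated(ids))
      msg <- c(msg, "contig ids must be unique")
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "contig sequences must be non-empty")
    bad <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    if (any(bad[, "other"] > 0L))
      msg <- c(msg, "sequences restricted to {A,C,G,T,N}")
  }
  if (length(object@lineTags) != length(object@sequences) ||
      length(object@assemblerTags) != length(object@sequences))
    msg <- c(msg, "provenance lists must parallel the sequences")
  if (length(object@lineTags) &&
      any(vapply(object@lineTags, length, 1L) == 0L))
    msg <- c(msg, "every contig needs at least one line tag")
  if (length(msg)) msg else TRUE
})

#' Pileup: per-contig, per-line nucleotide and indel evidence
#'
#' Column-wise tallies of aligned read evidence over one contig, kept
#' separately per inbred line (read group). For every line two integer
#' matrices of dimension 6 x contig-length are stored: rows A, C, G, T,
#' del, ins. \code{del} counts reads whose deletion spans the column;
#' \code{ins} counts reads with an insertion immediately right of the
#' column. The parallel \code{earlyCounts} matrices tally only base
#' evidence arising from the first few bases of a read, where 454
#' pyrosequencing errors concentrate; they feed an optional screening
#' proxy during candidate filtering.
#'
#' @slot contigId Contig identifier.
#' @slot counts Named list (one element per line) of 6 x L integer
#'   matrices with rownames A,C,G,T,del,ins.
#' @slot earlyCounts Named list of 4 x L integer matrices (rows A,C,G,T)
#'   restricted to read-start evidence.
#' @slot readStartWindow Integer: number of leading read bases counted as
#'   "early" (default 10).
#' @export
setClass("Pileup",
  representation(
    contigId = "character",
    counts = "list",
    earlyCounts = "list",
    readStartWindow = "integer"
  )
)

setValidity("Pileup", function(object) {
  msg <- character()
  if (length(object@contigId) != 1L)
    msg <- c(msg, "contigId must be a single string")
  L <- if (length(object@counts)) ncol(object@counts[[1L]]) else 0L
  for (m in object@counts) {
    if (!is.matrix(m) || nrow(m) != 6L || ncol(m) != L)
      msg <- c(msg, "counts must be 6 x L matrices of equal width")
    else if (any(m < 0L))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' GenotypeCalls: lines x SNPs genotype-call matrix with line metadata
#'
#' Stores AA/AB/BB calls (NA = missing) from a genotyping array, one row
#' per inbred line and one column per SNP assay, plus optional per-line
#' metadata: heterotic pool membership (\code{"seed"}, \code{"pollen"},
#' \code{"other"}) and selfing-generation label (e.g. \code{"F7"} or
#' \code{"F6:9"}).
#'
#' @slot calls Character matrix with dimnames; values in
#'   \{AA, AB, BB, NA\}.
#' @slot lineData \code{\link[S4Vectors]{DataFrame}} with one row per line;
#'   recognised columns: \code{pool}, \code{generation}.
#' @export
setClass("GenotypeCalls",
  representation(
    calls = "matrix",
    lineData = "DataFrame"
  )
)

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  cl <- object@calls
  if (!is.character(cl))
    msg <- c(msg, "calls must be a character matrix")
  else {
    ok <- cl %in% c("AA", "AB", "BB") | is.na(cl)
    if (!all(ok))
      msg <- c(msg, "calls restricted to {AA, AB, BB, NA}")
  }
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    msg <- c(msg, "calls must carry line ids (rownames) and snp ids (colnames)")
  if (nrow(object@lineData) != nrow(cl))
    msg <- c(msg, "lineData must have one row per line")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ContigSet", function(object) {
  n <- length(object@sequences)
  nl <- length(unique(unlist(object@lineTags)))
  cat(sprintf("ContigSet with %d contig%s from %d line%s\n",
              n, if (n == 1L) "" else "s", nl, if (nl == 1L) "" else "s"))
  if (n > 0L) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  widths: %d..%d bp (median %d)\n",
                min(w), max(w), as.integer(stats::median(w))))
  }
})

setMethod("show", "Pileup", function(object) {
  L <- if (length(object@counts)) ncol(object@counts[[1L]]) else 0L
  cat(sprintf("Pileup over contig '%s': %d columns, lines: %s\n",
              object@contigId, L,
              paste(names(object@counts), collapse = ", ")))
})

setMethod("show", "GenotypeCalls", function(object) {
  cat(sprintf("GenotypeCalls: %d lines x %d SNPs (%.1f%% missing)\n",
              nrow(object@calls), ncol(object@calls),
              100 * mean(is.na(object@calls))))
})

## ---- accessors ----------------------------------------------------------

#' @rdname ContigSet-accessors
#' @param x A \code{ContigSet}, \code{Pileup} or \code{GenotypeCalls}.
#' @return \code{contigIds}: character vector of contig identifiers.
#' @export
contigIds <- function(x) names(x@sequences)

#' Accessors for the core classes
#'
#' @name ContigSet-accessors
#' @param x Object.
#' @return \code{contigSeqs}: the \code{DNAStringSet};
#'   \code{lineTags}/\code{assemblerTags}: named lists of character
#'   vectors; \code{genotypeMatrix}: the character call matrix;
#'   \code{lineInfo}: the per-line \code{DataFrame}.
NULL

#' @rdname ContigSet-accessors
#' @export
contigSeqs <- function(x) x@sequences

#' @rdname ContigSet-accessors
#' @export
lineTags <- function(x) x@lineTags

#' @rdname ContigSet-accessors
#' @export
assemblerTags <- function(x) x@assemblerTags

#' @rdname ContigSet-accessors
#' @export
genotypeMatrix <- function(x) x@calls

#' @rdname ContigSet-accessors
#' @export
lineInfo <- function(x) x@lineData

#' @rdname ContigSet-accessors
#' @export
pileupCounts <- function(x) x@counts

#' Construct a ContigSet
#'
#' @param sequences A \code{DNAStringSet} or named character vector of DNA
#'   sequences (U is mapped to T, case normalised to upper).
#' @param lineTags Named list of character vectors or a single character
#'   vector recycled to all contigs.
#' @param assemblerTags As \code{lineTags}; may be omitted (empty).
#' @return A validated \code{ContigSet}.
#' @examples
#' cs <- ContigSet(c(c1 = "ACGTACGT"), lineTags = "Lo7")
#' contigIds(cs)
#' @export
ContigSet <- function(sequences, lineTags, assemblerTags = NULL) {
  if (is.character(sequences)) {
    sequences <- chartr("uU", "tT", sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  n <- length(sequences)
  norm_tags <- function(tags, default) {
    if (is.null(tags)) tags <- default
    if (is.character(tags)) tags <- rep(list(tags), n)
    if (length(tags) != n)
      stop("provenance must have one entry per contig")
    names(tags) <- names(sequences)
    tags
  }
  new("ContigSet",
      sequences = sequences,
      lineTags = norm_tags(lineTags, NULL),
      assemblerTags = norm_tags(assemblerTags, character(0)))
}

#' Construct a GenotypeCalls object
#'
#' @param calls Character matrix of AA/AB/BB/NA with line rownames and SNP
#'   colnames.
#' @param lineData Optional \code{data.frame}/\code{DataFrame} of per-line
#'   metadata (columns \code{pool}, \code{generation}).
#' @return A validated \code{GenotypeCalls}.
#' @examples
#' m <- matrix(c("AA", "AB", "BB", "AA"), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' GenotypeCalls(m)
#' @export
GenotypeCalls <- function(calls, lineData = NULL) {
  if (is.null(lineData))
    lineData <- S4Vectors::DataFrame(row.names = rownames(calls))
  else {
    lineData <- S4Vectors::DataFrame(lineData)
    if (!is.null(lineData$line_id)) {
      rownames(lineData) <- lineData$line_id
      lineData$line_id <- NULL
    }
    lineData <- lineData[rownames(calls), , drop = FALSE]
  }
  new("GenotypeCalls", calls = calls, lineData = lineData)
}
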