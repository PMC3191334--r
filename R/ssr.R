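#' Canonical form of an SSR unit
#'
#' The canonical unit is the lexicographically smallest string among all
#' rotations of the unit and all rotations of its reverse complement, so
#' the same locus reported from either strand or at a different phase
#' compares equal.
#'
#' @param unit Character vector of motif units over \{A,C,G,T\}.
#' @return Character vector of canonical units.
#' @examples
#' canonicalUnit(c("AC", "CA", "GT", "TG"))  # all "AC"
#' @export
canonicalUnit <- function(unit) {
  vapply(unit, function(u) {
    u <- toupper(u)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(u)))
    rots <- function(x) {
      k <- nchar(x)
      vapply(seq_len(k), function(i)
        paste0(substr(x, i, k), substr(x, 1, i - 1L)), "")
    }
    min(c(rots(u), rots(rc)))
  }, "", USE.NAMES = FALSE)
}

primitiveUnit <- function(u) {
  k <- nchar(u)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(u, 1L, d), k %/% d) == u)
      return(FALSE)
  }
  TRUE
}

#' Default minimum repeat counts per unit length
#'
#' Minimum number of tandem repeats, indexed by unit length 1-6, for a
#' perfect SSR to be reported: 10 for mononucleotide, 6 for
#' dinucleotide, 5 for tri- to hexanucleotide motifs. These mirror the
#' commonly distributed default parameter file of SSR mining tools.
#'
#' @return Named integer vector of length 6.
#' @export
defaultMinRepeats <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

#' Find perfect SSR motifs in one sequence
#'
#' Reports all maximal perfect simple sequence repeats with unit length
#' 1-6 bp meeting the per-unit-length minimum repeat count. Units are
#' primitive (a span explainable by two unit lengths is reported at the
#' shortest primitive unit), runs never include N, and each maximal
#' repeat region is anchored at its leftmost phase so every locus is
#' reported exactly once. Mononucleotide motifs are detected here and
#' removed downstream by \code{\link{dropMononucleotide}}, monomer runs
#' being the most frequent 454 sequencing error.
#'
#' @param sequence DNA string (character or \code{DNAString}).
#' @param minRepeats Named integer vector indexed by unit length
#'   \code{"1"}..\code{"6"}; see \code{\link{defaultMinRepeats}}.
#' @param contigId Identifier recorded in the output (default "").
#' @return \code{data.frame}: \code{contig_id}, \code{start}, \code{end}
#'   (0-based half-open), \code{unit}, \code{repeat_count}, \code{klass}
#'   (\code{"perfect"}), \code{canonical_unit}; sorted by start then unit
#'   length.
#' @examples
#' findSSRs("ACACACACACAC")       # (AC) x 6
#' @export
findSSRs <- function(sequence, minRepeats = defaultMinRepeats(),
                     contigId = "") {
  if (!all(as.character(1:6) %in% names(minRepeats)))
    stop("minRepeats must be defined for unit lengths 1..6")
  s <- toupper(as.character(sequence))
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  out <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    a <- x[seq_len(n - k)]
    b <- x[seq_len(n - k) + k]
    m <- a == b & a != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L      # 1-based index into m
    idx <- which(r$values)
    for (j in idx) {
      L <- r$lengths[j]
      count <- (L + k) %/% k
      if (count < minRepeats[[as.character(k)]]) next
      i <- starts[j]                     # anchor, 1-based seq position
      unit <- paste(x[i:(i + k - 1L)], collapse = "")
      if (!primitiveUnit(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contigId, start = i - 1L, end = i - 1L + k * count,
        unit = unit, repeat_count = count, klass = "perfect",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(emptySSRFrame())
  res <- do.call(rbind, out)
  res <- res[order(res$start, nchar(res$unit)), , drop = FALSE]
  res$canonical_unit <- canonicalUnit(res$unit)
  rownames(res) <- NULL
  res
}

emptySSRFrame <- function() {
  data.frame(contig_id = character(0), start = integer(0),
             end = integer(0), unit = character(0),
             repeat_count = integer(0), klass = character(0),
             canonical_unit = character(0), stringsAsFactors = FALSE)
}

#' Drop mononucleotide motifs
#'
#' Removes unit-length-1 SSRs; monomer runs are the most frequent
#' sequencing error in 454 pyrosequencing data and are not used as
#' markers. All other motifs are preserved in order.
#'
#' @param motifs SSR \code{data.frame} from \code{\link{findSSRs}}.
#' @return The filtered \code{data.frame}.
#' @export
dropMononucleotide <- function(motifs) {
  keep <- nchar(motifs$unit) > 1L | motifs$klass == "mixed"
  res <- motifs[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge close SSRs into mixed motifs
#'
#' Two SSR motifs on the same contig separated by less than \code{maxGap}
#' bp (default 100) are merged into one \code{klass = "mixed"} record
#' spanning from the first start to the last end; chains are transitive.
#' Singleton motifs stay perfect. Merging is idempotent because every
#' inter-record gap in the output is at least \code{maxGap}.
#'
#' @param motifs SSR \code{data.frame} on one contig, sorted by start.
#' @param maxGap Gap threshold in bp (strictly-less-than rule).
#' @return \code{data.frame} of perfect and mixed records. For mixed
#'   records \code{unit} is the \code{"+"}-joined member units and
#'   \code{repeat_count} is \code{NA}.
#' @export
mergeMixed <- function(motifs, maxGap = 100L) {
  if (nrow(motifs) < 2L) return(motifs)
  if (length(unique(motifs$contig_id)) > 1L)
    stop("mergeMixed expects motifs from a single contig")
  if (is.unsorted(motifs$start))
    stop("motifs must be sorted by start")
  gap <- motifs$start[-1L] - motifs$end[-nrow(motifs)]
  grp <- cumsum(c(1L, as.integer(gap >= maxGap)))
  pieces <- lapply(split(seq_len(nrow(motifs)), grp), function(ix) {
    if (length(ix) == 1L) return(motifs[ix, , drop = FALSE])
    mm <- motifs[ix, , drop = FALSE]
    data.frame(contig_id = mm$contig_id[1L],
               start = mm$start[1L], end = mm$end[nrow(mm)],
               unit = paste(mm$unit, collapse = "+"),
               repeat_count = NA_integer_, klass = "mixed",
               canonical_unit = paste(sort(canonicalUnit(
                 unlist(strsplit(mm$unit, "+", fixed = TRUE)))),
                 collapse = "+"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Build a per-line SSR dataset with flanking context
#'
#' Runs \code{\link{findSSRs}} over every contig of a line-specific
#' assembly, drops mononucleotide motifs, merges mixed motifs, and
#' attaches up to \code{flank} bp of sequence context on each side for
#' redundancy cross-matching and downstream primer design.
#'
#' @param contigs A \code{\link{ContigSet}} (one line-specific assembly).
#' @param lineId Line identifier recorded on every motif.
#' @param flank Flank length in bp (default 50).
#' @param minRepeats See \code{\link{findSSRs}}.
#' @param maxGap See \code{\link{mergeMixed}}.
#' @return \code{data.frame} with the SSR columns plus \code{line_id},
#'   \code{left_flank}, \code{right_flank}; sorted by
#'   (\code{contig_id}, \code{start}).
#' @export
ssrDataset <- function(contigs, lineId, flank = 50L,
                       minRepeats = defaultMinRepeats(), maxGap = 100L) {
  seqs <- contigSeqs(contigs)
  per <- lapply(contigIds(contigs), function(id) {
    s <- as.character(seqs[[id]])
    m <- findSSRs(s, minRepeats, contigId = id)
    m <- dropMononucleotide(m)
    if (nrow(m) > 1L) m <- mergeMixed(m, maxGap)
    if (nrow(m) == 0L) return(NULL)
    m$left_flank <- substr(rep(s, nrow(m)),
                           pmax(1L, m$start - flank + 1L), m$start)
    m$right_flank <- substr(rep(s, nrow(m)), m$end + 1L,
                            pmin(nchar(s), m$end + flank))
    m
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (!length(per)) {
    res <- emptySSRFrame()
    res$left_flank <- res$right_flank <- character(0)
  } else {
    res <- do.call(rbind, per)
    res <- res[order(res$contig_id, res$start), , drop = FALSE]
  }
  res$line_id <- rep(lineId, nrow(res))
  rownames(res) <- NULL
  res
}

# best ungapped sliding identity between two flank strings;
# returns max over shifts of (matches / overlap) for overlaps >= minOverlap
flankIdentity <- function(a, b, minOverlap = 30L, maxShift = 10L) {
  xa <- strsplit(toupper(a), "")[[1L]]
  xb <- strsplit(toupper(b), "")[[1L]]
  na <- length(xa); nb <- length(xb)
  best <- 0
  for (sh in -maxShift:maxShift) {
    ia <- max(1L, 1L + sh); ib <- max(1L, 1L - sh)
    ov <- min(na - ia, nb - ib) + 1L
    if (ov < minOverlap) next
    aa <- xa[ia:(ia + ov - 1L)]
    bb <- xb[ib:(ib + ov - 1L)]
    id <- sum(aa == bb) / ov
    if (id > best) best <- id
  }
  best
}

#' Cross-match SSR datasets into a non-redundant set
#'
#' Combines per-line SSR datasets into one non-redundant dataset. Two
#' motifs from different lines are redundant when their canonical units
#' match and the flanking context agrees on either side at >=
#' \code{minIdentity} over >= \code{minOverlap} aligned bp (ungapped
#' sliding comparison). Redundant groups keep the copy from
#' \code{referenceLine} when present (otherwise the first member) and
#' record all member lines.
#'
#' @param datasets List of \code{\link{ssrDataset}} outputs.
#' @param referenceLine Line id whose copy is retained for redundant
#'   groups; must occur among the datasets.
#' @param minIdentity Flank identity threshold (default 0.9).
#' @param minOverlap Minimum aligned flank overlap in bp (default 30).
#' @return Non-redundant \code{data.frame} sorted by
#'   (\code{contig_id}, \code{start}) with a \code{member_lines} column.
#' @export
crossmatchNonredundant <- function(datasets, referenceLine,
                                   minIdentity = 0.9, minOverlap = 30L) {
  if (!length(datasets)) stop("need at least one dataset")
  all <- do.call(rbind, datasets)
  if (!referenceLine %in% all$line_id)
    stop("reference line '", referenceLine, "' absent from datasets")
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (cu in unique(all$canonical_unit)) {
    ix <- which(all$canonical_unit == cu)
    if (length(ix) < 2L) next
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in (a + 1L):length(ix)) {
        i <- ix[a]; j <- ix[b]
        if (all$line_id[i] == all$line_id[j]) next
        lid <- flankIdentity(all$left_flank[i], all$left_flank[j],
                             minOverlap)
        rid <- flankIdentity(all$right_flank[i], all$right_flank[j],
                             minOverlap)
        if (max(lid, rid) >= minIdentity) union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  pieces <- lapply(split(seq_len(n), roots), function(ix) {
    ref <- ix[all$line_id[ix] == referenceLine]
    keep <- if (length(ref)) ref[1L] else ix[1L]
    row <- all[keep, , drop = FALSE]
    row$member_lines <- paste(sort(unique(all$line_id[ix])),
                              collapse = ",")
    row
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an SSR table (MISA-like TSV)
#'
#' @param motifs SSR \code{data.frame} (optionally with
#'   \code{member_lines}).
#' @param path Output TSV path. Coordinates are written 1-based inclusive.
#' @return \code{path}, invisibly.
#' @export
writeSSRTable <- function(motifs, path) {
  out <- data.frame(
    contig_id = motifs$contig_id,
    ssr_nr = seq_len(nrow(motifs)),
    motif = motifs$unit,
    klass = motifs$klass,
    repeat_count = motifs$repeat_count,
    start = motifs$start + 1L,
    end = motifs$end,
    member_lines = if ("member_lines" %in% names(motifs))
      motifs$member_lines else motifs$line_id %||% "",
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
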