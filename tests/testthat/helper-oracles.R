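# Independent brute-force oracles and tiny fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# position-by-position homopolymer scan
bruteHomopolymerRuns <- function(s, minLen) {
  x <- strsplit(toupper(s), "")[[1L]]
  n <- length(x)
  out <- data.frame(base = character(0), start = integer(0),
                    length = integer(0), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (j - i + 1L >= minLen && x[i] != "N")
      out <- rbind(out, data.frame(base = x[i], start = i - 1L,
                                   length = j - i + 1L,
                                   stringsAsFactors = FALSE))
    i <- j + 1L
  }
  out
}

# exhaustive (position, unit-length) SSR enumeration; reports each
# maximal repeat once, anchored at its leftmost phase
bruteSSRs <- function(s, minRepeats) {
  x <- strsplit(toupper(s), "")[[1L]]
  n <- length(x)
  prim <- function(u) {
    k <- nchar(u)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L))
      if (k %% d == 0L && strrep(substr(u, 1L, d), k %/% d) == u)
        return(FALSE)
    TRUE
  }
  rows <- list()
  for (k in 1:6) {
    minc <- minRepeats[[as.character(k)]]
    pos <- 1L
    while (pos + 2L * k - 1L <= n) {
      unit <- paste(x[pos:(pos + k - 1L)], collapse = "")
      if (grepl("N", unit) || !prim(unit)) { pos <- pos + 1L; next }
      # leftmost-phase anchor: period must not extend one base left
      if (pos > 1L && x[pos - 1L] != "N" &&
          x[pos - 1L] == x[pos - 1L + k]) { pos <- pos + 1L; next }
      cnt <- 1L
      while (pos + (cnt + 1L) * k - 1L <= n &&
             paste(x[(pos + cnt * k):(pos + (cnt + 1L) * k - 1L)],
                   collapse = "") == unit)
        cnt <- cnt + 1L
      if (cnt >= minc)
        rows[[length(rows) + 1L]] <- data.frame(
          start = pos - 1L, unit = unit, repeat_count = cnt,
          stringsAsFactors = FALSE)
      pos <- pos + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), unit = character(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$start, nchar(res$unit)), , drop = FALSE]
}

# explicit binomial upper-tail summation (excess-heterozygosity oracle)
binomTailOracle <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal single-contig SAM fixture
writeTestSam <- function(path, contigId, contigLen, reads, lines) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contigId, contigLen),
           sprintf("@RG\tID:%s\tSM:%s", lines, lines))
  rec <- vapply(reads, function(r)
    paste(r$qname, 0, contigId, r$pos, 60, r$cigar, "*", 0, 0, r$seq,
          strrep("I", nchar(r$seq)), paste0("RG:Z:", r$rg), sep = "\t"),
    "")
  writeLines(c(hdr, rec), path)
  path
}

# Pileup built directly from per-line base-count matrices (6 x L)
makePileup <- function(countsList, contigId = "c1") {
  early <- lapply(countsList, function(m) {
    e <- matrix(0L, 4L, ncol(m))
    rownames(e) <- c("A", "C", "G", "T")
    e
  })
  new("Pileup", contigId = contigId, counts = countsList,
      earlyCounts = early, readStartWindow = 10L)
}

countsMatrix <- function(L, ...) {
  m <- matrix(0L, 6L, L)
  rownames(m) <- c("A", "C", "G", "T", "del", "ins")
  fills <- list(...)
  for (f in fills) m[f[[1L]], f[[2L]]] <- as.integer(f[[3L]])
  m
}
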