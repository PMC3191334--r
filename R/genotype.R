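#' Read a genotype-call matrix from TSV
#'
#' First column \code{line_id}, then one column per SNP with values
#' AA/AB/BB/NA. Optional metadata TSV with columns \code{line_id},
#' \code{pool}, \code{generation}.
#'
#' @param path Genotype TSV path.
#' @param metadata Optional metadata TSV path.
#' @return A \code{\link{GenotypeCalls}}.
#' @export
readGenotypeTSV <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (names(df)[1L] != "line_id")
    stop("first column of a genotype TSV must be line_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$line_id
  md <- if (!is.null(metadata))
    utils::read.delim(metadata, stringsAsFactors = FALSE) else NULL
  GenotypeCalls(m, md)
}

#' Write a genotype-call matrix to TSV
#'
#' @param x A \code{\link{GenotypeCalls}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTSV <- function(x, path) {
  m <- genotypeMatrix(x)
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Remove SNP assays with too much missing data
#'
#' Drops SNP columns whose missing-call fraction is strictly greater
#' than \code{maxMissingFraction} (default 0.05, the "more than 5\%
#' missing data" cleaning rule); column order of survivors is
#' preserved.
#'
#' @param x A \code{\link{GenotypeCalls}}.
#' @param maxMissingFraction Threshold (default 0.05; strict inequality).
#' @return The cleaned \code{GenotypeCalls}.
#' @export
cleanSnps <- function(x, maxMissingFraction = 0.05) {
  m <- genotypeMatrix(x)
  miss <- colMeans(is.na(m))
  GenotypeCalls(m[, miss <= maxMissingFraction, drop = FALSE],
                lineInfo(x))
}

#' Allele frequency of the A allele at one SNP
#'
#' Computed from allele counts: \eqn{f_A = (2 n_{AA} + n_{AB}) /
#' (2 n_{called})}, so \eqn{f_A + f_B = 1}.
#'
#' @param x A \code{\link{GenotypeCalls}}.
#' @param snpId SNP column id (or index).
#' @return Frequency in \[0, 1\].
#' @export
alleleFrequency <- function(x, snpId) {
  m <- genotypeMatrix(x)
  if (is.character(snpId) && !snpId %in% colnames(m))
    stop("unknown SNP: ", snpId)
  cl <- m[, snpId]
  n <- sum(!is.na(cl))
  if (n == 0L)
    stop("allele frequency undefined: all calls missing for ", snpId)
  (2 * sum(cl == "AA", na.rm = TRUE) + sum(cl == "AB", na.rm = TRUE)) /
    (2 * n)
}

#' Allele frequencies for all SNPs
#'
#' @param x A \code{\link{GenotypeCalls}}.
#' @return Named numeric vector (NA where all calls are missing).
#' @export
alleleFrequencies <- function(x) {
  m <- genotypeMatrix(x)
  n <- colSums(!is.na(m))
  f <- (2 * colSums(m == "AA", na.rm = TRUE) +
          colSums(m == "AB", na.rm = TRUE)) / (2 * n)
  f[n == 0L] <- NA_real_
  f
}

#' Bin allele frequencies into a left-open histogram
#'
#' Values belong to a category when they are strictly greater than the
#' left border and at most the right border; values equal to 0 fall
#' into the first category (and 1 into the last by the closed right
#' border).
#'
#' @param frequencies Numeric vector in \[0, 1\].
#' @param nBins Number of equal-width bins (default 10).
#' @return Named integer vector of bin counts summing to
#'   \code{length(frequencies)}.
#' @export
frequencyHistogram <- function(frequencies, nBins = 10L) {
  if (any(is.na(frequencies)) ||
      any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  br <- seq(0, 1, length.out = nBins + 1L)
  cuts <- cut(frequencies, breaks = br, right = TRUE,
              include.lowest = TRUE)
  table(cuts)
}

#' Residual heterozygosity of one line
#'
#' Fraction of assayed (non-missing) SNPs called heterozygous (AB) in a
#' nominally inbred line.
#'
#' @param x A \code{\link{GenotypeCalls}}.
#' @param lineId Line row id.
#' @return Fraction in \[0, 1\].
#' @export
residualHeterozygosity <- function(x, lineId) {
  m <- genotypeMatrix(x)
  if (!lineId %in% rownames(m)) stop("unknown line: ", lineId)
  cl <- m[lineId, ]
  n <- sum(!is.na(cl))
  if (n == 0L) stop("no assayed SNPs for line ", lineId)
  sum(cl == "AB", na.rm = TRUE) / n
}

#' Expected heterozygosity under selfing
#'
#' After \eqn{s} selfing generations the expected fraction of
#' heterozygous loci is \eqn{(1/2)^s}. Generation labels parse as
#' \code{F<g>} (giving \eqn{s = g - 1}; F1 is the initial cross, so
#' F7 means six selfing rounds, 1.6\%) or as the seed-increase notation
#' \code{F<a>:<b>} (giving \eqn{s = a - 1}; F6:9 means five rounds,
#' 3.1\%). Underscores as in \code{F_7_} are tolerated.
#'
#' @param generation Generation label(s), e.g. \code{"F7"},
#'   \code{"F6:9"}, or directly a number of selfing generations via
#'   \code{selfingGenerations}.
#' @param selfingGenerations Optional non-negative integer vector
#'   overriding label parsing.
#' @return Expected heterozygous fraction(s) in (0, 1\].
#' @examples
#' expectedHeterozygosity("F7")    # 1/64
#' expectedHeterozygosity("F6:9")  # 1/32
#' @export
expectedHeterozygosity <- function(generation = NULL,
                                   selfingGenerations = NULL) {
  if (is.null(selfingGenerations)) {
    selfingGenerations <- vapply(generation, function(g) {
      g <- gsub("_", "", g)
      m <- regmatches(g, regexec("^F([0-9]+)(?::([0-9]+))?$", g))[[1L]]
      if (length(m) < 2L || m[2L] == "")
        stop("cannot parse generation label: ", g)
      gg <- as.integer(m[2L])
      if (gg < 1L) stop("generation must be >= 1: ", g)
      gg - 1L
    }, 1L, USE.NAMES = FALSE)
  }
  if (any(selfingGenerations < 0L))
    stop("selfing generations must be non-negative")
  0.5^selfingGenerations
}

#' One-sided exact binomial test for excess heterozygosity
#'
#' Tests whether the observed number of heterozygous loci exceeds the
#' expectation under \code{expectedP} using the exact binomial upper
#' tail \eqn{p = \sum_{k \ge n_{het}} \binom{n}{k} p_0^k (1-p_0)^{n-k}}.
#' Star codes follow the conventional thresholds: \code{*} p < 0.05,
#' \code{**} p < 0.01, \code{***} p < 0.001.
#'
#' @param nHet Observed heterozygous loci.
#' @param nAssayed Total assayed loci.
#' @param expectedP Expected heterozygous fraction in (0, 1).
#' @param alternative \code{"greater"} (default, the excess hypothesis)
#'   or \code{"two.sided"}.
#' @return List with \code{p.value} and \code{stars}.
#' @examples
#' testExcessHeterozygosity(141, 3145, 1/64)
#' @export
testExcessHeterozygosity <- function(nHet, nAssayed, expectedP,
                                     alternative = c("greater",
                                                     "two.sided")) {
  alternative <- match.arg(alternative)
  if (nAssayed < 1L || nHet < 0L || nHet > nAssayed)
    stop("need 0 <= nHet <= nAssayed with nAssayed >= 1")
  if (expectedP <= 0 || expectedP >= 1)
    stop("expectedP must lie strictly between 0 and 1")
  p <- stats::binom.test(nHet, nAssayed, p = expectedP,
                         alternative = alternative)$p.value
  list(p.value = p, stars = starCode(p))
}

#' @rdname testExcessHeterozygosity
#' @param p A p-value.
#' @export
starCode <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
}

# display rounding: half-up at `digits` decimals (percent reporting)
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Per-line heterozygosity report from locus counts
#'
#' Builds the observed-versus-expected residual-heterozygosity report
#' of a genotyped inbred panel directly from per-line counts:
#' observed percent (half-up to one decimal), expected percent from the
#' generation label, the one-sided exact binomial p-value and its star
#' code.
#'
#' @param counts \code{data.frame} with columns \code{line_id},
#'   \code{total}, \code{het}, \code{generation}.
#' @return \code{data.frame} with columns \code{line_id}, \code{total},
#'   \code{het}, \code{generation}, \code{observed_pct},
#'   \code{expected_pct}, \code{p_value}, \code{stars}.
#' @export
heterozygosityReport <- function(counts) {
  need <- c("line_id", "total", "het", "generation")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  ep <- expectedHeterozygosity(counts$generation)
  pv <- mapply(function(h, n, p)
    testExcessHeterozygosity(h, n, p)$p.value,
    counts$het, counts$total, ep)
  data.frame(line_id = counts$line_id,
             total = counts$total,
             het = counts$het,
             generation = counts$generation,
             observed_pct = roundHalfUp(100 * counts$het / counts$total),
             expected_pct = roundHalfUp(100 * ep),
             p_value = pv,
             stars = vapply(pv, starCode, ""),
             stringsAsFactors = FALSE)
}

#' Heterozygosity report from a call matrix
#'
#' Convenience wrapper: tallies heterozygous/assayed loci per line from
#' a \code{\link{GenotypeCalls}} (using its \code{generation} metadata)
#' and calls \code{\link{heterozygosityReport}}.
#'
#' @param x A \code{\link{GenotypeCalls}} with \code{generation}
#'   metadata.
#' @return See \code{\link{heterozygosityReport}}.
#' @export
heterozygosityReportFromCalls <- function(x) {
  m <- genotypeMatrix(x)
  info <- lineInfo(x)
  if (is.null(info$generation))
    stop("lineData must carry a 'generation' column")
  heterozygosityReport(data.frame(
    line_id = rownames(m),
    total = rowSums(!is.na(m)),
    het = rowSums(m == "AB", na.rm = TRUE),
    generation = info$generation,
    stringsAsFactors = FALSE))
}

#' Per-pool summary: mean heterozygosity and monomorphic fraction
#'
#' For each heterotic pool, the arithmetic mean of per-line residual
#' heterozygosity and the fraction of SNPs monomorphic within the pool
#' (all non-missing calls identical and homozygous). Pools with zero
#' lines are omitted with a warning.
#'
#' @param x A \code{\link{GenotypeCalls}} with \code{pool} metadata.
#' @return \code{data.frame}: \code{pool}, \code{n_lines},
#'   \code{mean_heterozygosity}, \code{monomorphic_fraction}.
#' @export
poolSummary <- function(x) {
  m <- genotypeMatrix(x)
  pool <- lineInfo(x)$pool
  if (is.null(pool)) stop("lineData must carry a 'pool' column")
  pools <- unique(pool)
  rows <- lapply(pools, function(p) {
    ix <- which(pool == p)
    if (!length(ix)) {
      warning("pool with zero lines omitted: ", p)
      return(NULL)
    }
    het <- vapply(rownames(m)[ix], function(l)
      residualHeterozygosity(x, l), 0)
    sub <- m[ix, , drop = FALSE]
    mono <- vapply(seq_len(ncol(sub)), function(j) {
      cl <- sub[, j]
      cl <- cl[!is.na(cl)]
      length(cl) > 0L && !any(cl == "AB") && length(unique(cl)) == 1L
    }, TRUE)
    data.frame(pool = p, n_lines = length(ix),
               mean_heterozygosity = mean(het),
               monomorphic_fraction = mean(mono),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
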