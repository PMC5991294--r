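# Match-level filters: the histogram noise filter plus plain identity
# and size thresholds. All filters preserve input order and return
# subsets of their input.

#' Histogram-based noise filter
#'
#' A match is considered noise when it is small and its size is very
#' frequent. The filter (1) groups matches into `floor(N / 10)`
#' equal-width size bins spanning `[min blocklen, max blocklen]`;
#' (2) scans bins in increasing size order and takes the first bin of
#' maximal count as the modal bin; (3) from the modal bin scans upward
#' for the first bin whose count has dropped to at most 1% of the modal
#' count; (4) removes every match in bins strictly below that bin.
#' With fewer than 20 matches (fewer than two bins), a degenerate size
#' range, or no bin satisfying step 3, nothing is removed.
#'
#' @param matches A match table.
#' @return A list with elements `matches` (the kept rows, input order
#'   preserved) and `report` (a [NoiseFilterReport-class]).
#' @export
noiseFilter <- function(matches) {
  validateMatches(matches, "noiseFilter")
  n <- nrow(matches)
  noop <- function(nbins = 1, edges = range(matches$blocklen, 0)) {
    list(matches = matches,
         report = new("NoiseFilterReport", nBins = nbins, binEdges = edges,
                      modalBin = NA_real_, cutoffBin = NA_real_,
                      removed = 0, kept = n))
  }
  if (n < 20) return(noop())
  nbins <- floor(n / 10)
  lo <- min(matches$blocklen); hi <- max(matches$blocklen)
  if (lo == hi) return(noop())
  edges <- seq(lo, hi, length.out = nbins + 1)
  bin <- pmin(pmax(findInterval(matches$blocklen, edges,
                                rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  modal <- which.max(counts)             # first bin of maximal count
  threshold <- 0.01 * counts[modal]
  above <- which(counts[modal:nbins] <= threshold)
  report_noop <- function() {
    list(matches = matches,
         report = new("NoiseFilterReport", nBins = nbins, binEdges = edges,
                      modalBin = as.numeric(modal), cutoffBin = NA_real_,
                      removed = 0, kept = n))
  }
  if (!length(above)) return(report_noop())
  cutoff <- modal + above[1] - 1L
  keep <- bin >= cutoff
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(matches = out,
       report = new("NoiseFilterReport", nBins = nbins, binEdges = edges,
                    modalBin = as.numeric(modal),
                    cutoffBin = as.numeric(cutoff),
                    removed = sum(!keep), kept = sum(keep)))
}

#' Filter matches by identity
#'
#' Keeps matches with identity at least `minIdentity` and whose identity
#' class is not hidden.
#'
#' @param matches A match table.
#' @param minIdentity Minimum identity in `[0, 1]` (default 0).
#' @param hiddenClasses Integer identity classes (1-4) to hide.
#' @return The kept rows, input order preserved.
#' @export
filterIdentity <- function(matches, minIdentity = 0,
                           hiddenClasses = integer()) {
  stopifnot(minIdentity >= 0, minIdentity <= 1)
  if (!nrow(matches)) return(matches)
  keep <- matches$identity >= minIdentity
  if (length(hiddenClasses))
    keep <- keep & !(identityClass(matches$identity) %in% hiddenClasses)
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter matches by minimum block length
#'
#' @param matches A match table.
#' @param minSize Minimum alignment block length in bases.
#' @return The kept rows, input order preserved.
#' @export
filterMinSize <- function(matches, minSize = 0) {
  stopifnot(minSize >= 0)
  if (!nrow(matches)) return(matches)
  out <- matches[matches$blocklen >= minSize, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply filters to a DotPlot
#'
#' Records the requested filters in the plot state (so rendering and
#' [visibleMatches()] honour them) and, when `noise = TRUE`, removes
#' noise matches from the match table itself.
#'
#' @param plot A [DotPlot-class].
#' @param minIdentity,minSize,hiddenClasses Filter settings; `NA` /
#'   empty disables the corresponding filter.
#' @param noise Apply [noiseFilter()] to the match table.
#' @return The updated plot. When `noise = TRUE` the noise report is
#'   attached as attribute `noiseReport`.
#' @export
applyFilters <- function(plot, minIdentity = NA_real_, minSize = NA_real_,
                         hiddenClasses = integer(), noise = FALSE) {
  plot@minIdentity <- as.numeric(minIdentity)
  plot@minSize <- as.numeric(minSize)
  plot@hiddenClasses <- as.integer(hiddenClasses)
  report <- NULL
  if (noise) {
    nf <- noiseFilter(plot@matches)
    plot@matches <- nf$matches
    plot@noiseFiltered <- TRUE
    report <- nf$report
  }
  validObject(plot)
  if (!is.null(report)) attr(plot, "noiseReport") <- report
  plot
}
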