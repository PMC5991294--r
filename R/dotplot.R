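# Dot-plot state: validated construction, identity classes, the
# largest-alignment cap, axis layout with small-sequence merging, and
# placement of matches in concatenated-axis coordinates.

DEFAULT_CAP <- 1e5
DEFAULT_MERGE_FRACTION <- 0.002

#' Build a validated DotPlot
#'
#' Checks that every match refers to a catalogued sequence and lies
#' within its bounds, then assembles the plot state.
#'
#' @param matches A match table (see [matchTable()], [readPaf()]).
#' @param query,target [SequenceCatalog-class] objects for the two axes.
#' @return A [DotPlot-class].
#' @examples
#' q <- SequenceCatalog("q1", 1000); t <- SequenceCatalog("t1", 2000)
#' m <- matchTable(qname = "q1", qlen = 1000, qstart = 0, qend = 500,
#'                 strand = "+", tname = "t1", tlen = 2000,
#'                 tstart = 100, tend = 600, nmatch = 450, blocklen = 500)
#' buildDotPlot(m, q, t)
#' @export
buildDotPlot <- function(matches, query, target) {
  validateMatches(matches, "buildDotPlot")
  rownames(matches) <- NULL
  new("DotPlot", matches = matches, query = query, target = target,
      sorted = FALSE, noiseFiltered = FALSE, minIdentity = NA_real_,
      minSize = NA_real_, hiddenClasses = integer(),
      originalQuery = query, reversedQueries = character())
}

#' Identity class of an alignment
#'
#' Bins identity values into the four classes used for colouring:
#' class 1 `< 0.25`, class 2 `[0.25, 0.50)`, class 3 `[0.50, 0.75)`,
#' class 4 `>= 0.75`. The classes partition `[0, 1]`; boundary values
#' fall in the upper class.
#'
#' @param identity Numeric vector of identities in `[0, 1]`.
#' @return Integer vector of classes in `1:4`.
#' @export
identityClass <- function(identity) {
  if (any(is.na(identity) | identity < 0 | identity > 1))
    stop("identity must lie in [0, 1]", call. = FALSE)
  cls <- findInterval(identity, c(0, 0.25, 0.50, 0.75))
  as.integer(cls)
}

#' Human-readable identity class labels
#' @return Character vector of length 4.
#' @export
identityClassLabels <- function() {
  c("< 25%", "25% - 50%", "50% - 75%", ">= 75%")
}

#' Keep only the largest alignments
#'
#' When a match table exceeds `cap` rows, retains the `cap` matches with
#' the greatest block length. Ties are broken by input order (stable)
#' and the kept matches are returned in input order.
#'
#' @param matches A match table.
#' @param cap Maximum number of matches to keep (default 100,000).
#' @return A match table with at most `cap` rows.
#' @export
capLargest <- function(matches, cap = DEFAULT_CAP) {
  stopifnot(cap >= 0)
  if (nrow(matches) <= cap) return(matches)
  if (cap == 0) return(matches[0, , drop = FALSE])
  ord <- order(-matches$blocklen)          # stable: ties keep input order
  keep <- sort(ord[seq_len(cap)])
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lay out one axis, merging runs of small sequences
#'
#' Maximal runs of successive sequences individually shorter than
#' `mergeFraction` of the axis total are merged into a single grayed
#' super-sequence group; all other sequences form singleton groups.
#' Group offsets are cumulative in catalog order.
#'
#' @param catalog A non-empty [SequenceCatalog-class].
#' @param mergeFraction Small-sequence threshold as a fraction of total
#'   axis length (default 0.002, i.e. 0.2%).
#' @return An [AxisLayout-class].
#' @export
layoutAxis <- function(catalog, mergeFraction = DEFAULT_MERGE_FRACTION) {
  if (length(catalog) == 0) stop("catalog is empty", call. = FALSE)
  lens <- catalog@seqlengths
  total <- sum(lens)
  small <- lens < mergeFraction * total
  # run-length encode the small flag to find maximal runs
  r <- rle(small)
  groups <- list(); glens <- numeric(); grayed <- logical()
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    idx <- seq(pos, length.out = r$lengths[k])
    if (r$values[k] && r$lengths[k] >= 2) {
      groups[[length(groups) + 1]] <- catalog@seqnames[idx]
      glens <- c(glens, sum(lens[idx])); grayed <- c(grayed, TRUE)
    } else {
      for (i in idx) {
        groups[[length(groups) + 1]] <- catalog@seqnames[i]
        glens <- c(glens, lens[i]); grayed <- c(grayed, FALSE)
      }
    }
    pos <- pos + r$lengths[k]
  }
  offsets <- cumsum(c(0, head(glens, -1)))
  seq_off <- cumsum(c(0, head(lens, -1)))
  new("AxisLayout", groups = groups, groupLengths = glens,
      groupOffsets = offsets, grayed = grayed,
      seqOffsets = stats::setNames(seq_off, catalog@seqnames), total = total)
}

#' Drop trivial self-alignment matches
#'
#' Removes every forward-strand match of a sequence against itself at
#' identical positions -- the trivial diagonal that a self-alignment
#' produces. Repeats (same sequence, different positions) and
#' reverse-strand self-overlaps (inverted repeats) are kept.
#'
#' @param matches A match table.
#' @return The match table without trivial self matches.
#' @export
removeSelfMatches <- function(matches) {
  if (!nrow(matches)) return(matches)
  trivial <- matches$strand == "+" & matches$qname == matches$tname &
    matches$qstart == matches$tstart & matches$qend == matches$tend
  out <- matches[!trivial, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place matches in concatenated-axis coordinates
#'
#' Maps every match of the plot to a line segment on the concatenated
#' axes: x = target coordinate + axis offset of its target sequence,
#' y = query coordinate + offset of its query sequence. Forward matches
#' run diagonally (increasing x with increasing y); reverse matches run
#' anti-diagonally, from `(tend, qstart)` to `(tstart, qend)`.
#'
#' @param plot A [DotPlot-class].
#' @param layoutQ,layoutT [AxisLayout-class] objects built from the
#'   plot's catalogs in their current order; computed when omitted.
#' @return A data.frame with columns `x1,y1,x2,y2`, `class` (identity
#'   class) and `blocklen`.
#' @export
globalCoordinates <- function(plot, layoutQ = layoutAxis(plot@query),
                              layoutT = layoutAxis(plot@target)) {
  m <- visibleMatches(plot)
  if (!nrow(m))
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), class = integer(),
                      blocklen = numeric()))
  offq <- layoutQ@seqOffsets[m$qname]
  offt <- layoutT@seqOffsets[m$tname]
  fwd <- m$strand == "+"
  x1 <- ifelse(fwd, m$tstart, m$tend) + offt
  x2 <- ifelse(fwd, m$tend, m$tstart) + offt
  y1 <- m$qstart + offq
  y2 <- m$qend + offq
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             class = identityClass(m$identity), blocklen = m$blocklen,
             row.names = NULL)
}

#' Matches visible under the plot's active filters
#'
#' Applies the stored minimum-identity, hidden-class and minimum-size
#' filters (set via [applyFilters()]) to the plot's match table.
#'
#' @param plot A [DotPlot-class].
#' @return The filtered match table.
#' @export
visibleMatches <- function(plot) {
  m <- plot@matches
  if (!nrow(m)) return(m)
  keep <- rep(TRUE, nrow(m))
  if (!is.na(plot@minIdentity)) keep <- keep & m$identity >= plot@minIdentity
  if (length(plot@hiddenClasses))
    keep <- keep & !(identityClass(m$identity) %in% plot@hiddenClasses)
  if (!is.na(plot@minSize)) keep <- keep & m$blocklen >= plot@minSize
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
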