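# Reference identity profile: the fraction of reference bases whose
# best covering alignment falls in each identity class. Computed with
# interval arithmetic (IRanges) so whole-genome references are cheap;
# bases covered by several matches count once, at the highest class.

#' Remove matches included in another match on the reference
#'
#' Drops every match whose reference interval `[tstart, tend)` is
#' contained within another match's interval on the same target
#' sequence. Matches with identical intervals are collapsed to the one
#' of highest identity (first in input order on ties). Containment is
#' judged on the reference axis only.
#'
#' @param matches A match table.
#' @return The match table without included matches, input order
#'   preserved.
#' @export
removeIncluded <- function(matches) {
  validateMatches(matches, "removeIncluded")
  n <- nrow(matches)
  if (n < 2) return(matches)
  drop <- logical(n)
  for (idx in split(seq_len(n), matches$tname)) {
    if (length(idx) < 2) next
    # sort: start asc, end desc, identity desc, input order; any earlier
    # item in this order whose end >= this end contains this interval
    o <- idx[order(matches$tstart[idx], -matches$tend[idx],
                   -matches$identity[idx], idx)]
    max_end <- -Inf
    for (i in o) {
      if (matches$tend[i] <= max_end) drop[i] <- TRUE
      max_end <- max(max_end, matches$tend[i])
    }
  }
  out <- matches[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference identity profile
#'
#' Summarises how much of the reference is covered at each identity
#' class: the match list is sorted along the reference, included
#' matches are removed, the noise filter is applied, and then every
#' reference base is attributed to the highest identity class among the
#' matches covering it. Fractions are covered bases per class divided
#' by the total reference length; `no_match` is the uncovered fraction.
#' The pipeline runs on a working copy -- the plot itself is untouched.
#'
#' @param plot A [DotPlot-class].
#' @return A [SummaryProfile-class].
#' @examples
#' q <- SequenceCatalog("q1", 1000); t <- SequenceCatalog("t1", 1000)
#' m <- matchTable(qname = "q1", qlen = 1000, qstart = 0, qend = 500,
#'                 strand = "+", tname = "t1", tlen = 1000,
#'                 tstart = 0, tend = 500, nmatch = 450, blocklen = 500)
#' profileFractions(summaryProfile(buildDotPlot(m, q, t)))
#' @export
summaryProfile <- function(plot) {
  work <- applySort(plot)
  m <- removeIncluded(work@matches)
  m <- noiseFilter(m)$matches
  total <- sum(plot@target@seqlengths)
  covered <- numeric(4)
  if (nrow(m)) {
    cls <- identityClass(m$identity)
    for (tname in unique(m$tname)) {
      sel <- m$tname == tname
      higher <- IRanges::IRanges()           # bases already claimed
      for (k in 4:1) {
        ksel <- sel & cls == k
        if (!any(ksel)) next
        ir <- IRanges::reduce(IRanges::IRanges(start = m$tstart[ksel] + 1,
                                               end = m$tend[ksel]))
        new_cov <- IRanges::setdiff(ir, higher)
        covered[k] <- covered[k] + sum(IRanges::width(new_cov))
        higher <- IRanges::reduce(IRanges::union(higher, ir))
      }
    }
  }
  fractions <- c(covered, total - sum(covered)) / total
  names(fractions) <- c("class1", "class2", "class3", "class4", "no_match")
  new("SummaryProfile", fractions = fractions, totalReference = total)
}

#' Serialize a summary profile
#'
#' @param profile A [SummaryProfile-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeSummaryJson <- function(profile, path) {
  x <- as.list(profile@fractions)
  x$total_reference <- profile@totalReference
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeSummaryJson
#' @export
writeSummaryTsv <- function(profile, path) {
  df <- data.frame(class = c(identityClassLabels(), "no match"),
                   percent = 100 * unname(profile@fractions))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
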