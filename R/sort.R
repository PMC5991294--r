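# Query ordering and orientation along the reference. Each query contig
# is assigned the target carrying most of its aligned bases, oriented by
# the dominant strand of those alignments, and placed at the
# block-length-weighted mean position of its matches on that target.

#' Compute the query sort plan
#'
#' For each query sequence: the assigned target is the one maximising
#' the summed block length of its matches (ties broken by target catalog
#' order); the orientation is reverse when reverse-strand matches to the
#' assigned target carry more aligned bases than forward-strand ones
#' (ties forward); the position is the block-length-weighted mean of the
#' target-interval midpoints. Queries are ordered by (target catalog
#' index, position); queries with no matches follow in input order.
#'
#' @param plot A [DotPlot-class].
#' @return A [SortPlan-class].
#' @export
computeSortPlan <- function(plot) {
  m <- plot@matches
  qnames <- plot@query@seqnames
  tnames <- plot@target@seqnames
  assigned <- rep(NA_character_, length(qnames))
  orient <- rep("forward", length(qnames))
  tindex <- rep(NA_real_, length(qnames))
  pos <- rep(NA_real_, length(qnames))
  for (i in seq_along(qnames)) {
    mi <- m[m$qname == qnames[i], , drop = FALSE]
    if (!nrow(mi)) next
    mass <- tapply(mi$blocklen, mi$tname, sum)
    cand <- names(mass)[mass == max(mass)]
    tgt <- cand[which.min(match(cand, tnames))]
    assigned[i] <- tgt
    tindex[i] <- match(tgt, tnames)
    mt <- mi[mi$tname == tgt, , drop = FALSE]
    rev_mass <- sum(mt$blocklen[mt$strand == "-"])
    fwd_mass <- sum(mt$blocklen[mt$strand == "+"])
    rev_now <- rev_mass > fwd_mass
    # orientation is expressed relative to the input orientation, so a
    # query already mirrored by an earlier sort reports a stable plan
    if (xor(rev_now, qnames[i] %in% plot@reversedQueries))
      orient[i] <- "reverse"
    pos[i] <- weighted.mean((mt$tstart + mt$tend) / 2, mt$blocklen)
  }
  has <- !is.na(assigned)
  ord <- c(which(has)[order(tindex[has], pos[has])], which(!has))
  new("SortPlan", queries = qnames[ord], assignedTargets = assigned[ord],
      orientations = orient[ord], targetIndex = tindex[ord],
      positions = pos[ord])
}

mirrorQueries <- function(matches, qnames) {
  sel <- matches$qname %in% qnames
  if (any(sel)) {
    qs <- matches$qstart[sel]
    matches$qstart[sel] <- matches$qlen[sel] - matches$qend[sel]
    matches$qend[sel] <- matches$qlen[sel] - qs
    matches$strand[sel] <- ifelse(matches$strand[sel] == "+", "-", "+")
  }
  matches
}

#' Apply a sort plan to a plot
#'
#' Reorders the query catalog per the plan and mirrors every match of a
#' reverse-oriented query (`qstart' = qlen - qend`, strand toggled).
#' [unsort()] restores the original catalog order and orientations
#' exactly.
#'
#' @param plot A [DotPlot-class].
#' @param plan A [SortPlan-class] covering the plot's query catalog;
#'   computed with [computeSortPlan()] when omitted.
#' @return The sorted plot.
#' @export
applySort <- function(plot, plan = computeSortPlan(plot)) {
  if (!setequal(plan@queries, plot@query@seqnames) ||
      length(plan@queries) != length(plot@query@seqnames))
    stop("sort plan does not cover the query catalog", call. = FALSE)
  lens <- catalogLengths(plot@query)
  plot@query <- SequenceCatalog(plan@queries, lens[plan@queries])
  to_rev <- plan@queries[plan@orientations == "reverse"]
  flip <- union(setdiff(to_rev, plot@reversedQueries),
                setdiff(plot@reversedQueries, to_rev))
  plot@matches <- mirrorQueries(plot@matches, flip)
  plot@reversedQueries <- to_rev
  plot@sorted <- TRUE
  validObject(plot)
  plot
}

#' Undo sorting
#'
#' Restores the input query order and un-mirrors every currently
#' reversed query, so that `unsort(applySort(plot))` reproduces the
#' original plot exactly.
#'
#' @param plot A [DotPlot-class].
#' @return The restored plot.
#' @export
unsort <- function(plot) {
  plot@matches <- mirrorQueries(plot@matches, plot@reversedQueries)
  plot@reversedQueries <- character()
  plot@query <- plot@originalQuery
  plot@sorted <- FALSE
  validObject(plot)
  plot
}

#' Reverse a single query sequence
#'
#' Mirrors the matches of one query (as [applySort()] does for
#' reverse-oriented queries) without changing the catalog order.
#' Reversing twice is the identity.
#'
#' @param plot A [DotPlot-class].
#' @param qname Query sequence name.
#' @return The updated plot.
#' @export
reverseQuery <- function(plot, qname) {
  if (!qname %in% plot@query@seqnames)
    stop("unknown query sequence: ", qname, call. = FALSE)
  plot@matches <- mirrorQueries(plot@matches, qname)
  if (qname %in% plot@reversedQueries)
    plot@reversedQueries <- setdiff(plot@reversedQueries, qname)
  else
    plot@reversedQueries <- c(plot@reversedQueries, qname)
  validObject(plot)
  plot
}

#' Query-to-reference association table
#'
#' One row per query, in plan order: the query name and the reference
#' sequence carrying the greatest share of its aligned bases (`"None"`
#' for unaligned queries).
#'
#' @param plan A [SortPlan-class].
#' @return A data.frame with columns `Query` and `Target`.
#' @export
associationTable <- function(plan) {
  data.frame(Query = plan@queries,
             Target = ifelse(is.na(plan@assignedTargets), "None",
                             plan@assignedTargets),
             stringsAsFactors = FALSE)
}

#' Write the association table as TSV
#' @param plan A [SortPlan-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAssociationTable <- function(plan, path) {
  write.table(associationTable(plan), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
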