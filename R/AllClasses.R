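#' @import methods
#' @importFrom utils head tail read.table write.table untar
#' @importFrom stats runif rbinom weighted.mean
NULL

PAF_COLUMNS <- c("qname", "qlen", "qstart", "qend", "strand",
                 "tname", "tlen", "tstart", "tend",
                 "nmatch", "blocklen", "mapq")

MATCH_COLUMNS <- c(PAF_COLUMNS, "identity", "tags")

#' Construct a match table
#'
#' Builds the data.frame representation of pairwise local alignments used
#' throughout the package: one row per alignment, PAF-style 0-based
#' half-open coordinates, with identity computed as the number of residue
#' matches divided by the alignment block length.
#'
#' @param qname,tname Query/target sequence names.
#' @param qlen,tlen Full query/target sequence lengths in bases.
#' @param qstart,qend,tstart,tend 0-based half-open alignment coordinates.
#' @param strand `"+"` for forward, `"-"` for reverse alignments.
#' @param nmatch Number of matching bases in the alignment.
#' @param blocklen Alignment block length in bases (the "size" of a match).
#' @param mapq Mapping quality (carried through, not interpreted).
#' @param tags Extra PAF tag columns as a single tab-joined string,
#'   preserved opaquely on round-trip.
#' @return A validated `data.frame` with one row per match.
#' @examples
#' m <- matchTable(qname = "q1", qlen = 1000, qstart = 0, qend = 500,
#'                 strand = "+", tname = "t1", tlen = 2000,
#'                 tstart = 100, tend = 600, nmatch = 450, blocklen = 500)
#' m$identity  # 0.9
#' @export
matchTable <- function(qname = character(), qlen = numeric(),
                       qstart = numeric(), qend = numeric(),
                       strand = character(), tname = character(),
                       tlen = numeric(), tstart = numeric(),
                       tend = numeric(), nmatch = numeric(),
                       blocklen = numeric(), mapq = 60L,
                       tags = "") {
  n <- length(qname)
  df <- data.frame(
    qname = as.character(qname), qlen = as.numeric(qlen),
    qstart = as.numeric(qstart), qend = as.numeric(qend),
    strand = as.character(strand), tname = as.character(tname),
    tlen = as.numeric(tlen), tstart = as.numeric(tstart),
    tend = as.numeric(tend), nmatch = as.numeric(nmatch),
    blocklen = as.numeric(blocklen),
    mapq = rep_len(as.numeric(mapq), n),
    tags = rep_len(as.character(tags), n),
    stringsAsFactors = FALSE
  )
  df$identity <- ifelse(df$blocklen > 0, df$nmatch / df$blocklen, NA_real_)
  df <- df[, MATCH_COLUMNS]
  validateMatches(df)
  df
}

emptyMatchTable <- function() matchTable()

validateMatches <- function(m, where = "match table") {
  if (!is.data.frame(m))
    stop(where, ": matches must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(MATCH_COLUMNS, names(m))
  if (length(missing_cols))
    stop(where, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(m) == 0) return(invisible(TRUE))
  if (!all(m$strand %in% c("+", "-")))
    stop(where, ": strand must be '+' or '-'", call. = FALSE)
  bad <- !(m$qstart >= 0 & m$qstart < m$qend & m$qend <= m$qlen)
  if (any(bad))
    stop(where, ": query coordinates violate 0 <= qstart < qend <= qlen at row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  bad <- !(m$tstart >= 0 & m$tstart < m$tend & m$tend <= m$tlen)
  if (any(bad))
    stop(where, ": target coordinates violate 0 <= tstart < tend <= tlen at row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  if (any(m$blocklen < 1))
    stop(where, ": blocklen must be >= 1", call. = FALSE)
  if (any(m$nmatch < 0 | m$nmatch > m$blocklen))
    stop(where, ": nmatch must lie in [0, blocklen]", call. = FALSE)
  invisible(TRUE)
}

#' SequenceCatalog: ordered sequence names and lengths for one axis
#'
#' An ordered set of (name, length) pairs describing one axis of a dot
#' plot. The order is meaningful: plots are laid out following the input
#' FASTA sequence order.
#'
#' @slot seqnames Character vector of unique sequence names, in axis order.
#' @slot seqlengths Numeric vector of sequence lengths in bases (>= 1).
#' @export
setClass("SequenceCatalog",
         representation(seqnames = "character", seqlengths = "numeric"))

setValidity("SequenceCatalog", function(object) {
  if (length(object@seqnames) != length(object@seqlengths))
    return("names and lengths differ in length")
  if (anyDuplicated(object@seqnames))
    return(paste0("duplicate sequence name: ",
                  object@seqnames[duplicated(object@seqnames)][1]))
  if (length(object@seqlengths) && any(object@seqlengths < 1))
    return("sequence lengths must be >= 1")
  TRUE
})

#' Create a SequenceCatalog
#'
#' @param seqnames Character vector of sequence names (unique).
#' @param seqlengths Numeric vector of lengths in bases; may be named
#'   instead of passing `seqnames`.
#' @return A [SequenceCatalog-class] object.
#' @examples
#' SequenceCatalog(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
SequenceCatalog <- function(seqnames = names(seqlengths), seqlengths) {
  if (is.null(seqnames)) stop("sequence names are required")
  new("SequenceCatalog", seqnames = as.character(seqnames),
      seqlengths = unname(as.numeric(seqlengths)))
}

#' @describeIn SequenceCatalog-class Sequence names in axis order.
#' @param x A `SequenceCatalog`.
#' @export
setMethod("names", "SequenceCatalog", function(x) x@seqnames)

#' Sequence lengths of a catalog
#' @param x A [SequenceCatalog-class].
#' @return Named numeric vector of lengths in axis order.
#' @export
catalogLengths <- function(x) {
  stats::setNames(x@seqlengths, x@seqnames)
}

#' @describeIn SequenceCatalog-class Number of sequences.
#' @export
setMethod("length", "SequenceCatalog", function(x) length(x@seqnames))

setMethod("show", "SequenceCatalog", function(object) {
  cat("SequenceCatalog with", length(object), "sequence(s),",
      format(sum(object@seqlengths), big.mark = ","), "bases total\n")
  n <- min(length(object), 6L)
  if (n > 0) {
    for (i in seq_len(n))
      cat(" ", object@seqnames[i], ": ",
          format(object@seqlengths[i], big.mark = ","), " bp\n", sep = "")
    if (length(object) > n) cat("  ...\n")
  }
})

#' ChunkMap: mapping from chunk names back to original sequences
#'
#' Records, for every chunk produced by [splitCatalog()], the original
#' sequence name and the 0-based offset of the chunk within it, so that
#' alignments computed against chunks can be lifted back to original
#' coordinates with [unchunk()].
#'
#' @slot chunkSize Chunk size in bases.
#' @slot chunkNames Character vector of chunk names (unique).
#' @slot originalNames Original sequence name per chunk.
#' @slot offsets 0-based base offset of each chunk within its original
#'   sequence; always a multiple of `chunkSize`.
#' @slot originalLengths Full length of the original sequence per chunk.
#' @export
setClass("ChunkMap",
         representation(chunkSize = "numeric", chunkNames = "character",
                        originalNames = "character", offsets = "numeric",
                        originalLengths = "numeric"))

setValidity("ChunkMap", function(object) {
  n <- length(object@chunkNames)
  if (length(object@originalNames) != n || length(object@offsets) != n ||
      length(object@originalLengths) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@chunkNames))
    return("chunk names must be unique")
  if (n && any(object@offsets %% object@chunkSize != 0))
    return("offsets must be multiples of the chunk size")
  TRUE
})

setMethod("show", "ChunkMap", function(object) {
  cat("ChunkMap:", length(object@chunkNames), "chunk(s) over",
      length(unique(object@originalNames)), "sequence(s), chunk size",
      format(object@chunkSize, big.mark = ","), "\n")
})

#' AxisLayout: grouped axis placement with small-sequence merging
#'
#' The layout of one axis: sequences in order, with maximal runs of
#' successive small sequences (shorter than `mergeFraction` of the axis
#' total) collapsed into grayed "super-sequence" groups.
#'
#' @slot groups List of character vectors; each element is one group
#'   (singleton ordinary sequence or a merged super-sequence).
#' @slot groupLengths Total length of each group in bases.
#' @slot groupOffsets Cumulative start offset of each group.
#' @slot grayed Logical per group; `TRUE` for super-sequences.
#' @slot seqOffsets Named numeric: global axis offset of every sequence.
#' @slot total Total axis length in bases.
#' @export
setClass("AxisLayout",
         representation(groups = "list", groupLengths = "numeric",
                        groupOffsets = "numeric", grayed = "logical",
                        seqOffsets = "numeric", total = "numeric"))

setValidity("AxisLayout", function(object) {
  if (length(object@groups) != length(object@groupLengths) ||
      length(object@groups) != length(object@grayed) ||
      length(object@groups) != length(object@groupOffsets))
    return("group slots differ in length")
  if (length(object@groupOffsets) > 1 && any(diff(object@groupOffsets) <= 0))
    return("group offsets must be strictly increasing")
  if (length(object@groupLengths) &&
      abs(sum(object@groupLengths) - object@total) > 1e-6)
    return("group lengths must sum to the axis total")
  TRUE
})

setMethod("show", "AxisLayout", function(object) {
  cat("AxisLayout:", length(object@groups), "group(s) (",
      sum(object@grayed), "super-sequence(s) ) over",
      format(object@total, big.mark = ","), "bases\n")
})

#' DotPlot: the full dot-plot state
#'
#' Holds the match table, the query and target catalogs (query order may
#' change when sorted), the active filters, and enough state to undo a
#' sort exactly.
#'
#' @slot matches Match table (see [matchTable()]), in current display
#'   coordinates (query mirroring applied for reversed queries).
#' @slot query,target [SequenceCatalog-class] for each axis.
#' @slot sorted Logical; `TRUE` after [applySort()].
#' @slot noiseFiltered Logical; `TRUE` after [noiseFilter()] has been
#'   applied through [applyFilters()].
#' @slot minIdentity,minSize Active filter thresholds (`NA` = none).
#' @slot hiddenClasses Integer identity classes currently hidden.
#' @slot originalQuery The query catalog in input order (for unsort).
#' @slot reversedQueries Names of queries currently mirrored.
#' @export
setClass("DotPlot",
         representation(matches = "data.frame", query = "SequenceCatalog",
                        target = "SequenceCatalog", sorted = "logical",
                        noiseFiltered = "logical", minIdentity = "numeric",
                        minSize = "numeric", hiddenClasses = "integer",
                        originalQuery = "SequenceCatalog",
                        reversedQueries = "character"))

setValidity("DotPlot", function(object) {
  m <- object@matches
  if (nrow(m)) {
    unk_q <- setdiff(unique(m$qname), object@query@seqnames)
    if (length(unk_q))
      return(paste0("unknown query sequence: ", unk_q[1]))
    unk_t <- setdiff(unique(m$tname), object@target@seqnames)
    if (length(unk_t))
      return(paste0("unknown target sequence: ", unk_t[1]))
    ql <- catalogLengths(object@query)[m$qname]
    tl <- catalogLengths(object@target)[m$tname]
    if (any(m$qend > ql))
      return(paste0("match exceeds query length on ",
                    m$qname[which(m$qend > ql)[1]]))
    if (any(m$tend > tl))
      return(paste0("match exceeds target length on ",
                    m$tname[which(m$tend > tl)[1]]))
  }
  TRUE
})

setMethod("show", "DotPlot", function(object) {
  cat("DotPlot: ", nrow(object@matches), " match(es); query ",
      length(object@query), " seq(s), target ", length(object@target),
      " seq(s)\n", sep = "")
  flags <- c(if (object@sorted) "sorted",
             if (object@noiseFiltered) "noise-filtered",
             if (!is.na(object@minIdentity)) sprintf("min identity %.2f", object@minIdentity),
             if (!is.na(object@minSize)) sprintf("min size %g", object@minSize),
             if (length(object@hiddenClasses))
               paste0("hidden classes ", paste(object@hiddenClasses, collapse = ",")))
  if (length(flags)) cat("  flags:", paste(flags, collapse = "; "), "\n")
})

#' Matches of a DotPlot
#' @param plot A [DotPlot-class].
#' @return The match table currently held by the plot.
#' @export
plotMatches <- function(plot) plot@matches

#' Query / target catalog accessors
#' @param plot A [DotPlot-class].
#' @return The corresponding [SequenceCatalog-class].
#' @export
queryCatalog <- function(plot) plot@query

#' @rdname queryCatalog
#' @export
targetCatalog <- function(plot) plot@target

#' SortPlan: per-query target assignment, orientation and order
#'
#' @slot queries Query names, one per catalog entry, in sorted order
#'   (assigned queries first, unaligned queries last in input order).
#' @slot assignedTargets Assigned reference per query (`NA` if unaligned).
#' @slot orientations `"forward"` or `"reverse"` per query.
#' @slot targetIndex Catalog index of the assigned target (`NA` if none).
#' @slot positions Block-length-weighted mean target midpoint per query.
#' @export
setClass("SortPlan",
         representation(queries = "character", assignedTargets = "character",
                        orientations = "character", targetIndex = "numeric",
                        positions = "numeric"))

setValidity("SortPlan", function(object) {
  n <- length(object@queries)
  if (length(object@assignedTargets) != n || length(object@orientations) != n ||
      length(object@targetIndex) != n || length(object@positions) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@queries))
    return("each query must appear exactly once")
  if (n && !all(object@orientations %in% c("forward", "reverse")))
    return("orientations must be 'forward' or 'reverse'")
  TRUE
})

setMethod("show", "SortPlan", function(object) {
  cat("SortPlan for", length(object@queries), "query sequence(s);",
      sum(is.na(object@assignedTargets)), "unaligned,",
      sum(object@orientations == "reverse"), "reversed\n")
})

#' SummaryProfile: reference coverage by identity class
#'
#' Fractions of reference bases whose best covering alignment falls in
#' each identity class, plus the uncovered fraction. Fractions sum to 1.
#'
#' @slot fractions Numeric of length 5, named `class1`..`class4` and
#'   `no_match`.
#' @slot totalReference Total reference length in bases.
#' @export
setClass("SummaryProfile",
         representation(fractions = "numeric", totalReference = "numeric"))

setValidity("SummaryProfile", function(object) {
  if (length(object@fractions) != 5) return("five fractions expected")
  if (any(object@fractions < -1e-12 | object@fractions > 1 + 1e-12))
    return("fractions must lie in [0, 1]")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    return("fractions must sum to 1")
  TRUE
})

setMethod("show", "SummaryProfile", function(object) {
  cat("SummaryProfile over", format(object@totalReference, big.mark = ","),
      "reference bases\n")
  lab <- c("identity < 25%", "25% - 50%", "50% - 75%", "identity >= 75%",
           "no match")
  for (i in 1:5)
    cat(sprintf("  %-16s %6.2f%%\n", lab[i], 100 * object@fractions[i]))
})

#' Fractions of a SummaryProfile
#' @param x A [SummaryProfile-class].
#' @return Named numeric vector (`class1`..`class4`, `no_match`).
#' @export
profileFractions <- function(x) x@fractions

#' NoiseFilterReport: diagnostics from the histogram noise filter
#'
#' @slot nBins Number of equal-width size bins used.
#' @slot binEdges Bin edge positions (length `nBins + 1`), in bases.
#' @slot modalBin Index of the first most-populated bin.
#' @slot cutoffBin Index of the first bin at or above the modal bin whose
#'   count dropped to <= 1% of the modal count (`NA` if none found).
#' @slot removed,kept Counts of matches removed and kept.
#' @export
setClass("NoiseFilterReport",
         representation(nBins = "numeric", binEdges = "numeric",
                        modalBin = "numeric", cutoffBin = "numeric",
                        removed = "numeric", kept = "numeric"))

setMethod("show", "NoiseFilterReport", function(object) {
  cat("NoiseFilterReport:", object@nBins, "bin(s); modal bin",
      object@modalBin, "; cutoff bin",
      ifelse(is.na(object@cutoffBin), "none", object@cutoffBin),
      ";", object@removed, "removed,", object@kept, "kept\n")
})

#' Serialize a noise-filter report as JSON
#' @param report A [NoiseFilterReport-class].
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
noiseReportJson <- function(report, path = NULL) {
  x <- list(n_bins = report@nBins, bin_edges = report@binEdges,
            modal_bin = report@modalBin,
            cutoff_bin = if (is.na(report@cutoffBin)) NULL else report@cutoffBin,
            removed = report@removed, kept = report@kept)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
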