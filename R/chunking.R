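# Query chunking: long query sequences are split into fixed-size chunks
# (10 Mb by default) before alignment to bound aligner memory; alignments
# against chunks are then lifted back to original coordinates and
# contiguous chunk alignments are rejoined. Only the query side is ever
# chunked.

CHUNK_SEP <- "_###_"
DEFAULT_CHUNK_SIZE <- 1e7

chunkName <- function(name, index) paste0(name, CHUNK_SEP, index)

#' Split a catalog into fixed-size chunks
#'
#' Each sequence of length L becomes `ceiling(L / chunkSize)` chunks;
#' chunk i (from 0) covers bases `[i * chunkSize, min((i+1) * chunkSize, L))`
#' and is named `<original>_###_<i>`. Sequences not longer than
#' `chunkSize` pass through with their original name (offset 0).
#'
#' @param catalog A [SequenceCatalog-class].
#' @param chunkSize Chunk size in bases (default 10 Mb).
#' @return A list with elements `catalog` (the chunked
#'   [SequenceCatalog-class]) and `map` (a [ChunkMap-class]).
#' @export
splitCatalog <- function(catalog, chunkSize = DEFAULT_CHUNK_SIZE) {
  stopifnot(chunkSize >= 1)
  nms <- catalog@seqnames
  lens <- catalog@seqlengths
  if (any(grepl(CHUNK_SEP, nms, fixed = TRUE)))
    stop("sequence names may not contain the chunk separator '",
         CHUNK_SEP, "'", call. = FALSE)
  chunk_names <- character(); orig <- character()
  offs <- numeric(); clens <- numeric(); olens <- numeric()
  for (i in seq_along(nms)) {
    L <- lens[i]
    if (L <= chunkSize) {
      chunk_names <- c(chunk_names, nms[i]); orig <- c(orig, nms[i])
      offs <- c(offs, 0); clens <- c(clens, L); olens <- c(olens, L)
    } else {
      k <- ceiling(L / chunkSize)
      idx <- seq_len(k) - 1
      starts <- idx * chunkSize
      chunk_names <- c(chunk_names, chunkName(nms[i], idx))
      orig <- c(orig, rep(nms[i], k))
      offs <- c(offs, starts)
      clens <- c(clens, pmin(starts + chunkSize, L) - starts)
      olens <- c(olens, rep(L, k))
    }
  }
  list(catalog = SequenceCatalog(chunk_names, clens),
       map = new("ChunkMap", chunkSize = chunkSize, chunkNames = chunk_names,
                 originalNames = orig, offsets = offs,
                 originalLengths = olens))
}

#' Split a FASTA file into chunked records
#'
#' Materialises [splitCatalog()]: writes one FASTA record per chunk,
#' residues exactly the original slice, so that concatenating the chunks
#' of a sequence in offset order reproduces it.
#'
#' @param infile Input FASTA path (plain or gzip).
#' @param outfile Output FASTA path.
#' @param chunkSize Chunk size in bases.
#' @return The [ChunkMap-class], invisibly carrying the output path as
#'   attribute `path`.
#' @export
splitFasta <- function(infile, outfile, chunkSize = DEFAULT_CHUNK_SIZE) {
  catalog <- readCatalog(infile)   # errors on empty/duplicate input
  seqs <- Biostrings::readDNAStringSet(infile)
  names(seqs) <- sub("[ \t].*$", "", names(seqs))
  split <- splitCatalog(catalog, chunkSize)
  map <- split$map
  out <- Biostrings::DNAStringSet(lapply(seq_along(map@chunkNames), function(i) {
    Biostrings::subseq(seqs[[map@originalNames[i]]],
                       start = map@offsets[i] + 1,
                       width = split$catalog@seqlengths[i])
  }))
  names(out) <- map@chunkNames
  Biostrings::writeXStringSet(out, outfile)
  attr(map, "path") <- outfile
  invisible(map)
}

#' Lift chunk-coordinate matches back to original coordinates
#'
#' Replaces each chunk query name by the original sequence name, shifts
#' `qstart`/`qend` by the chunk offset and restores the full original
#' query length. Target fields are untouched. Query names absent from
#' the map but carrying no chunk suffix are passed through unchanged
#' (unsplit sequences).
#'
#' @param matches A match table with chunk-level query coordinates.
#' @param map The [ChunkMap-class] from [splitCatalog()]/[splitFasta()].
#' @return A match table in original query coordinates.
#' @export
unchunk <- function(matches, map) {
  validateMatches(matches, "unchunk")
  if (!nrow(matches)) return(matches)
  idx <- match(matches$qname, map@chunkNames)
  unknown <- is.na(idx) & grepl(CHUNK_SEP, matches$qname, fixed = TRUE)
  if (any(unknown))
    stop("unknown chunk name: ", matches$qname[which(unknown)[1]],
         call. = FALSE)
  hit <- !is.na(idx)
  matches$qstart[hit] <- matches$qstart[hit] + map@offsets[idx[hit]]
  matches$qend[hit] <- matches$qend[hit] + map@offsets[idx[hit]]
  matches$qlen[hit] <- map@originalLengths[idx[hit]]
  matches$qname[hit] <- map@originalNames[idx[hit]]
  validateMatches(matches, "unchunk output")
  matches
}

#' Project original-coordinate matches into chunk coordinates
#'
#' The inverse of [unchunk()] for collinear (diagonal) matches: splits
#' each match at chunk boundaries of its query and expresses the pieces
#' in chunk-local coordinates, the way a per-chunk aligner run would
#' report them. `nmatch` and `blocklen` are apportioned to pieces in
#' proportion to their query span, with rounding corrected so totals are
#' conserved. Intended for stitching tests and for preparing expected
#' chunk-level alignments; assumes query and target advance together
#' within a match.
#'
#' @param matches A match table in original coordinates.
#' @param map A [ChunkMap-class].
#' @return A match table in chunk coordinates.
#' @export
chunkMatches <- function(matches, map) {
  validateMatches(matches, "chunkMatches")
  if (!nrow(matches)) return(matches)
  cs <- map@chunkSize
  pieces <- lapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    if (!(m$qname %in% map@originalNames)) return(m)
    lo <- ceiling(m$qstart / cs); hi <- floor(m$qend / cs)
    bnds <- if (hi >= lo) seq(lo, hi) * cs else numeric(0)
    cuts <- unique(c(m$qstart, bnds, m$qend))
    cuts <- sort(cuts[cuts >= m$qstart & cuts <= m$qend])
    a <- head(cuts, -1); b <- tail(cuts, -1)
    keep <- b > a
    a <- a[keep]; b <- b[keep]
    span <- b - a
    nm <- apportion(m$nmatch, span)
    bl <- apportion(m$blocklen, span)
    bl <- pmax(bl, 1)
    ci <- floor(a / cs)            # chunk index per piece
    qlen_orig <- m$qlen
    single <- qlen_orig <= cs      # unsplit sequence keeps its name
    cname <- if (single) m$qname else chunkName(m$qname, ci)
    coff <- ci * cs
    clen <- pmin(coff + cs, qlen_orig) - coff
    if (single) { coff <- rep(0, length(a)); clen <- rep(qlen_orig, length(a)) }
    if (m$strand == "+") {
      ts <- m$tstart + (a - m$qstart); te <- m$tstart + (b - m$qstart)
    } else {
      ts <- m$tstart + (m$qend - b); te <- m$tstart + (m$qend - a)
    }
    matchTable(qname = cname, qlen = clen, qstart = a - coff, qend = b - coff,
               strand = m$strand, tname = m$tname, tlen = m$tlen,
               tstart = ts, tend = te, nmatch = nm, blocklen = bl,
               mapq = m$mapq, tags = m$tags)
  })
  do.call(rbind, pieces)
}

apportion <- function(total, weights) {
  if (length(weights) == 1) return(total)
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  short <- round(total - sum(out))
  if (short > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(short)]] <- out[ord[seq_len(short)]] + 1
  }
  out
}

#' Merge contiguous chunk alignments
#'
#' Rejoins matches that were split at chunk boundaries: two matches
#' sharing query name, target name and strand are merged when the second
#' continues the first within `gapTolerance` bases on both axes (on the
#' reverse strand the target runs in decreasing coordinates as the query
#' advances). Merging is transitive after sorting candidates by query
#' start; the merged match spans the union on both axes and sums
#' `nmatch` and `blocklen` (identity is recomputed from the sums).
#'
#' @param matches A match table in original (unchunked) coordinates.
#' @param gapTolerance Maximum absolute gap/overlap in bases allowed on
#'   each axis at the junction (default 0: exact contiguity).
#' @return A match table with contiguous runs merged.
#' @export
mergeContiguous <- function(matches, gapTolerance = 0) {
  validateMatches(matches, "mergeContiguous")
  if (nrow(matches) < 2) return(matches)
  key <- paste(matches$qname, matches$tname, matches$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(matches)), key), function(idx) {
    g <- matches[idx[order(matches$qstart[idx], matches$tstart[idx])], ]
    if (nrow(g) == 1) return(g)
    merged <- g[1, ]
    res <- list()
    for (i in 2:nrow(g)) {
      nxt <- g[i, ]
      qgap <- nxt$qstart - merged$qend
      tgap <- if (merged$strand == "+") nxt$tstart - merged$tend
              else merged$tstart - nxt$tend
      if (abs(qgap) <= gapTolerance && abs(tgap) <= gapTolerance) {
        merged$qend <- max(merged$qend, nxt$qend)
        merged$qstart <- min(merged$qstart, nxt$qstart)
        merged$tstart <- min(merged$tstart, nxt$tstart)
        merged$tend <- max(merged$tend, nxt$tend)
        merged$nmatch <- merged$nmatch + nxt$nmatch
        merged$blocklen <- merged$blocklen + nxt$blocklen
        merged$identity <- merged$nmatch / merged$blocklen
      } else {
        res[[length(res) + 1]] <- merged
        merged <- nxt
      }
    }
    res[[length(res) + 1]] <- merged
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # restore a stable overall order: by query name then query start
  out[order(match(out$qname, unique(matches$qname)), out$qstart, out$tstart), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write / read a ChunkMap as TSV
#'
#' Serialises the chunk map as a 4-column TSV (chunk name, original
#' name, offset, original length) so external aligner runs over a split
#' FASTA can be stitched later.
#'
#' @param map A [ChunkMap-class].
#' @param path TSV path.
#' @return `writeChunkMap`: the path, invisibly. `readChunkMap`: the map.
#' @export
writeChunkMap <- function(map, path) {
  df <- data.frame(chunk = map@chunkNames, original = map@originalNames,
                   offset = format(map@offsets, scientific = FALSE, trim = TRUE),
                   length = format(map@originalLengths, scientific = FALSE,
                                   trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeChunkMap
#' @param chunkSize Chunk size to record when reading (default 10 Mb).
#' @export
readChunkMap <- function(path, chunkSize = DEFAULT_CHUNK_SIZE) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "numeric"))
  new("ChunkMap", chunkSize = chunkSize, chunkNames = df$chunk,
      originalNames = df$original, offsets = df$offset,
      originalLengths = df$length)
}
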