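# Sequence and archive exports: the sorted query FASTA (reverse-
# complementing reversed queries), unaligned sequences for either axis,
# and the three-file backup archive that reconstructs a plot.

#' Export query sequences reorganised along the reference
#'
#' Writes the query records in sort-plan order; queries with reverse
#' orientation are written as their reverse complement (IUPAC-aware)
#' with `(reversed)` noted in the record description.
#'
#' @param queryFasta Path to the query FASTA (plain or gzip) covering
#'   every query of the plan.
#' @param plan A [SortPlan-class].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
exportSortedFasta <- function(queryFasta, plan, path) {
  seqs <- Biostrings::readDNAStringSet(queryFasta)
  names(seqs) <- sub("[ \t].*$", "", names(seqs))
  missing <- setdiff(plan@queries, names(seqs))
  if (length(missing))
    stop("sequence missing from ", queryFasta, ": ", missing[1],
         call. = FALSE)
  out <- seqs[plan@queries]
  rev <- plan@orientations == "reverse"
  if (any(rev)) {
    out[rev] <- Biostrings::reverseComplement(out[rev])
    names(out)[rev] <- paste0(names(out)[rev], " (reversed)")
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Export sequences that appear in no match
#'
#' Writes every catalogued sequence absent from the match list (the
#' raw, pre-filter list should be passed). Works for either axis: pass
#' the query catalog with `axis = "query"` or the target catalog with
#' `axis = "target"`.
#'
#' @param catalog The [SequenceCatalog-class] of the axis.
#' @param matches The match table.
#' @param fasta FASTA path holding the axis sequences.
#' @param path Output FASTA path.
#' @param axis `"query"` or `"target"`: which match column to check.
#' @return Character vector of unaligned sequence names, invisibly.
#' @export
exportUnaligned <- function(catalog, matches, fasta, path,
                            axis = c("query", "target")) {
  axis <- match.arg(axis)
  aligned <- unique(if (axis == "query") matches$qname else matches$tname)
  unaligned <- setdiff(catalog@seqnames, aligned)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("[ \t].*$", "", names(seqs))
  Biostrings::writeXStringSet(seqs[intersect(names(seqs), unaligned)], path)
  invisible(unaligned)
}

BACKUP_MEMBERS <- c(query = "query.fasta", target = "target.fasta",
                    alignment = "alignment.paf")

#' Backup archive round-trip
#'
#' `makeBackup()` bundles the query FASTA, target FASTA and PAF file
#' into a tar.gz archive under canonical member names (`query.fasta`,
#' `target.fasta`, `alignment.paf`; a `.gz` suffix is kept for
#' gzip-compressed FASTA members). `loadBackup()` extracts and
#' validates an archive and rebuilds the [DotPlot-class].
#'
#' @param queryFasta,targetFasta,paf Input file paths.
#' @param archive Archive path (tar.gz).
#' @return `makeBackup()`: the archive path, invisibly.
#'   `loadBackup()`: a list with `plot` ([DotPlot-class]) and the paths
#'   `query`, `target`, `alignment` of the extracted members.
#' @export
makeBackup <- function(queryFasta, targetFasta, paf, archive) {
  for (f in c(queryFasta, targetFasta, paf))
    if (!file.exists(f)) stop("no such file: ", f, call. = FALSE)
  staging <- tempfile("backup-staging-")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE))
  member <- function(path, canonical) {
    if (isGzip(path)) canonical <- paste0(canonical, ".gz")
    file.copy(path, file.path(staging, canonical))
    canonical
  }
  members <- c(member(queryFasta, BACKUP_MEMBERS[["query"]]),
               member(targetFasta, BACKUP_MEMBERS[["target"]]),
               member(paf, BACKUP_MEMBERS[["alignment"]]))
  old <- setwd(staging)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  archive_abs <- if (startsWith(archive, "/")) archive
                 else file.path(old, archive)
  utils::tar(archive_abs, files = members, compression = "gzip",
             tar = "internal")
  invisible(archive)
}

#' @rdname makeBackup
#' @param exdir Directory to extract into (a fresh temporary directory
#'   by default).
#' @export
loadBackup <- function(archive, exdir = tempfile("backup-")) {
  dir.create(exdir, showWarnings = FALSE, recursive = TRUE)
  utils::untar(archive, exdir = exdir, tar = "internal")
  found <- list.files(exdir)
  locate <- function(canonical) {
    hit <- found[found %in% c(canonical, paste0(canonical, ".gz"))]
    if (!length(hit))
      stop("backup archive is missing member '", canonical, "'",
           call. = FALSE)
    file.path(exdir, hit[1])
  }
  qpath <- locate(BACKUP_MEMBERS[["query"]])
  tpath <- locate(BACKUP_MEMBERS[["target"]])
  apath <- locate(BACKUP_MEMBERS[["alignment"]])
  plot <- buildDotPlot(readPaf(apath), readCatalog(qpath),
                       readCatalog(tpath))
  list(plot = plot, query = qpath, target = tpath, alignment = apath)
}
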