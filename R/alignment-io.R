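# Readers and writers for the alignment and sequence-catalog formats the
# tool touches: PAF, MAF, FASTA (plain or gzip) and samtools-style .fai.
# Coordinates are 0-based half-open everywhere internally (the PAF
# convention); MAF minus-strand coordinates are converted at parse time.

readSourceLines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    con <- if (isGzip(x)) gzfile(x, "rt") else file(x, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  as.character(x)
}

isGzip <- function(path) {
  magic <- readBin(path, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a PAF alignment file
#'
#' Parses Pairwise mApping Format records (12 mandatory tab-separated
#' columns, 0-based half-open coordinates). Identity is computed as
#' column 10 / column 11 (residue matches over alignment block length).
#' Optional SAM-style tag columns beyond column 12 are preserved as
#' opaque text and written back verbatim by [writePaf()].
#'
#' @param x Path to a PAF file (optionally gzip-compressed), a
#'   connection, or a character vector of PAF lines.
#' @return A match table (see [matchTable()]) with one row per input
#'   line, input order preserved.
#' @seealso [writePaf()], [readMaf()], [readAlignment()]
#' @export
readPaf <- function(x) {
  lines <- readSourceLines(x)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(emptyMatchTable())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("PAF format error: line ", lineno[which(nf < 12)[1]],
         " has ", nf[which(nf < 12)[1]], " fields (>= 12 required)",
         call. = FALSE)
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  numcol <- function(i, what) {
    v <- suppressWarnings(as.numeric(getcol(i)))
    raw <- getcol(i)
    bad <- is.na(v) | v != floor(v) | !grepl("^[0-9]+$", raw)
    if (any(bad))
      stop("PAF format error: non-integer ", what, " '", raw[which(bad)[1]],
           "' at line ", lineno[which(bad)[1]], call. = FALSE)
    v
  }
  qstart <- numcol(3, "query start"); qend <- numcol(4, "query end")
  if (any(qend <= qstart))
    stop("PAF format error: query end <= query start at line ",
         lineno[which(qend <= qstart)[1]], call. = FALSE)
  strand <- getcol(5)
  if (!all(strand %in% c("+", "-")))
    stop("PAF format error: bad strand at line ",
         lineno[which(!strand %in% c("+", "-"))[1]], call. = FALSE)
  tags <- vapply(fields, function(f)
    if (length(f) > 12) paste(f[-(1:12)], collapse = "\t") else "",
    character(1))
  matchTable(
    qname = getcol(1), qlen = numcol(2, "query length"),
    qstart = qstart, qend = qend, strand = strand,
    tname = getcol(6), tlen = numcol(7, "target length"),
    tstart = numcol(8, "target start"), tend = numcol(9, "target end"),
    nmatch = numcol(10, "match count"), blocklen = numcol(11, "block length"),
    mapq = numcol(12, "mapping quality"), tags = tags)
}

#' Write a match table as PAF
#'
#' Emits the 12 mandatory columns plus any preserved tag columns; a
#' parse/write round-trip reproduces the mandatory columns byte for
#' byte.
#'
#' @param matches A match table.
#' @param path Output file path or connection.
#' @return Invisibly, the path.
#' @export
writePaf <- function(matches, path) {
  validateMatches(matches, "writePaf")
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  if (nrow(matches)) {
    lines <- paste(matches$qname, fmt(matches$qlen), fmt(matches$qstart),
                   fmt(matches$qend), matches$strand, matches$tname,
                   fmt(matches$tlen), fmt(matches$tstart), fmt(matches$tend),
                   fmt(matches$nmatch), fmt(matches$blocklen),
                   fmt(matches$mapq), sep = "\t")
    has_tags <- nzchar(matches$tags)
    lines[has_tags] <- paste(lines[has_tags], matches$tags[has_tags],
                             sep = "\t")
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF pairwise alignment file
#'
#' Converts pairwise Multiple Alignment Format blocks (an "a" line
#' followed by exactly two "s" lines; first s-line target, second query
#' -- the convention of pairwise aligners) to the internal match model.
#' MAF minus-strand coordinates, which are given relative to the
#' reverse-complemented source, are converted to forward coordinates via
#' `start_fwd = srcSize - start - size`. `nmatch` counts identical
#' aligned non-gap column pairs and `blocklen` counts aligned columns.
#'
#' @param x Path, connection or character vector of MAF lines.
#' @return A match table, one row per alignment block.
#' @export
readMaf <- function(x) {
  lines <- readSourceLines(x)
  lines <- lines[!grepl("^#", lines)]
  out <- list()
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!startsWith(line, "a")) { i <- i + 1L; next }
    block <- block + 1L
    s_lines <- character()
    j <- i + 1L
    while (j <= length(lines)) {
      l2 <- trimws(lines[j])
      if (startsWith(l2, "s ")) s_lines <- c(s_lines, l2)
      else if (startsWith(l2, "a") || l2 == "") break
      j <- j + 1L
    }
    if (length(s_lines) != 2)
      stop("MAF format error: block ", block, " has ", length(s_lines),
           " s-lines (pairwise blocks require exactly 2)", call. = FALSE)
    tgt <- parseMafS(s_lines[1], block)
    qry <- parseMafS(s_lines[2], block)
    if (nchar(tgt$text) != nchar(qry$text))
      stop("MAF format error: block ", block,
           " alignment texts differ in length", call. = FALSE)
    tchars <- strsplit(toupper(tgt$text), "", fixed = TRUE)[[1]]
    qchars <- strsplit(toupper(qry$text), "", fixed = TRUE)[[1]]
    nmatch <- sum(tchars == qchars & tchars != "-")
    blocklen <- length(tchars)
    tc <- mafForwardCoords(tgt)
    qc <- mafForwardCoords(qry)
    out[[block]] <- matchTable(
      qname = qry$name, qlen = qry$srcSize, qstart = qc[1], qend = qc[2],
      strand = if (tgt$strand == qry$strand) "+" else "-",
      tname = tgt$name, tlen = tgt$srcSize, tstart = tc[1], tend = tc[2],
      nmatch = nmatch, blocklen = blocklen, mapq = 255)
    i <- j
  }
  if (!length(out)) return(emptyMatchTable())
  do.call(rbind, out)
}

parseMafS <- function(line, block) {
  f <- strsplit(line, "[ \t]+")[[1]]
  if (length(f) < 7)
    stop("MAF format error: malformed s-line in block ", block, call. = FALSE)
  list(name = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
       strand = f[5], srcSize = as.numeric(f[6]), text = f[7])
}

mafForwardCoords <- function(s) {
  if (s$strand == "-") {
    start <- s$srcSize - s$start - s$size
  } else {
    start <- s$start
  }
  c(start, start + s$size)
}

#' Read a sequence catalog from FASTA or FASTA index
#'
#' Accepts plain FASTA, gzip-compressed FASTA (detected by the gzip
#' magic bytes, not the extension), or a samtools-style 5-column `.fai`
#' (only columns 1-2 consumed). Names and lengths are returned in file
#' order; FASTA lengths count residues ignoring whitespace.
#'
#' @param path Path to the FASTA or .fai file.
#' @return A [SequenceCatalog-class].
#' @export
readCatalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty sequence file: ", path, call. = FALSE)
  first <- peekFirstChar(path)
  if (identical(first, ">")) {
    lens <- Biostrings::fasta.seqlengths(path)
    if (!length(lens)) stop("no sequences in FASTA file: ", path, call. = FALSE)
    nms <- sub("[ \t].*$", "", names(lens))
    if (anyDuplicated(nms))
      stop("duplicate sequence name in ", path, ": ",
           nms[duplicated(nms)][1], call. = FALSE)
    return(SequenceCatalog(nms, as.numeric(lens)))
  }
  fai <- read.table(path, sep = "\t", header = FALSE, comment.char = "",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(fai) < 2)
    stop("not a FASTA or .fai file: ", path, call. = FALSE)
  nms <- fai[[1]]
  if (anyDuplicated(nms))
    stop("duplicate sequence name in ", path, ": ",
         nms[duplicated(nms)][1], call. = FALSE)
  SequenceCatalog(nms, as.numeric(fai[[2]]))
}

peekFirstChar <- function(path) {
  con <- if (isGzip(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  b <- readBin(con, "raw", 1)
  if (!length(b)) return("")
  rawToChar(b)
}

# ---- pluggable alignment-format registry --------------------------------

formatRegistry <- new.env(parent = emptyenv())

#' Register an alignment file format
#'
#' Extends the set of alignment formats accepted by [readAlignment()]
#' (and the command-line `plot` mode). A format is keyed by its file
#' extension and supplies a validator predicate and a converter that
#' turns the file into a match table. `"paf"` and `"maf"` are built in.
#'
#' @param extension File extension (without dot), e.g. `"xyz"`.
#' @param validator Function(path) returning `TRUE` when the file is in
#'   this format.
#' @param converter Function(path) returning a match table.
#' @return Invisibly, the extension.
#' @examples
#' \dontrun{
#' registerFormat("tab", function(p) TRUE, function(p) readPaf(p))
#' }
#' @export
registerFormat <- function(extension, validator, converter) {
  extension <- tolower(extension)
  if (exists(extension, envir = formatRegistry, inherits = FALSE))
    stop("format already registered: ", extension, call. = FALSE)
  stopifnot(is.function(validator), is.function(converter))
  assign(extension, list(validator = validator, converter = converter),
         envir = formatRegistry)
  invisible(extension)
}

#' @rdname registerFormat
#' @export
registeredFormats <- function() sort(ls(formatRegistry))

resetFormats <- function() {
  rm(list = ls(formatRegistry), envir = formatRegistry)
  registerFormat("paf", function(path) {
    lines <- readSourceLines(path)
    lines <- lines[nzchar(trimws(lines))]
    length(lines) == 0 ||
      all(lengths(strsplit(lines, "\t", fixed = TRUE)) >= 12)
  }, readPaf)
  registerFormat("maf", function(path) {
    lines <- readSourceLines(path)
    lines <- trimws(lines[nzchar(trimws(lines))])
    length(lines) == 0 || any(grepl("^(##maf|a\\b|a$)", lines))
  }, readMaf)
}
resetFormats()

#' Read an alignment file of any registered format
#'
#' Dispatches on the file extension (a trailing `.gz` is ignored),
#' validates the file with the registered predicate, then converts it to
#' a match table.
#'
#' @param path Path to the alignment file.
#' @param format Optional explicit format name overriding the extension.
#' @return A match table.
#' @export
readAlignment <- function(path, format = NULL) {
  ext <- tolower(format %||% alignmentExtension(path))
  if (!exists(ext, envir = formatRegistry, inherits = FALSE))
    stop("unsupported alignment format '", ext, "'; known formats: ",
         paste(registeredFormats(), collapse = ", "), call. = FALSE)
  entry <- get(ext, envir = formatRegistry)
  if (!isTRUE(entry$validator(path)))
    stop("file ", path, " failed validation for format '", ext, "'",
         call. = FALSE)
  entry$converter(path)
}

alignmentExtension <- function(path) {
  ext <- tools::file_ext(path)
  if (tolower(ext) == "gz")
    ext <- tools::file_ext(sub("\\.gz$", "", path, ignore.case = TRUE))
  ext
}

`%||%` <- function(a, b) if (is.null(a)) b else a
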