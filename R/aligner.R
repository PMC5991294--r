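# Thin optional wrapper around an external aligner. The aligner is
# configured through a small YAML tools file (executable, command
# skeleton, threads, memory cap) and invoked with its default
# parameters; nothing downstream depends on it being present.

#' Read an aligner tools configuration
#'
#' Parses a YAML tools file describing available aligners. Each entry
#' names an executable, a command skeleton with `{query}`, `{target}`,
#' `{threads}` and `{out}` placeholders, and optional thread and memory
#' caps.
#'
#' @param path YAML file path. A built-in configuration for minimap2 is
#'   used when omitted.
#' @return Named list of tool definitions.
#' @export
readToolsConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("tools", "tools.yaml", package = "GenomeDotplot")
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("empty tools configuration: ", path, call. = FALSE)
  for (nm in names(cfg)) {
    if (is.null(cfg[[nm]]$exec) || is.null(cfg[[nm]]$command))
      stop("tool '", nm, "' must define 'exec' and 'command'",
           call. = FALSE)
  }
  cfg
}

#' Align query against target with minimap2
#'
#' Invokes the external minimap2 executable (with its default alignment
#' parameters) on the given FASTA files and returns the path of the PAF
#' it wrote. Chunk the query first with [splitFasta()] to bound memory;
#' lift coordinates back with [unchunk()] and [mergeContiguous()].
#'
#' @param query,target FASTA paths.
#' @param out Output PAF path.
#' @param tool Tool name in the configuration (default `"minimap2"`).
#' @param config Tools configuration from [readToolsConfig()].
#' @param threads Thread count (capped by the configuration).
#' @return The PAF path, invisibly.
#' @export
runMinimap2 <- function(query, target, out = tempfile(fileext = ".paf"),
                        tool = "minimap2", config = readToolsConfig(),
                        threads = 1L) {
  if (!tool %in% names(config))
    stop("tool '", tool, "' not present in the tools configuration",
         call. = FALSE)
  def <- config[[tool]]
  exec <- Sys.which(def$exec)
  if (!nzchar(exec))
    stop("aligner executable '", def$exec, "' not found on PATH; ",
         "install it or use the plot mode with a precomputed PAF/MAF file",
         call. = FALSE)
  if (!is.null(def$threads)) threads <- min(threads, def$threads)
  cmd <- def$command
  cmd <- gsub("{query}", shQuote(query), cmd, fixed = TRUE)
  cmd <- gsub("{target}", shQuote(target), cmd, fixed = TRUE)
  cmd <- gsub("{threads}", as.character(threads), cmd, fixed = TRUE)
  cmd <- gsub("{out}", shQuote(out), cmd, fixed = TRUE)
  args <- strsplit(cmd, " +")[[1]]
  errfile <- tempfile("aligner-stderr-")
  status <- suppressWarnings(
    system2(exec, args, stdout = out, stderr = errfile))
  if (!is.null(status) && status != 0) {
    err <- tryCatch(readLines(errfile, warn = FALSE), error = function(e) "")
    stop("aligner failed (exit ", status, "): ",
         paste(utils::tail(err, 3), collapse = " | "), call. = FALSE)
  }
  invisible(out)
}
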