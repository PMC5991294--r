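# Shared builders for tests: small catalogs, random-but-valid match
# tables, and toy FASTA files written on the fly.

toyCatalogs <- function(qlens = c(q1 = 1000, q2 = 800),
                        tlens = c(t1 = 2000, t2 = 1500)) {
  list(query = SequenceCatalog(names(qlens), qlens),
       target = SequenceCatalog(names(tlens), tlens))
}

# n random valid matches over the given catalogs
randomMatches <- function(n, query, target, seed = NULL,
                          blocklenRange = c(10, 500)) {
  if (!is.null(seed)) set.seed(seed)
  qlens <- catalogLengths(query)
  tlens <- catalogLengths(target)
  qn <- sample(names(qlens), n, replace = TRUE)
  tn <- sample(names(tlens), n, replace = TRUE)
  span <- pmin(floor(runif(n, blocklenRange[1], blocklenRange[2])),
               qlens[qn] - 1, tlens[tn] - 1)
  span <- pmax(span, 1)
  qs <- floor(runif(n) * (qlens[qn] - span))
  ts <- floor(runif(n) * (tlens[tn] - span))
  bl <- pmax(span, 1)
  nm <- pmax(1, floor(bl * runif(n)))
  matchTable(qname = qn, qlen = qlens[qn], qstart = qs, qend = qs + span,
             strand = sample(c("+", "-"), n, replace = TRUE),
             tname = tn, tlen = tlens[tn], tstart = ts, tend = ts + span,
             nmatch = nm, blocklen = bl)
}

writeToyFasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                          width = 60) {
  con <- file(path, "wt")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  path
}

gzipCopy <- function(path, out = tempfile(fileext = ".gz")) {
  con <- gzfile(out, "wb")
  writeLines(readLines(path), con)
  close(con)
  out
}

# A plot with a planted rearrangement, built from the fixture generator
fixturePlot <- function(plan) {
  pair <- generatePair(plan)
  query <- SequenceCatalog(names(pair$query), Biostrings::width(pair$query))
  target <- SequenceCatalog(names(pair$reference),
                            Biostrings::width(pair$reference))
  list(plot = buildDotPlot(pair$truth, query, target), pair = pair)
}

# literal per-base array oracle for the reference identity profile,
# applying the same sort / include-removal / noise-filter pipeline
perBaseProfile <- function(plot) {
  work <- applySort(plot)
  m <- noiseFilter(removeIncluded(plotMatches(work)))$matches
  lens <- catalogLengths(targetCatalog(plot))
  counts <- numeric(4)
  for (tname in names(lens)) {
    best <- integer(lens[[tname]])    # 0 = uncovered
    for (i in which(m$tname == tname)) {
      idx <- (m$tstart[i] + 1):m$tend[i]
      best[idx] <- pmax(best[idx], identityClass(m$identity[i]))
    }
    for (k in 1:4) counts[k] <- counts[k] + sum(best == k)
  }
  c(counts, sum(lens) - sum(counts)) / sum(lens)
}
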