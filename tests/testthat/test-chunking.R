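# Chunk splitting, coordinate lifting, and rejoining of contiguous
# chunk alignments.

test_that("splitCatalog produces ceiling(L/chunk) chunks with exact covers", {
  cat0 <- SequenceCatalog(c("big", "edge", "tiny"), c(25e6, 10e6, 1))
  sp <- splitCatalog(cat0, 1e7)
  expect_equal(names(sp$catalog),
               c("big_###_0", "big_###_1", "big_###_2", "edge", "tiny"))
  expect_equal(unname(catalogLengths(sp$catalog)), c(1e7, 1e7, 5e6, 1e7, 1))
  expect_equal(sp$map@offsets[1:3], c(0, 1e7, 2e7))
  # conservation of total bases
  expect_equal(sum(catalogLengths(sp$catalog)), sum(catalogLengths(cat0)))
})

test_that("splitFasta slices residues exactly and concatenation restores them", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  fa <- writeToyFasta(list(chrA = s, small = "ACGT"))
  out <- tempfile(fileext = ".fasta")
  map <- splitFasta(fa, out, chunkSize = 10)
  chunks <- Biostrings::readDNAStringSet(out)
  expect_equal(unname(Biostrings::width(chunks)), c(10, 10, 5, 4))
  expect_equal(paste(as.character(chunks[1:3]), collapse = ""), s)
  expect_equal(as.character(chunks[["small"]]), "ACGT")
  expect_error(splitFasta(tempfile(), out), "no such file")
})

test_that("unchunk shifts query coordinates by the chunk offset only", {
  cat0 <- SequenceCatalog("c", 25e6)
  sp <- splitCatalog(cat0, 1e7)
  m <- matchTable(qname = "c_###_1", qlen = 1e7, qstart = 5, qend = 50,
                  strand = "+", tname = "t", tlen = 1e6, tstart = 100,
                  tend = 145, nmatch = 40, blocklen = 45)
  u <- unchunk(m, sp$map)
  expect_equal(u$qname, "c")
  expect_equal(u$qstart, 1e7 + 5)
  expect_equal(u$qend, 1e7 + 50)
  expect_equal(u$qlen, 25e6)
  expect_equal(u[, c("tstart", "tend", "nmatch")], m[, c("tstart", "tend", "nmatch")])
  # chunk 0: name restored, coordinates unchanged
  m0 <- m; m0$qname <- "c_###_0"
  u0 <- unchunk(m0, sp$map)
  expect_equal(u0$qstart, 5)
  expect_error(unchunk({m$qname <- "d_###_9"; m}, sp$map), "unknown chunk")
})

test_that("chunk round-trip is exact and idempotent on fixture coordinates", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    lens <- floor(runif(3, 1e6, 3e7))
    cat0 <- SequenceCatalog(paste0("s", 1:3), lens)
    sp <- splitCatalog(cat0, 1e7)
    span <- floor(lens * 0.8)
    ts <- floor(runif(3, 0, 4e7 - span))
    truth <- matchTable(qname = paste0("s", 1:3), qlen = lens,
                        qstart = floor(lens * 0.1),
                        qend = floor(lens * 0.1) + span,
                        strand = sample(c("+", "-"), 3, replace = TRUE),
                        tname = "t", tlen = 4e7,
                        tstart = ts, tend = ts + span,
                        nmatch = floor(span * 0.9), blocklen = span)
    pieces <- chunkMatches(truth, sp$map)
    lifted <- unchunk(pieces, sp$map)
    expect_identical(unchunk(lifted, sp$map), lifted)  # idempotent
    merged <- mergeContiguous(lifted)
    merged <- merged[order(merged$qname), ]
    truth_o <- truth[order(truth$qname), ]
    rownames(merged) <- rownames(truth_o) <- NULL
    for (col in c("qname", "qstart", "qend", "tstart", "tend", "nmatch",
                  "blocklen"))
      expect_equal(merged[[col]], truth_o[[col]], info = paste("seed", seed, col))
  }
})

test_that("mergeContiguous joins exact-boundary diagonals and sums counts", {
  a <- matchTable(qname = "q", qlen = 2e7, qstart = 0, qend = 1e7,
                  strand = "+", tname = "t", tlen = 2e7, tstart = 0,
                  tend = 1e7, nmatch = 9e6, blocklen = 1e7)
  b <- matchTable(qname = "q", qlen = 2e7, qstart = 1e7, qend = 1.5e7,
                  strand = "+", tname = "t", tlen = 2e7, tstart = 1e7,
                  tend = 1.5e7, nmatch = 4e6, blocklen = 5e6)
  m <- mergeContiguous(rbind(a, b), gapTolerance = 0)
  expect_equal(nrow(m), 1)
  expect_equal(m$qend, 1.5e7); expect_equal(m$tend, 1.5e7)
  expect_equal(m$nmatch, 1.3e7)
  expect_equal(m$blocklen, 1.5e7)
  expect_equal(m$identity, 1.3e7 / 1.5e7)
})

test_that("mergeContiguous refuses strand, target and gap mismatches", {
  a <- matchTable(qname = "q", qlen = 2e7, qstart = 0, qend = 1e7,
                  strand = "+", tname = "t", tlen = 2e7, tstart = 0,
                  tend = 1e7, nmatch = 9e6, blocklen = 1e7)
  b <- a; b$qstart <- 1e7; b$qend <- 1.5e7; b$tstart <- 1e7; b$tend <- 1.5e7
  b_rev <- b; b_rev$strand <- "-"
  expect_equal(nrow(mergeContiguous(rbind(a, b_rev))), 2)
  b_t <- b; b_t$tname <- "t2"
  expect_equal(nrow(mergeContiguous(rbind(a, b_t))), 2)
  b_gap <- b; b_gap$tstart <- 1e7 + 5; b_gap$tend <- 1.5e7 + 5
  expect_equal(nrow(mergeContiguous(rbind(a, b_gap), gapTolerance = 0)), 2)
  expect_equal(nrow(mergeContiguous(rbind(a, b_gap), gapTolerance = 5)), 1)
})

test_that("merging never loses matched bases nor exceeds sequence bounds", {
  caps <- toyCatalogs()
  for (seed in 1:5) {
    m <- randomMatches(60, caps$query, caps$target, seed = 100 + seed)
    out <- mergeContiguous(m, gapTolerance = 3)
    expect_gte(sum(out$nmatch), sum(m$nmatch) - 1e-9)
    expect_true(all(out$qend <= out$qlen & out$qstart >= 0))
    expect_true(all(out$tend <= out$tlen & out$tstart >= 0))
  }
})

test_that("ChunkMap TSV round-trips", {
  sp <- splitCatalog(SequenceCatalog(c("a", "b"), c(2.5e7, 5e6)), 1e7)
  tsv <- tempfile(fileext = ".tsv")
  writeChunkMap(sp$map, tsv)
  back <- readChunkMap(tsv)
  expect_equal(back@chunkNames, sp$map@chunkNames)
  expect_equal(back@offsets, sp$map@offsets)
  expect_equal(back@originalLengths, sp$map@originalLengths)
})
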