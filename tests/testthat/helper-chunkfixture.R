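# Coordinate-level chunking fixture: a catalog of whole-chromosome-
# scale sequences with planted diagonal alignments, used to exercise
# split / lift / merge without materialising megabase sequences.

chunkFixture <- function(seed, minLen = 1e6, maxLen = 3e7) {
  set.seed(seed)
  nseq <- sample(1:3, 1)
  lens <- floor(runif(nseq, minLen, maxLen))
  cat0 <- SequenceCatalog(sprintf("chr%d_s%d", seq_len(nseq), seed), lens)
  span <- floor(lens * runif(nseq, 0.5, 0.9))
  qs <- floor((lens - span) * runif(nseq))
  tlen <- 4e7
  ts <- floor((tlen - span) * runif(nseq))
  truth <- matchTable(qname = names(cat0), qlen = lens, qstart = qs,
                      qend = qs + span,
                      strand = sample(c("+", "-"), nseq, replace = TRUE),
                      tname = "ref", tlen = tlen, tstart = ts,
                      tend = ts + span,
                      nmatch = pmax(1, floor(span * runif(nseq, 0.7, 1))),
                      blocklen = span)
  list(catalog = cat0, truth = truth)
}
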