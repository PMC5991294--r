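# Synthetic genome pairs with planted rearrangements and exact
# ground-truth alignments, so chunking, stitching, sorting and the
# filters can be tested end to end without running an aligner.

#' Describe a planted rearrangement
#'
#' The reference is a single sequence of `nFragments` concatenated
#' random fragments; the query presents one contig per fragment, in
#' `permutation` order, with the `reversed` subset reverse-complemented
#' and point substitutions applied at rate `1 - identity`. Optional
#' small spurious matches emulate aligner noise.
#'
#' @param seed Integer seed; the whole construction is reproducible.
#' @param nFragments Number of fragments.
#' @param fragmentLength Fragment length in bases.
#' @param permutation Integer permutation of `1:nFragments` giving the
#'   query contig order (random when `NULL`).
#' @param reversed Indices of fragments planted in reverse orientation
#'   (random subset when `NULL`).
#' @param identity Per-fragment expected identity in `(0, 1]` (recycled).
#' @param noiseMatches Number of spurious small ground-truth matches to
#'   append.
#' @param noiseSizeRange Block-length range of noise matches.
#' @return A list describing the plan (class `"rearrangementPlan"`).
#' @export
rearrangementPlan <- function(seed = 1L, nFragments = 10L,
                              fragmentLength = 1000L, permutation = NULL,
                              reversed = NULL, identity = 0.95,
                              noiseMatches = 0L,
                              noiseSizeRange = c(20L, 60L)) {
  stopifnot(nFragments >= 1, fragmentLength >= 1,
            all(identity > 0 & identity <= 1))
  set.seed(seed)
  if (is.null(permutation)) permutation <- sample(nFragments)
  if (is.null(reversed))
    reversed <- which(runif(nFragments) < 0.5)
  stopifnot(length(permutation) == nFragments,
            all(sort(permutation) == seq_len(nFragments)))
  structure(list(seed = seed, nFragments = nFragments,
                 fragmentLength = fragmentLength,
                 permutation = as.integer(permutation),
                 reversed = as.integer(reversed),
                 identity = rep_len(identity, nFragments),
                 noiseMatches = noiseMatches,
                 noiseSizeRange = noiseSizeRange),
            class = "rearrangementPlan")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic rearranged genome pair with ground truth
#'
#' Materialises a [rearrangementPlan()]: the reference sequence, the
#' rearranged query contigs, and the exact ground-truth match table
#' (coordinates, strand and realised identity per fragment, plus any
#' requested noise matches).
#'
#' @param plan A [rearrangementPlan()].
#' @param dir Optional directory; when given, `reference.fasta`,
#'   `query.fasta` and `truth.paf` are written there.
#' @return A list with `reference` / `query`
#'   ([Biostrings::DNAStringSet]), `truth` (match table), `plan`, and
#'   (when `dir` is given) the file paths.
#' @export
generatePair <- function(plan, dir = NULL) {
  stopifnot(inherits(plan, "rearrangementPlan"))
  set.seed(plan$seed)
  L <- plan$fragmentLength
  n <- plan$nFragments
  frags <- vapply(seq_len(n), function(i) randomDna(L), character(1))
  reference <- Biostrings::DNAStringSet(paste(frags, collapse = ""))
  names(reference) <- "ref"
  refLen <- n * L
  qseqs <- character(n)
  truth_rows <- vector("list", n)
  for (slot in seq_len(n)) {
    frag_idx <- plan$permutation[slot]
    s <- frags[frag_idx]
    nmut <- rbinom(1, L, 1 - plan$identity[frag_idx])
    if (nmut > 0) {
      pos <- sample(L, nmut)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in pos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      s <- paste(chars, collapse = "")
    }
    is_rev <- frag_idx %in% plan$reversed
    if (is_rev)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    qseqs[slot] <- s
    truth_rows[[slot]] <- matchTable(
      qname = sprintf("frag_%02d", slot), qlen = L, qstart = 0, qend = L,
      strand = if (is_rev) "-" else "+", tname = "ref", tlen = refLen,
      tstart = (frag_idx - 1) * L, tend = frag_idx * L,
      nmatch = L - nmut, blocklen = L)
  }
  truth <- do.call(rbind, truth_rows)
  if (plan$noiseMatches > 0) {
    sz <- sample(seq(plan$noiseSizeRange[1], plan$noiseSizeRange[2]),
                 plan$noiseMatches, replace = TRUE)
    qn <- sprintf("frag_%02d", sample(n, plan$noiseMatches, replace = TRUE))
    qs <- floor(runif(plan$noiseMatches, 0, L - sz))
    ts <- floor(runif(plan$noiseMatches, 0, refLen - sz))
    noise <- matchTable(qname = qn, qlen = L, qstart = qs, qend = qs + sz,
                        strand = sample(c("+", "-"), plan$noiseMatches,
                                        replace = TRUE),
                        tname = "ref", tlen = refLen, tstart = ts,
                        tend = ts + sz, nmatch = pmax(round(sz * 0.5), 1),
                        blocklen = sz)
    truth <- rbind(truth, noise)
  }
  query <- Biostrings::DNAStringSet(qseqs)
  names(query) <- sprintf("frag_%02d", seq_len(n))
  out <- list(reference = reference, query = query, truth = truth,
              plan = plan)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$referencePath <- file.path(dir, "reference.fasta")
    out$queryPath <- file.path(dir, "query.fasta")
    out$truthPath <- file.path(dir, "truth.paf")
    Biostrings::writeXStringSet(reference, out$referencePath)
    Biostrings::writeXStringSet(query, out$queryPath)
    writePaf(truth, out$truthPath)
  }
  out
}
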