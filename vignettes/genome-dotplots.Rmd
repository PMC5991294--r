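---
title: "Methods: building and summarising whole-genome dot plots"
author: "GenomeDotplot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and summarising whole-genome dot plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomeDotplot)
```

# Overview

A dot plot places two sequence sets on orthogonal axes and draws one
diagonal segment per local alignment: forward matches run diagonally,
inversions anti-diagonally. GenomeDotplot implements the analysis layer
behind such plots for whole-genome comparisons: it reads pairwise
alignments (PAF or MAF) and sequence catalogs (FASTA or `.fai`), splits
long query sequences into fixed-size chunks before alignment and
stitches the coordinates back afterwards, filters spurious small
alignments, orders and orients query contigs along the reference,
summarises reference coverage by identity class, and renders static
SVG/PNG figures.

The unit of data is the *match*: one pairwise local alignment with
0-based half-open coordinates on both sequences, a strand, a count of
matching bases (`nmatch`) and an alignment block length (`blocklen`).
Identity is always `nmatch / blocklen` — the only similarity measure
computable from a PAF record (columns 10 and 11) — and the *size* of a
match, wherever a filter refers to size, is its block length.

# Coordinate conventions

All coordinates are 0-based half-open, the PAF convention. MAF blocks
are converted at parse time: a minus-strand MAF interval, which is
reported relative to the reverse-complemented source sequence, becomes
`start_fwd = srcSize - start - size` on the forward strand, so
downstream code sees a single convention. In pairwise MAF blocks the
first `s`-line is taken as the target and the second as the query, the
convention of pairwise aligners; this is documented rather than
configurable.

# Chunking and stitching

Aligning a whole chromosome as one query drives aligner memory up
sharply. `splitCatalog()`/`splitFasta()` therefore cut each query
sequence longer than the chunk size (default 10 Mb) into consecutive
chunks named `<name>_###_<i>`; the separator cannot appear in FASTA
identifiers produced by common assemblers, and the index makes the
original name and offset recoverable. Sequences that fit in one chunk
keep their original name, which avoids churn in downstream outputs.
Only the query side is ever chunked.

After alignment, `unchunk()` lifts chunk coordinates back by integer
offset addition — the round trip is exact — and `mergeContiguous()`
rejoins matches that a chunk boundary cut apart: two matches sharing
query, target and strand are merged when the second continues the
first within `gapTolerance` bases on both axes (target coordinates run
backwards on the reverse strand). The default tolerance is 0, i.e.
exact contiguity at chunk boundaries, because that is what boundary
splitting produces on ideal input; real aligner output is ragged at
boundaries, so the tolerance is exposed as a parameter. A merged match
sums `nmatch` and `blocklen` and recomputes identity from the sums,
which keeps the `identity = nmatch / blocklen` invariant; averaging
identities would not.

# Display rules

Four identity classes drive colouring: `< 25%`, `25–50%`, `50–75%` and
`>= 75%`. The classes partition `[0, 1]`; boundary values are assigned
to the upper class, a choice that prose ranges leave open and that the
tests pin down exhaustively on a grid.

To bound drawing cost, only the 100,000 largest alignments are kept for
display (`capLargest()`); "largest" means block length, ties are broken
stably by input order. On each axis, maximal runs of two or more
successive sequences individually shorter than 0.2% of that axis's
total length are merged into one "super-sequence" group whose margin is
grayed (`layoutAxis()`); the threshold is applied per axis against that
axis's own total. A lone small sequence between large ones stays a
singleton — there is nothing to merge it with.

Self-alignments (reference against itself) produce a trivial
full-length diagonal for every sequence; `removeSelfMatches()` drops
exactly the forward-strand matches of a sequence against itself at
identical positions. Reverse-strand self-overlaps are kept: they are
inverted repeats, not artifacts.

# The noise filter

Spurious small alignments are abundant and cluster at small sizes. The
filter histograms match sizes into `floor(N / 10)` equal-width bins
spanning the observed size range, scans bins in increasing size order
for the first bin of maximal count (the modal bin), then continues
upward for the first bin whose count has fallen to at most 1% of the
modal count. Everything in bins strictly below that cutoff bin is
noise. With fewer than 20 matches the histogram has fewer than two bins
and the procedure is meaningless, so nothing is removed; likewise for a
degenerate size range or when no bin ever falls below the 1% threshold.
The `<=` comparison (rather than `<`) and the plain upward scan are the
package's choices where the procedure's description leaves slack; the
test suite checks the whole procedure against an independently coded
brute-force implementation on randomized inputs of 20–5000 matches.
Re-running the filter on its own output recomputes bins and may remove
more; only the non-increasing-count property is guaranteed and tested.

# Sorting queries along the reference

`computeSortPlan()` assigns each query contig the target sequence
carrying the greatest summed block length of its matches (ties go to
the earlier target in catalog order), orients it by whichever strand
carries more aligned bases to that target (ties forward, for
determinism), and places it at the block-length-weighted mean of its
match midpoints on the target. Queries sort by (target catalog index,
position); unaligned queries follow in input order. Weighting by
matched bases rather than match count makes one long alignment count
for more than many spurious short ones.

`applySort()` mirrors the matches of reverse-oriented queries
(`qstart' = qlen - qend`, strand toggled) — an involution, so
`unsort()` restores the original plot exactly, and plans are expressed
relative to the input orientation so re-sorting a sorted plot is a
no-op. On synthetic genomes built by permuting and reverse-
complementing reference fragments at identity ≥ 0.9, the plan recovers
the planted order and orientation exactly; this is the package's
parameter-recovery test.

# The reference identity profile

`summaryProfile()` reports which fraction of the reference is covered
at each identity class, plus the uncovered fraction. The pipeline runs
on a working copy (the displayed plot is untouched): sort, then remove
matches whose reference interval is contained in another match's
interval on the same target (equal intervals keep the higher identity,
first on ties — containment is judged on the reference axis only,
since the statistic is a reference projection), then noise-filter with
the default parameters. Each reference base is then attributed to the
highest identity class among the matches covering it. Counting each
base once at its best class is the only overlap rule that keeps all
fractions in `[0, 1]` and makes them sum to exactly 1 (bases are
counted as integers and divided once at the end); projection sums that
count overlaps per match could exceed the reference length. The
interval-arithmetic implementation (IRanges set operations) is tested
against a literal per-base array oracle on small targets.

# Rendering

`renderSvg()` writes one `<line>` element per visible match, so figure
structure is verifiable by counting elements; `renderPng()` rasterises
the same scene geometry with a deterministic in-package rasteriser, so
identical inputs give byte-identical files. Six palettes map the four
classes to colours, one deuteranopia-safe; exact colours are
configuration, not contract. By default a match shorter than
`minVisualLength` pixels (1) is padded to that length so it remains
visible; the *strong precision* mode disables the padding so sub-pixel
matches vanish, revealing gaps between non-contiguous matches. This is
implemented as a rendering-time choice, not a deletion from the model.
Margin labels are middle-truncated when a group is too narrow for its
name and omitted entirely when not even a truncated form fits.

# Synthetic data

`generatePair()` builds test genomes with exact ground truth: the
reference is `nFragments` concatenated random fragments (uniform ACGT);
the query has one contig per fragment, permuted, a subset
reverse-complemented, with point substitutions at rate `1 - identity`.
Defaults (10 fragments of 1 kb at identity 0.95, no noise) keep unit
tests fast; recovery tests draw 8–40 fragments at identity 0.9–1.0,
the regime where assignment and orientation are identifiable. The
mutation count per fragment is Binomial(L, 1 − identity), so realised
identity is reproducible under a fixed seed. Mutations are
substitutions only — indels would break exact ground-truth
coordinates — and fragments neither overlap nor repeat, so the
generator does not emulate segmental duplications, tandem repeats or
assembly gaps. Passing tests therefore demonstrate correctness of the
coordinate arithmetic and the selection/ordering logic, not robustness
to repeat-rich real genomes, where assignment ties are genuinely
ambiguous.

Chunk-stitching tests use a coordinate-level fixture instead (catalogs
of 1–30 Mb sequences with planted diagonal matches, projected into
chunk coordinates by `chunkMatches()`), which exercises megabase
arithmetic without materialising megabase strings. Problem sizes
throughout (50 stitching genomes, 200 noise-filter sets up to N = 5000,
100 summary plots, 20 recovery plans) were chosen to exercise each
procedure's branch points while keeping the whole suite in the
tens-of-seconds range.

# External aligner

Alignment itself is delegated to minimap2, invoked with its default
parameters through a small YAML tools file (executable, command
skeleton, thread/memory caps); new aligners are added by editing that
file, and new alignment formats by `registerFormat()`, which pairs a
validator predicate with a converter keyed on the file extension.
Nothing in the analysis layer depends on the aligner being installed:
every procedure runs from precomputed PAF/MAF input, and the aligner
wrapper fails with an actionable message when the executable is
absent.

# Known limitations

* Only the 12 mandatory PAF columns are interpreted; tag columns
  (including `cg`/`cs` CIGAR strings) are preserved opaquely, so
  identity is always columns 10/11 even when a tag would allow a finer
  estimate.
* Nucleic sequences only; protein input is out of scope.
* `chunkMatches()` assumes query and target advance together within a
  match (true for the diagonal fixtures it serves); it is a test and
  stitching aid, not a general liftover.
* The target axis is never sorted, and no optimal-ordering search
  (TSP-style diagonalisation) is attempted.
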