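# GenomeDotplot

Static whole-genome dot plots from pairwise alignments, for anyone
assessing an assembly against a reference or comparing two genomes:
read a PAF or MAF alignment plus the two sequence catalogs (FASTA or
`.fai`), and get back a rendered dot plot, an ordered and oriented
query, a noise-cleaned match set, and a reference identity profile.
Alignment itself is delegated to minimap2 (optional); every analysis
step runs from precomputed alignment files.

## What it computes

A *match* is one local alignment with PAF-style 0-based half-open
coordinates, a strand, `nmatch` matching bases and block length
`blocklen`; identity is `nmatch / blocklen` (PAF columns 10/11).
On top of that single data type the package implements:

* **Chunking** — query sequences longer than 10 Mb are split into
  10 Mb chunks before alignment (bounding aligner memory), then chunk
  coordinates are lifted back by exact integer offsets and matches that
  a boundary cut apart are rejoined when contiguous on both axes,
  summing `nmatch` and `blocklen`.
* **Noise filter** — matches are histogrammed by size into
  `floor(N/10)` equal-width bins; scanning upward from the first
  most-populated bin, the first bin whose count falls to ≤ 1% of the
  modal count is the cutoff, and everything in smaller-size bins is
  discarded.
* **Display rules** — four identity classes (<25%, 25–50%, 50–75%,
  ≥75%) for colouring; only the 100,000 largest alignments are drawn;
  runs of sequences each shorter than 0.2% of an axis are merged into
  grayed super-sequences; trivial self-alignment diagonals are removed
  in self-comparison mode.
* **Query ordering** — each query contig is assigned the reference
  sequence carrying most of its aligned bases, oriented by the dominant
  strand, and placed at the block-length-weighted mean position of its
  matches; sorting is exactly undoable.
* **Identity profile** — the fraction of reference bases whose best
  covering match falls in each identity class (after sorting,
  included-match removal and noise filtering), plus the uncovered
  fraction; fractions sum to 1.
* **Exports** — SVG/PNG dot plots and summary bar graphs, sorted-query
  and unaligned-sequence FASTA, a query→reference association table,
  and a three-file backup archive that reconstructs the plot.

## Worked example

Simulate a rearranged genome pair with ground-truth alignments, then
run the analysis:

```r
library(GenomeDotplot)

plan <- rearrangementPlan(seed = 11, nFragments = 6, fragmentLength = 500,
                          identity = 0.92, noiseMatches = 40)
pair <- generatePair(plan, dir = "example")
plot <- buildDotPlot(readPaf(pair$truthPath),
                     readCatalog(pair$queryPath),
                     readCatalog(pair$referencePath))
plot
#> DotPlot: 46 match(es); query 6 seq(s), target 1 seq(s)

noiseFilter(plotMatches(plot))$report
#> NoiseFilterReport: 4 bin(s); modal bin 1 ; cutoff bin 2 ; 40 removed, 6 kept

summaryProfile(plot)
#> SummaryProfile over 3,000 reference bases
#>   identity < 25%     0.00%
#>   25% - 50%          0.00%
#>   50% - 75%          0.00%
#>   identity >= 75%  100.00%
#>   no match           0.00%
```

The 40 planted spurious matches land in the smallest size bin and are
removed; the 6 real fragment alignments (identity 0.92, class ≥75%)
cover the whole reference, so the profile reports 100% in the top
class. Sorting recovers the planted arrangement — the plan permuted
the fragments as `2 6 4 1 5 3`, so the contigs order as:

```r
associationTable(computeSortPlan(plot))
#>     Query Target
#> 1 frag_04    ref
#> 2 frag_01    ref
#> 3 frag_06    ref
#> 4 frag_03    ref
#> 5 frag_05    ref
#> 6 frag_02    ref
```

Render with `renderSvg(plot, renderOptions(), "dotplot.svg")` or
`renderPng()`; the same pipeline is scriptable from a shell via the
installed entry point:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/dotplot.R",
                                      package="GenomeDotplot"))') \
    plot --alignment aln.paf --query q.fasta --target t.fasta \
    --sort --out out/
```

Subcommands: `align` (chunk → minimap2 → stitch → plot, self-mode when
`--target` is omitted), `plot`, `summary`, `backup`, `simulate`; flags
mirror the display controls (`--min-identity`, `--min-size`,
`--no-noise-filter`, `--sort`, `--reverse QUERY`, `--strong-precision`,
`--color-schema`).

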