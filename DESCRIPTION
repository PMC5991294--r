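Package: GenomeDotplot
Title: Whole-Genome Alignment Dot Plots with Chunking, Filtering and Query Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds static genome-to-genome dot plots from pairwise alignment
    files. Reads PAF and MAF alignments and FASTA or FASTA-index sequence
    catalogs, splits long query sequences into fixed-size chunks before
    alignment and stitches chunk coordinates back together afterwards,
    removes spurious small alignments with a histogram-based noise filter,
    caps plots at the largest alignments, orders and orients query contigs
    along the reference, summarises reference coverage by identity class,
    and exports SVG/PNG figures, sorted or unaligned FASTA sequences,
    association tables and backup archives. An optional wrapper invokes
    minimap2 for alignment; all analysis steps run without it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'alignment-io.R'
    'chunking.R'
    'dotplot.R'
    'filters.R'
    'sort.R'
    'summary.R'
    'render.R'
    'export.R'
    'simulate.R'
    'aligner.R'
    'cli.R'
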