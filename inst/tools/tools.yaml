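# Aligner definitions: executable, command skeleton (PAF on stdout),
# thread and memory caps. Order defines presentation order.
minimap2:
  exec: minimap2
  command: "-t {threads} {target} {query}"
  threads: 4
  max_memory_gb: 40
  label: "Minimap2: fast pairwise alignment of large genomes"
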