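protein: null          # filled in by the caller (path to a FASTA file)
policy:
  vocabulary_file: null # defaults to the shipped toy vocabulary
  table: null           # defaults to the shipped deterministic chain table
  order: 1
objectives: surrogate
c: 1.0
iterations: 100
max_depth: 5
seed: 7
n_molecules: 2
share_pool: true
out_dir: toy_run
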