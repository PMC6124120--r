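# Example pipeline configuration: simulate a two-locus cross, scan it and
# call candidate regions. Run with
#   run_pipeline(system.file("extdata", "cross_example.yaml",
#                            package = "segscan"), outdir = "example_run")
seed: 1
stages: [simulate, scan, regions]
simulate:
  n_chrom: 17
  markers_per_chrom: 20
  n_f2: 2000
  n_f1: 200
  misclass_rate: 0.05
  depth_unicellular: 155
  depth_multicellular: 128
  seq_error_rate: 0.002
  phenotype_model: ALL
  causal_loci:
    - {chrom: chr14, pos: 2375000}
    - {chrom: chr16, pos: 2375000}
regions:
  threshold: 3
  max_gap: 500000
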