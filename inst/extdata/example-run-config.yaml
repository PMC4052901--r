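# Example pipeline configuration (see read_run_config()).
# Any key overrides the corresponding pipeline_params() default.
window: [-400, 100]
widths: [14, 16, 18, 20, 22, 24]
restarts: 3
q: 0.75
pseudocount: 0.5
max_gap: 100
min_genomes: 2
tau: 0.8
passes: 2
method: kmer
kmer_size: 4
seed: 1
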