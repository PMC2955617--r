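# Demo pipeline configuration: a small synthetic cohort that runs every
# stage in a few seconds. All keys map to run_config() arguments.
seed: 1
simulate: true
n_substrates: 256
n_kinases: 30
n_active: 4
n_tumor: 4
n_control: 2
top_n: 50
min_total_hits: 0
boost: 3
replicate_cv: 0.1
fdr_q: 0.05
excess_threshold: 0.1
viability_n_replicates: 4
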