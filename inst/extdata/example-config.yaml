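# Minimal pipeline configuration: simulate a small dataset and run all
# three suites with short chains. See ?load_config for the schema.
seed: 11
out_dir: ratemorph_run
log_level: info
min_genes: 2
sim:
  n_species: 12
  detection_prob: 0.55
suites:
  - suite: allometry
    n_iterations: 3000
    burn_in: 1000
    thin: 2
  - suite: rates
    partitions: [none, plant_diet, subfamily]
    n_iterations: 3000
    burn_in: 1000
    thin: 2
  - suite: multiresponse
    n_iterations: 3000
    burn_in: 1000
    thin: 2
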