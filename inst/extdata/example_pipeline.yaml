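# Example pipeline configuration: simulate a null scenario, then the same
# file can drive summarize / diversity / permanova on the written CSVs.
output_dir: out
seed: 1
preset: null_homogeneous
scenario:
  pellets_per_cell: 20
pellets: out/pellets.csv
availability: out/availability.csv
traits: out/traits.csv
group_by: [area]
q_grid: [-1, 0, 1, 2, 3]
q_set: [0, 1, 2]
B: 1000
n_perm: 999
formula: "area"
distance: bray
universe: union
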