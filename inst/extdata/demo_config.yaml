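# Demo configuration for run_pipeline(): a reduced simulated two-species
# run exercising every stage. Paths are relative to the working
# directory at run time.
simulate:
  n_types_shared: 3
  n_types_specific_a: 1
  n_types_specific_b: 1
  cells_per_type_per_timepoint: 40
  n_timepoints: 2
  genes_per_species: 600
  n_one2one: 400
  n_one2many: 40
  program_size: 15
  seed: 7
qc:
  min_genes: 10
  min_counts: 20
  max_mito_frac: 0.05
atlas:
  scale_factor: 10000
  n_hvg: 400
  n_pcs: 8
  knn_k: 20
  resolution: 1
  seed: 0
markers:
  min_pct: 0.05
  min_logfc: 0.25
  alpha: 0.05
integration:
  min_cells: 2
  dims: 8
  k_anchor: 5
  resolution: 1
  seed: 0
overlap:
  - clusters_a: 0
    clusters_b: 0
bulk:
  n_genes: 2000
  seed: 1
out_dir: results/demo_run
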