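# Example pipeline configuration: a small synthetic two-cohort study.
# Run with:
#   Rscript inst/cli/regulomix.R run --config inst/extdata/example_config.yaml --outdir demo_out
seed: 5
simulate:
  n_genes: 280
  cohorts:
    - {name: A, n_disease: 22, n_control: 10}
  modules:
    - {module_id: m1, n_genes: 20, r2_disease: 0.8, r2_control: 0.1,
       regulator_tf: TF_m1, pathway_label: path_m1}
    - {module_id: m2, n_genes: 20, r2_disease: 0.8, r2_control: 0.1}
    - {module_id: m3, n_genes: 20, r2_disease: 0.8, r2_control: 0.6}
  n_decoy_tfs: 10
  n_decoy_cmps: 2
  n_decoy_sets: 10
modules:
  k_max: 60
dcx:
  n_perm: 200
conservation:
  n_perm: 200
structure:
  n_pcs: 3
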