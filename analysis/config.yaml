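# Shared experiment configuration for the numbered analysis scripts.
# Desk-scale mirror of the study design: a cohort of 20,000 subjects with
# 100 sparse binary covariates, 69 negative-control outcomes, exposure
# prevalence 0.26; plasmode replicates of 5,000 rows with a true treatment
# effect of log(2) and a marginal outcome risk of 0.0075.
cohort:
  n_subjects: 20000
  n_covariates: 100
  n_nco: 69
  nco_baseline_hazard: 2.0e-5
  target_exposure_prevalence: 0.26
plasmode:
  n_resample: 5000
  n_replicates: 20
  target_exposure_prevalence: 0.26
  target_outcome_risk: 0.0075
  role_sizes: [50, 20, 20]
methods: [reference, lasso]
targets: [ps, drs_full]
match:
  max_ratio: 5
  caliper: 0.05
output_dir: results/experiment
master_seed: 20260926
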