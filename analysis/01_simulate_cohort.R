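#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic base cohort.
#
# Emulates the statistical structure of a primary-care antihypertensive
# cohort: sparse, positively correlated binary covariates; covariate-driven
# prescription uptake calibrated to an exposure prevalence of 0.26;
# 69 negative-control time-to-event outcomes whose hazard depends on
# covariates but never on treatment (true HR = 1 by construction); and one
# clinical reference outcome used only for confounder selection and DRS
# model fitting. Writes the cohort CSVs under results/cohort/.

suppressMessages(library(psdrsim))

cfg <- validate_config("analysis/config.yaml")
cohort_cfg <- cfg$cohort
cohort_cfg$seed <- derive_seed(cfg$master_seed, "cohort")

base <- generate_base_cohort(cohort_cfg)
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
write_base_cohort(base, "results/cohort")

cat(sprintf("cohort: %d subjects, %d covariates, %d prescription rows\n",
            length(base$subject_ids), ncol(base$covariates),
            nrow(base$prescriptions)))
cat(sprintf("covariate prevalence range: %.4f .. %.4f\n",
            min(colMeans(base$covariates)), max(colMeans(base$covariates))))
cat(sprintf("negative-control outcomes: %d, pooled event rate %.4f\n",
            ncol(base$nco_observed), mean(base$nco_observed)))
cat(sprintf("clinical reference outcome rate: %.4f\n",
            mean(base$clinical_observed)))
cat("wrote results/cohort/{cohort_covariates,prescriptions,nco_events}.csv\n")
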