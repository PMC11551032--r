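#!/usr/bin/env Rscript
# Stage 2 — drug eras, exposure classification and the covariate filter.
#
# Prescriptions are concatenated into treatment eras with the < 90-day
# refill-gap rule; subjects with at least one era are users (index day =
# first era start), all others non-users; covariates with prevalence
# <= 0.004 are dropped. Writes results/cohort/cohort.csv and
# covariates_kept.txt.

suppressMessages(library(psdrsim))

cfg <- validate_config("analysis/config.yaml")
cohort_cfg <- cfg$cohort
cohort_cfg$seed <- derive_seed(cfg$master_seed, "cohort")
base <- generate_base_cohort(cohort_cfg)

eras <- build_eras(base$prescriptions, gap_days = 90L)
cohort <- assign_exposure(eras, base)
filt <- filter_covariates(base$covariates, 0.004)

utils::write.csv(cohort, "results/cohort/cohort.csv", row.names = FALSE)
writeLines(filt$kept, "results/cohort/covariates_kept.txt")

cat(sprintf("prescriptions: %d rows -> %d eras\n",
            nrow(base$prescriptions), nrow(eras)))
cat(sprintf("users: %d (%.1f%%), non-users: %d\n", sum(cohort$treated),
            100 * mean(cohort$treated), sum(1 - cohort$treated)))
cat(sprintf("covariates kept by the prevalence filter: %d of %d\n",
            length(filt$kept), ncol(base$covariates)))
cat("wrote results/cohort/cohort.csv, covariates_kept.txt\n")
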