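#!/usr/bin/env Rscript
# Stability of the MetDiv marker: patient-fraction resampling of the
# survival analyses, cell subsampling of the Shannon score, and half-tissue
# splits of a full-scale synthetic section.

suppressPackageStartupMessages({
  library(metdiv)
  library(data.table)
})

prof <- fread("results/patient_profiles.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
strata <- fread("results/stratification.tsv")
dat <- Reduce(function(a, b) merge(a, b, by = "patient_id"),
              list(prof[!is.na(metdiv)], clinical, strata))
dat[, metdiv_group := factor(metdiv_group, levels = c("low", "high"))]

stab_uni <- resampling_stability(dat$os_months, dat$os_event, dat$metdiv_group,
                                 n_reps = 1000, seed = 71, endpoint = "OS")
cat("Univariate (log-rank) stability of the MetDiv grouping:\n")
print(stab_uni)

mv <- data.frame(metdiv_group = dat$metdiv_group,
                 age_group = factor(dat$age_group),
                 stromal_group = factor(dat$stromal_group),
                 lym_group = factor(dat$lym_group))
stab_mv <- resampling_stability(dat$os_months, dat$os_event, covariates = mv,
                                covariate = "metdiv_group", n_reps = 1000,
                                seed = 72, endpoint = "OS")
cat("\nMultivariate (Cox Wald) stability of MetDiv:\n")
print(stab_mv)
write_table(rbind(cbind(analysis = "univariate", stab_uni$curve),
                  cbind(analysis = "multivariate", stab_mv$curve)),
            "results/stability_curves.tsv")

# full-scale section for tissue-amount robustness
cfg_full <- cohort_config(count_multiplier = 1, seed = 73)
section <- generate_section("omentum", cfg_full, seed = 73)
cat(sprintf("\nfull-scale synthetic section: %d cells\n", nrow(section)))
sub <- cell_subsampling_stability(section, n_reps = 100, seed = 74)
print(sub)
write_table(sub, "results/cell_subsampling.tsv")

splits <- rbindlist(lapply(c("horizontal", "vertical"), function(o) {
  s <- half_split_stability(section, o)
  data.table(orientation = o, h_whole = s$h_whole, h_half1 = s$h_half1,
             h_half2 = s$h_half2, max_abs_dh = max(s$abs_diff))
}))
cat("\nhalf-tissue splits:\n")
print(splits)
write_table(splits, "results/half_splits.tsv")
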