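#!/usr/bin/env Rscript
# Prognostic stratification and survival models: dichotomize MetDiv and the
# sibling scores, fit univariate Cox models for OS and PFS, apply the
# univariate-eligibility rule for the multivariate model, and read off
# 5-year survival per MetDiv group.

suppressPackageStartupMessages({
  library(metdiv)
  library(data.table)
})

prof <- fread("results/patient_profiles.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
dat <- merge(prof[!is.na(metdiv)], clinical, by = "patient_id")

ga <- iterative_threshold(setNames(dat$metdiv, dat$patient_id),
                          dat$os_months, dat$os_event, variable = "metdiv")
print(ga)
dat[, metdiv_group := factor(as.character(ga$labels[patient_id]),
                             levels = c("low", "high"))]
dat[, stromal_group := median_split(dat$ovary_stromal_ratio)$labels]
dat[, lym_group := tertile_split(dat$ovary_lym_ratio)$labels]
dat[, age_group := median_split(dat$age)$labels]

vars <- c("metdiv_group", "stromal_group", "lym_group", "age_group")
rows <- list()
for (ep in c("OS", "PFS")) {
  tm <- if (ep == "OS") dat$os_months else dat$pfs_months
  ev <- if (ep == "OS") dat$os_event else dat$pfs_event
  for (v in vars) {
    fit <- suppressWarnings(cox_fit(tm, ev, setNames(data.frame(dat[[v]]), v), ep))
    rows[[length(rows) + 1]] <- data.table(
      endpoint = ep, variable = v, hr = fit$table$hr[1],
      ci_low = fit$table$ci_low[1], ci_high = fit$table$ci_high[1],
      p = fit$table$p[1], concordance = fit$concordance)
  }
}
uni <- rbindlist(rows)
write_table(uni, "results/survival_univariate.tsv")
cat("Univariate Cox models:\n"); print(uni)

os_p <- setNames(uni[endpoint == "OS", p], uni[endpoint == "OS", variable])
eligible <- select_multivariate_factors(os_p)
cat(sprintf("\neligible for multivariate entry (p < 0.05, OS): %s\n",
            paste(eligible, collapse = ", ")))
mv_vars <- union("metdiv_group", union(eligible, c("stromal_group", "lym_group")))
mv <- rbindlist(lapply(c("OS", "PFS"), function(ep) {
  tm <- if (ep == "OS") dat$os_months else dat$pfs_months
  ev <- if (ep == "OS") dat$os_event else dat$pfs_event
  fit <- suppressWarnings(cox_fit(tm, ev, as.data.frame(dat)[, mv_vars], ep))
  cbind(data.table(endpoint = ep, concordance = fit$concordance), fit$table)
}))
write_table(mv, "results/survival_multivariate.tsv")
cat("\nMultivariate Cox models:\n"); print(mv)

km_low <- km_estimate(dat[metdiv_group == "low", os_months],
                      dat[metdiv_group == "low", os_event])
km_high <- km_estimate(dat[metdiv_group == "high", os_months],
                       dat[metdiv_group == "high", os_event])
cat(sprintf("\n5-year OS: %.0f%% (low MetDiv) vs %.0f%% (high MetDiv)\n",
            100 * landmark_survival(km_low, 60),
            100 * landmark_survival(km_high, 60)))

grDevices::png("results/km_metdiv_os.png", 900, 700, res = 120)
plot_km_groups(dat$os_months, dat$os_event, dat$metdiv_group,
               main = "Overall survival by MetDiv group")
grDevices::dev.off()
write_table(dat[, .(patient_id, metdiv_group, stromal_group, lym_group,
                    age_group)], "results/stratification.tsv")
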