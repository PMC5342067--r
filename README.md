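# metdiv

Ecological diversity analysis of multi-site tumor microenvironments from
single-cell histology maps, with prognostic survival modelling and
stability diagnostics.

## What this package is for

Automated H&E image analysis of high-grade serous ovarian carcinoma
(HGSOC) yields, for every resected lesion of a patient — the ovary tumor
plus local metastases in omentum, peritoneum, lymph node, appendix, spleen
or umbilicus — a table of classified nuclei (cancer / lymphocyte /
stromal, with coordinates). `metdiv` takes such cell maps downstream:

* **Per-section scoring.** Cell-type composition (cell ratios), Shannon
  diversity `H = -Σ pᵢ log pᵢ` (nats) and Simpson index `D = Σ pᵢ²`.
* **Patient aggregation.** **MetDiv** — the mean Shannon diversity over all
  of a patient's *non-ovary* lesions — plus sibling aggregates (diversity
  including the ovary, SD of Shannon across metastases, ovary and mean
  metastasis cell ratios, number of sites).
* **Prognostic stratification.** Median, lower-tertile and iterative
  (optimal-cutpoint, log-rank-minimizing, size-constrained, with median
  fallback) dichotomization; Kruskal-Wallis and Fisher's exact association
  tests.
* **Survival analysis.** Kaplan-Meier, log-rank, univariate and
  multivariate Cox models (Efron ties, Wald CIs, Harrell concordance) with
  the univariate-eligibility rule (`p < 0.05`) plus forced covariates, and
  landmark (e.g. 5-year) survival per group.
* **Robustness.** Patient-fraction resampling of the survival analyses
  (fractions 100%→70%, percentage of draws staying significant), cell
  subsampling of the Shannon score, and half-tissue splits.
* **Classifier validation metrics.** One-vs-rest sensitivity, specificity
  and balanced average per class and site; field-of-view proportion
  correlations (Pearson/Spearman).
* **Synthetic cohort generator.** A fully parameterized generative model
  (site sampling with exactly calibrated frequencies, per-site Dirichlet
  compositions with a per-patient tilt, log-normal cell counts fitted to
  published per-section summaries, exponential proportional-hazards
  outcomes coupled to the true diversity grouping) with complete ground
  truth, so every stage is testable end to end without raw patient data.

The repository is organized as an analysis workflow: all computation lives
in the package (`R/`), and the numbered scripts under `analysis/` are thin
narrative drivers that run the stages in order and write their tables under
`results/`.

## Worked example

```r
library(metdiv)

cfg <- cohort_config(seed = 20260924)      # 61 patients, desk-scale cell maps
cohort <- generate_cohort(cfg)
secdiv <- diversity_by_section(cohort$cells)
prof   <- patient_profiles(secdiv)
dat    <- merge(prof, cohort$clinical, by = "patient_id")

ga <- iterative_threshold(setNames(dat$metdiv, dat$patient_id),
                          dat$os_months, dat$os_event, variable = "metdiv")
print(ga)
#> <group_assignment> metdiv by iterative split at 0.6916: low 29 / high 32
#>   note: p-value minimized over cutpoint scan; optimistic without correction

grp <- factor(as.character(ga$labels[dat$patient_id]), levels = c("low", "high"))
cox_fit(dat$os_months, dat$os_event, data.frame(metdiv_group = grp))
#> <survival_fit> OS: n=61, events=50, concordance=0.600
#>   metdiv_grouphigh             HR 2.48 (1.37-4.49) p=0.00278
```

The printed fit says: patients in the high-MetDiv group (diverse
microenvironments across their metastases; here split at Shannon ~ 0.69)
die at ~2.5 times the hazard of the low-MetDiv group in this synthetic
cohort, whose generating truth is HR 3.18 at n = 61. Exact numbers vary
with `seed`.

Resampling stability of that marker:

```r
resampling_stability(dat$os_months, dat$os_event, grp,
                     fractions = c(0.7, 0.85, 1), n_reps = 1000, seed = 1)
#> <stability_curve> univariate OS, 1000 reps, alpha=0.05, seed=1
#>    fraction n_sub pct_significant n_failed
#> 1:     0.70    42            86.3        0
#> 2:     0.85    51            99.5        0
#> 3:     1.00    61           100.0        0
```

So with only 70% of patients redrawn, the grouping stays prognostic in
86% of resamples.

The full chain, reproducibly, with a manifest:

```r
run_pipeline(system.file("extdata", "default_config.yaml", package = "metdiv"),
             out_dir = "results/pipeline_run")
```

or stage by stage:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_diversity_scores.R
Rscript analysis/03_survival_analysis.R
Rscript analysis/04_robustness.R
Rscript analysis/05_classifier_validation.R
Rscript analysis/06_full_pipeline.R
```

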