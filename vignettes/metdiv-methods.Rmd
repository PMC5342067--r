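---
title: "Microenvironmental diversity of multi-site tumor cell maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironmental diversity of multi-site tumor cell maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdiv)
```

## The scientific problem

High-grade serous ovarian carcinoma (HGSOC) disseminates through the
peritoneal cavity, so a single patient typically presents with several
resectable lesions: the ovary tumor plus local metastases in the omentum,
peritoneum, lymph nodes, appendix, and occasionally spleen or umbilicus.
Automated analysis of H&E histology can classify every nucleus in a
whole-tumor section into three broad classes — cancer cells, lymphocytes and
stromal cells — producing, per lesion, a spatial cell map with hundreds of
thousands of classified cells.

`metdiv` implements the downstream analysis of such cell maps. The central
question is whether the *collective* make-up of the tumor microenvironment
across a patient's metastases — rather than the abundance of any single cell
type at any single site — carries prognostic information.

## Diversity scores

For a section $j$ with cell-type proportions $p_{ji}$ over $R = 3$ classes
(the *cell ratios*: class count over all classified cells), the package
computes the Shannon diversity index in natural log units

$$H_j = -\sum_{i=1}^{R} p_{ji}\,\log p_{ji}, \qquad 0 \le H_j \le \log R,$$

and the Simpson index

$$D_j = \sum_{i=1}^{R} p_{ji}^2, \qquad 1/R \le D_j \le 1 .$$

$H_j = 0$ and $D_j = 1$ both characterize single-class dominance; a uniform
mixture attains $H = \log 3$ and $D = 1/3$. Conventions: natural logarithm
(the ecology standard; the defining formula leaves the base open),
$0 \log 0 := 0$ by continuity, and plug-in (maximum-likelihood) proportion
estimates without small-sample entropy bias correction — sections carry
$10^4$–$10^5$ cells, where the bias ($\sim (R-1)/2N$ nats) is far below
every effect of interest.

The patient-level score is

$$\mathrm{MetDiv} = \frac{1}{|M|}\sum_{j \in M} H_j,$$

the *unweighted* arithmetic mean over the patient's non-ovary sections $M$.
Weighting by cell count was considered and rejected: section cellularity
reflects block size and sectioning, not biology, and the score should treat
each lesion as one habitat. Sibling aggregates (`metdiv_incl_ovary`, the
$n-1$ sample SD of Shannon scores over metastases, per-site mean cell
ratios) are computed alongside. Patients without a non-ovary section have
undefined MetDiv; they are flagged, logged and excluded downstream. Rare
sites (spleen, umbilicus) count as metastases like any other non-ovary site.

Because raw Simpson *decreases* as Shannon increases, the agreement between
the two indices (`index_agreement()`) is reported in both orientations
($H$ vs $D$ and $H$ vs $1-D$) plus the Spearman rank correlation, rather
than silently picking one sign.

## Prognostic stratification

Continuous scores are dichotomized before survival modelling (their
distributions are skewed; `skewness_adj()` exposes the adjusted
Fisher–Pearson statistic used to check this):

* **median split** — threshold at the sample median, ties to "high"
  (`high` always means score $\ge$ threshold, matching the $\ge$ convention
  of the ratio-based groupings);
* **lower-tertile split** — "low" below the interpolated 33rd percentile
  (`quantile` type 7, documented so group sizes are reproducible), used for
  lymphocyte ratios;
* **iterative threshold** — a constrained optimal-cutpoint scan: every
  midpoint between consecutive sorted unique scores whose two groups both
  contain at least `min_group_frac` (default 10%) of patients is evaluated
  by the two-group log-rank test, and the cutpoint minimizing $p$ is
  selected; if no cutpoint is admissible the method falls back to the
  median split and says so. The selected $p$ is a minimum over a scan and
  therefore optimistic; the result carries an explicit note, and no
  multiplicity correction is applied (the grouped analyses report raw
  p-values). The scan's argmin is also intrinsically noisy: simulations
  with a planted 4-fold hazard step show the recovered cutpoint scattering
  within roughly $\pm 0.07$ (score units on $[0,1]$) around the true step,
  because the p-curve is locally flat. Tests therefore check oracle
  agreement per draw and distribution-level recovery, not single-draw
  pinpoint accuracy.

Associations use `kruskal.test` (continuous vs categorical, tie-corrected)
and `fisher.test` (2×2 categorical, two-sided by summing hypergeometric
probabilities at or below the observed table's).

## Survival modelling

Kaplan–Meier product-limit curves, the $k$-group log-rank test, and Cox
proportional-hazards fits all go through the `survival` package. Fixed
choices: Efron tie handling (less biased than Breslow at the monthly tie
density of clinical follow-up), Wald 95% CIs and p-values on the log-HR
scale, Harrell's concordance attached to every fit, and dichotomized
covariates by default. Multivariate models admit covariates that are
significant ($p < 0.05$, strict) in univariate analysis via
`select_multivariate_factors()`, plus *forced* covariates: the reference
analysis keeps the stromal and lymphocyte groupings in the multivariate
model for both endpoints even where they miss univariate eligibility, so
the pipeline accepts a forced-covariate list rather than guessing whether
the eligibility gate was applied per endpoint. The pipeline also always
retains the MetDiv grouping itself — it is the marker under study, and the
multivariate stability stage must be able to monitor it. Landmark survival
(e.g. 5-year OS per group) is read off the KM step function and flagged
undefined beyond follow-up.

## Robustness procedures

Three stability checks mirror the reference analysis:

1. **Patient-fraction resampling** (`resampling_stability()`): for fractions
   100%→70%, draw that share of patients without replacement (default 1000
   times), rerun the test (log-rank for univariate groupings; the marker's
   Wald p in the multivariate Cox model), and record the percentage of
   draws that stay significant at $\alpha = 0.05$. Group labels are
   computed once on the full cohort and held fixed — this isolates the
   stability of the *marker*, is reproducible, and matches a protocol in
   which the dichotomization is part of the marker definition; re-deriving
   the median split inside every draw is available behind `rederive =
   TRUE`. At fraction 1.0 the procedure reproduces the full-cohort test
   verbatim (percentage exactly 0 or 100). Note that on any *single* null
   cohort the recorded percentage is a high-variance quantity (subsample
   test statistics correlate with the full-cohort statistic by roughly
   $\sqrt{f}$); only the marginal rate over independent cohorts is anchored
   at the nominal 5%, and the test suite checks exactly that.
2. **Cell subsampling** (`cell_subsampling_stability()`): recompute Shannon
   diversity on 100/75/50% of a section's cells (without replacement) and
   report the SD over replicates. The delta method gives
   $\mathrm{SD}(H) \approx \sqrt{\sum_i (\log p_i + H)^2 p_i\,(1-f)/(fN)}$,
   the finite-population oracle the tests compare against; at full section
   scale ($N \approx 5\times10^5$, $f = 0.5$) this is $\sim 10^{-3}$ nats.
3. **Half-tissue splits** (`half_split_stability()`): split a section at
   the midpoint of its cell bounding box along the chosen axis (the best
   proxy for splitting the image when only cell coordinates are retained),
   score each half, and report $|\Delta H|$ against the whole section. The
   full per-section distribution is reported rather than a single pooled
   SD, whose reference population (sections, patients or orientations) is
   not well defined. A "horizontal" split means a horizontal dividing line
   (top/bottom halves, i.e. split on $y$; image convention with $y$
   increasing downward).

## Classifier validation metrics

`confusion_metrics()` computes one-vs-rest sensitivity and specificity per
cell class (the standard reduction for a 3-class problem) and their
arithmetic mean, the *balanced average*, pooled and per site.
`proportion_agreement()` correlates automated against expert cell ratios
over fields of view; because the reference description names both Pearson
(in the methods text) and Spearman (in the figure), the method is an
explicit parameter with Pearson as default, and the analysis scripts print
both.

## The synthetic cohort generator

No raw cohort data are published, so the generator is the package's testbed
and defines the study conditions every downstream stage is validated under.
It is first-class, tested code with ground truth attached. Defaults, chosen
once against the printed cohort summaries:

* **Cohort geometry** — 61 patients; one ovary section each plus 1–4
  distinct non-ovary sites; total sites per patient on $\{2,\dots,5\}$ with
  probabilities $(0.30, 0.35, 0.25, 0.10)$, giving median 3 and mean 3.15
  ($\approx 192/61$ sections per patient). Non-ovary site frequencies
  follow the block counts 51 omentum / 48 peritoneum / 20 lymph node /
  9 appendix / 2 umbilicus / 1 spleen out of 131. Because at most one
  section per site per patient is drawn (consistent with the block
  accounting), naive weighted sampling without replacement would depress
  frequent sites by up to ~6 percentage points; the generator therefore
  computes exact inclusion probabilities for successive weighted draws
  (feasible by enumeration over 6 sites) and inverts them by a fixed point
  so that *realized* marginal frequencies equal the configured ones.
* **Compositions** — per-site Dirichlet priors over (cancer, lymphocyte,
  stromal) with total concentration ~10: lymph node lymphocyte-rich,
  appendix stromal/lymphocyte-rich, ovary centered near stromal ratio 0.24
  and lymphocyte ratio 0.07–0.10 (the reference dichotomization
  thresholds). A per-patient log-normal tilt (`patient_effect_sd`, default
  0.4) multiplies the concentration triple for all of a patient's sections,
  inducing the within-patient correlation between ovary and metastasis
  ratios reported for real cohorts ($r \approx 0.3$); a purely site-level
  model would make them independent. The tilted draw is the section's
  ground-truth mixture, recorded exactly.
* **Cell counts** — per-class log-normal models fitted to the printed
  per-section means and IQRs (cancer 362,417; lymphocyte 67,433; stromal
  92,861), parameterized as `mean * exp(s Z - s^2/2)` so the arithmetic
  mean is exact and a zero log-SD yields a constant count. A desk-scale
  multiplier (default 1/100) shrinks sections to ~5,000 cells so the full
  pipeline runs in seconds; full scale is one argument away.
* **Space** — uniform placement in a 20×20 mm footprint by default;
  a Matérn-style parent–offspring clustered mode (50 parents, 500 µm
  Gaussian spread) exists to make half-tissue splits non-trivially
  inhomogeneous.
* **Survival** — exponential proportional hazards with OS/PFS medians
  43.33/19.8 months; the top half (`high_fraction = 0.5`) of *true* MetDiv
  carries log-HRs $\log 3.18$ (OS) and $\log 2.83$ (PFS) by default. The
  effect acts through the dichotomized latent group, mirroring the grouped
  analyses. Censoring is administrative at 120 months plus a uniform early
  censoring time for a configurable fraction (default 0.33) of patients.
  Progression and death are coupled (`PFS = min(progression, death)`
  before censoring) so PFS never exceeds OS.

What the generator does **not** emulate: nucleus morphology and pixel data,
spatial interaction between cell types, section-to-section heterogeneity
within one site of one patient, non-proportional hazards, and informative
censoring. Passing tests therefore demonstrate correctness of the scoring
and inference machinery under a clean generative model, not performance of
the upstream classifier or transportability to real slides.

## Numerical and design choices

* Determinism: every generator and resampling function takes a seed; the
  cohort generator derives per-section seeds from the root seed, so the
  clinical table is bit-identical whether or not cell maps are
  materialized, and `run_pipeline()` writes a manifest (config snapshot,
  stage seeds, row counts, file MD5s) such that re-runs are bit-identical.
* Degenerate inputs fail loudly: empty sections, constant scores, groups
  below minimum size, all-censored concordance, zero-variance correlations
  are errors or flagged `NA`s, never silent numbers.
* Ties at dichotomization thresholds go to "high" ($\ge$ rule).
* Problem sizes in the test suite and acceptance script are the package's
  own validation design: 10,000 random compositions for bounds; all 2×2
  tables with margins ≤ 12 against the hypergeometric oracle; 200 cohorts
  of 500 patients per hazard ratio for recovery/coverage (500 for the null
  rejection rate); 250 null cohorts for the marginal size of the
  resampling procedure; $10^5$-cell sections for subsampling/split noise;
  25 replicates for cutpoint recovery.

## Known limitations

The exponential survival baseline has constant hazard — adequate for
recovery tests, unrealistic for late follow-up. The iterative threshold
reports raw minimized p-values (with a warning) as the reference analysis
does; any confirmatory use would need shrinkage or cross-validation. The
validation module measures agreement only; it cannot detect shared bias
between classifier and annotators. And all empirical statements in this
vignette are properties of the synthetic model, computed by the package's
tests and scripts — no claim is made about any real cohort.
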