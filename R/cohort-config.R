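#' Log-normal count model from a mean and interquartile range
#'
#' Parameterizes a log-normal section-count distribution by its arithmetic
#' mean and IQR. The log-scale spread is recovered from the quartile ratio
#' (`sdlog = log(q75/q25) / (2 * qnorm(0.75))`); draws are generated as
#' `mean * exp(sdlog * Z - sdlog^2/2)` so the arithmetic mean is matched
#' exactly and the IQR approximately.
#'
#' @param mean Arithmetic mean count.
#' @param q25,q75 Lower and upper quartiles of the target distribution.
#' @return List with elements `mean` and `sdlog`.
#' @export
lognormal_count_model <- function(mean, q25, q75) {
  if (mean <= 0 || q25 <= 0 || q75 < q25) stopf("invalid count summary")
  list(mean = mean, sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}

# Per-class whole-section count models fitted to the reported cohort-level
# mean and IQR of classified nuclei per section.
default_cells_per_section <- function() {
  list(
    cancer     = lognormal_count_model(362417, 208129, 502789),
    lymphocyte = lognormal_count_model(67433, 27944, 90852),
    stromal    = lognormal_count_model(92861, 39075, 106220)
  )
}

# Dirichlet concentration triples (cancer, lymphocyte, stromal) per site.
# Means follow the observed site contrasts: lymph node lymphocyte-rich,
# appendix stromal/lymphocyte-rich, ovary with stromal ratio centered near
# the 0.24 dichotomization threshold and lymphocyte ratio near 0.07-0.10.
# Total concentration ~10 gives realistic between-section spread.
default_composition_priors <- function() {
  list(
    ovary      = c(cancer = 6.6, lymphocyte = 1.0, stromal = 2.4),
    omentum    = c(cancer = 7.0, lymphocyte = 1.0, stromal = 2.0),
    peritoneum = c(cancer = 7.0, lymphocyte = 1.0, stromal = 2.0),
    appendix   = c(cancer = 4.0, lymphocyte = 2.5, stromal = 3.5),
    lymph_node = c(cancer = 4.5, lymphocyte = 4.0, stromal = 1.5),
    spleen     = c(cancer = 6.0, lymphocyte = 2.0, stromal = 2.0),
    umbilicus  = c(cancer = 6.5, lymphocyte = 1.0, stromal = 2.5)
  )
}

#' Exact inclusion probabilities for successive weighted sampling
#'
#' For `m` draws without replacement from items with weights `w` (each draw
#' proportional to the remaining weights), returns the probability that each
#' item is drawn at least once. Computed by exact recursion over ordered
#' draw sequences; intended for small item sets (here: 6 metastasis sites,
#' m <= 4).
#'
#' @param w Positive weights (need not sum to 1).
#' @param m Number of draws (0 <= m <= length(w)).
#' @return Numeric vector of inclusion probabilities, same names as `w`.
#' @export
inclusion_probabilities <- function(w, m) {
  n <- length(w)
  if (m < 0 || m > n) stopf("m must be between 0 and length(w)")
  rec <- function(avail, m) {
    res <- numeric(n)
    if (m == 0L || length(avail) == 0L) return(res)
    W <- sum(w[avail])
    for (i in avail) {
      pi <- w[i] / W
      res[i] <- res[i] + pi
      if (m > 1L) res <- res + pi * rec(setdiff(avail, i), m - 1L)
    }
    res
  }
  out <- rec(seq_len(n), as.integer(m))
  names(out) <- names(w)
  out
}

# Expected share of sections per site given sampling weights and the
# sites-per-patient distribution (k non-ovary draws = k_total - 1).
expected_site_shares <- function(w, sites_per_patient) {
  ks <- as.integer(names(sites_per_patient))
  counts <- numeric(length(w))
  for (j in seq_along(ks)) {
    counts <- counts + sites_per_patient[j] * inclusion_probabilities(w, ks[j] - 1L)
  }
  counts / sum(counts)
}

# Invert expected_site_shares: find sampling weights whose realized marginal
# section frequencies equal the target frequencies. Without-replacement
# sampling caps each site at one section per patient, which depresses
# high-frequency sites relative to their weights; this fixed point corrects
# for that so the generator reproduces the configured frequencies.
calibrate_site_weights <- function(target, sites_per_patient,
                                   tol = 1e-10, max_iter = 1000L) {
  w <- target / sum(target)
  for (i in seq_len(max_iter)) {
    share <- expected_site_shares(w, sites_per_patient)
    if (max(abs(share - target)) < tol) break
    w <- w * target / share
    w <- w / sum(w)
  }
  share <- expected_site_shares(w, sites_per_patient)
  if (max(abs(share - target)) > 1e-6) {
    warnf("site-weight calibration did not fully converge (max dev %.2e)",
          max(abs(share - target)))
  }
  w
}

#' Configuration for the synthetic multi-site cohort generator
#'
#' Bundles every distributional choice of the generator: cohort size, site
#' sampling, per-site cell-type composition priors, per-section cell counts,
#' spatial placement, and the proportional-hazards survival model coupling
#' outcome to the true diversity grouping. Defaults emulate the reference
#' cohort: 61 patients, 2-5 sites each (median 3), non-ovary site frequencies
#' 51/48/20/9/2/1 out of 131 sections, section counts with mean 362,417
#' (cancer), 67,433 (lymphocyte) and 92,861 (stromal) at multiplier 1, OS/PFS
#' medians 43.33/19.8 months and true-group hazard ratios 3.18/2.83.
#'
#' @param n_patients Number of patients.
#' @param site_frequencies Named probabilities over the six non-ovary sites;
#'   the expected share of generated non-ovary sections per site. Must sum
#'   to 1.
#' @param sites_per_patient Named probabilities over total sites per patient
#'   (support within 2..5; every patient gets one ovary section plus k-1
#'   distinct non-ovary sections).
#' @param composition_priors Named list of strictly positive Dirichlet
#'   concentration triples `(cancer, lymphocyte, stromal)` per site.
#' @param cells_per_section Named list of per-class log-normal count models
#'   (see [lognormal_count_model()]).
#' @param count_multiplier Desk-scale multiplier on cell counts (default
#'   1/100); set to 1 for full-scale sections.
#' @param patient_effect_sd SD of the per-patient log-normal tilt applied to
#'   the Dirichlet concentrations of every section of a patient. A positive
#'   value makes compositions of the same patient correlate across sites
#'   (as observed between ovary and metastasis ratios); 0 disables it.
#' @param spatial_mode `"uniform"` or `"clustered"` placement of cells in the
#'   section footprint.
#' @param section_size_um Side length (micrometers) of the square section
#'   footprint.
#' @param cluster_params For clustered mode: `n_clusters` parent points and
#'   Gaussian `spread_um` of offspring around parents.
#' @param survival_model List: `os_median`, `pfs_median` (months; exponential
#'   baselines), `log_hr_os`, `log_hr_pfs` (log hazard ratios of the true
#'   high-diversity group), `high_fraction` (top fraction of true MetDiv
#'   labelled high), `censor_time` (administrative censoring, months; may be
#'   `Inf`), `censor_fraction` (share of patients with an additional uniform
#'   early-censoring time).
#' @param seed Integer root seed; all generator randomness derives from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 61,
                          site_frequencies = c(omentum = 51, peritoneum = 48,
                                               lymph_node = 20, appendix = 9,
                                               umbilicus = 2, spleen = 1) / 131,
                          sites_per_patient = c("2" = 0.30, "3" = 0.35,
                                                "4" = 0.25, "5" = 0.10),
                          composition_priors = default_composition_priors(),
                          cells_per_section = default_cells_per_section(),
                          count_multiplier = 0.01,
                          patient_effect_sd = 0.4,
                          spatial_mode = c("uniform", "clustered"),
                          section_size_um = 20000,
                          cluster_params = list(n_clusters = 50, spread_um = 500),
                          survival_model = list(os_median = 43.33,
                                                pfs_median = 19.8,
                                                log_hr_os = log(3.18),
                                                log_hr_pfs = log(2.83),
                                                high_fraction = 0.5,
                                                censor_time = 120,
                                                censor_fraction = 0.33),
                          seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  if (n_patients < 1) stopf("n_patients must be >= 1")

  if (is.null(names(site_frequencies)) ||
      !all(names(site_frequencies) %in% MET_SITES)) {
    stopf("site_frequencies must be named with non-ovary sites (%s)",
          paste(MET_SITES, collapse = ", "))
  }
  if (any(site_frequencies < 0)) stopf("site_frequencies must be non-negative")
  if (abs(sum(site_frequencies) - 1) > 1e-6) {
    stopf("site_frequencies must sum to 1 over non-ovary sites")
  }
  site_frequencies <- site_frequencies / sum(site_frequencies)

  ks <- suppressWarnings(as.integer(names(sites_per_patient)))
  if (any(is.na(ks)) || any(ks < 2) || any(ks > 5)) {
    stopf("sites_per_patient support must lie in 2..5")
  }
  if (any(sites_per_patient < 0) || abs(sum(sites_per_patient) - 1) > 1e-6) {
    stopf("sites_per_patient must be a probability distribution")
  }
  sites_per_patient <- sites_per_patient / sum(sites_per_patient)
  if (max(ks[sites_per_patient > 0]) - 1 > sum(site_frequencies > 0)) {
    stopf("not enough distinct non-ovary sites for the largest patient")
  }

  needed <- union("ovary", names(site_frequencies)[site_frequencies > 0])
  missing_priors <- setdiff(needed, names(composition_priors))
  if (length(missing_priors) > 0) {
    stopf("composition_priors missing site(s): %s",
          paste(missing_priors, collapse = ", "))
  }
  for (s in names(composition_priors)) {
    a <- composition_priors[[s]]
    if (length(a) != 3 || any(!is.finite(a)) || any(a <= 0)) {
      stopf("Dirichlet concentrations for site '%s' must be 3 strictly positive values", s)
    }
  }

  if (!all(CELL_CLASSES %in% names(cells_per_section))) {
    stopf("cells_per_section must have models for %s",
          paste(CELL_CLASSES, collapse = ", "))
  }
  if (count_multiplier <= 0) stopf("count_multiplier must be positive")
  if (patient_effect_sd < 0) stopf("patient_effect_sd must be >= 0")

  sm <- survival_model
  for (f in c("os_median", "pfs_median")) {
    if (is.null(sm[[f]]) || !is.finite(sm[[f]]) || sm[[f]] <= 0) {
      stopf("survival_model$%s must be a positive number of months", f)
    }
  }
  sm$log_hr_os <- sm$log_hr_os %||% 0
  sm$log_hr_pfs <- sm$log_hr_pfs %||% 0
  sm$high_fraction <- sm$high_fraction %||% 0.5
  if (sm$high_fraction <= 0 || sm$high_fraction >= 1) {
    stopf("survival_model$high_fraction must be in (0, 1)")
  }
  sm$censor_time <- sm$censor_time %||% Inf
  if (sm$censor_time <= 0) stopf("survival_model$censor_time must be positive")
  sm$censor_fraction <- sm$censor_fraction %||% 0
  if (sm$censor_fraction < 0 || sm$censor_fraction > 1) {
    stopf("survival_model$censor_fraction must be in [0, 1]")
  }

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    site_frequencies = site_frequencies,
    site_weights = calibrate_site_weights(site_frequencies, sites_per_patient),
    sites_per_patient = sites_per_patient,
    composition_priors = composition_priors,
    cells_per_section = cells_per_section,
    count_multiplier = count_multiplier,
    patient_effect_sd = patient_effect_sd,
    spatial_mode = spatial_mode,
    section_size_um = section_size_um,
    cluster_params = cluster_params,
    survival_model = sm,
    seed = as.integer(seed)
  ), class = "cohort_config")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  patients: %d, seed: %d, count multiplier: %g\n",
              x$n_patients, x$seed, x$count_multiplier))
  cat(sprintf("  sites/patient: %s\n",
              paste(sprintf("%s:%.2f", names(x$sites_per_patient),
                            x$sites_per_patient), collapse = " ")))
  cat(sprintf("  non-ovary site frequencies: %s\n",
              paste(sprintf("%s:%.3f", names(x$site_frequencies),
                            x$site_frequencies), collapse = " ")))
  cat(sprintf("  survival: OS median %.2f mo (HR %.2f), PFS median %.2f mo (HR %.2f), censor %g%% by %g mo\n",
              x$survival_model$os_median, exp(x$survival_model$log_hr_os),
              x$survival_model$pfs_median, exp(x$survival_model$log_hr_pfs),
              100 * x$survival_model$censor_fraction, x$survival_model$censor_time))
  invisible(x)
}
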