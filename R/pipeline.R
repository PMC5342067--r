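#' Read a pipeline configuration file
#'
#' YAML with an optional `cohort:` block (arguments of [cohort_config()]),
#' and optional `robustness:` (`fractions`, `n_reps`, `alpha`),
#' `survival:` (`force`: covariates forced into the multivariate model) and
#' `validation:` (`simulate`: logical) blocks. Unset values fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return List with a `cohort_config` in `$cohort` plus stage settings.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(raw)
}

pipeline_config <- function(raw = list()) {
  ch <- raw$cohort %||% list()
  for (f in c("site_frequencies", "sites_per_patient")) {
    if (!is.null(ch[[f]])) ch[[f]] <- unlist(ch[[f]])
  }
  if (!is.null(ch$composition_priors)) {
    ch$composition_priors <- lapply(ch$composition_priors, unlist)
  }
  if (!is.null(ch$cells_per_section)) {
    ch$cells_per_section <- lapply(ch$cells_per_section, function(m) {
      do.call(lognormal_count_model, as.list(unlist(m)))
    })
  }
  cohort <- do.call(cohort_config, ch)
  rb <- raw$robustness %||% list()
  sv <- raw$survival %||% list()
  vl <- raw$validation %||% list()
  list(
    cohort = cohort,
    robustness = list(
      fractions = rb$fractions %||% seq(0.70, 1.00, by = 0.05),
      n_reps = rb$n_reps %||% 1000,
      alpha = rb$alpha %||% 0.05
    ),
    survival = list(
      force = sv$force %||% c("stromal_group", "lym_group")
    ),
    validation = list(simulate = isTRUE(vl$simulate %||% TRUE))
  )
}

# Univariate survival report row for one dichotomized or continuous factor.
univariate_row <- function(variable, covariate, times, events, endpoint) {
  fit <- suppressWarnings(
    cox_fit(times, events, setNames(data.frame(covariate), variable),
            endpoint = endpoint)
  )
  lr_p <- if (is.factor(covariate) || is.character(covariate)) {
    logrank_test(times, events, covariate)$p
  } else NA_real_
  data.table(variable = variable, endpoint = endpoint,
             hr = fit$table$hr[1], ci_low = fit$table$ci_low[1],
             ci_high = fit$table$ci_high[1], p = fit$table$p[1],
             logrank_p = lr_p, concordance = fit$concordance)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> per-section diversity -> patient profiles -> stratification
#' -> univariate and multivariate survival models (univariate-eligibility
#' rule plus forced covariates) -> resampling stability -> classifier
#' validation, writing every table as TSV to `out_dir` together with a run
#' manifest (config snapshot, seeds, row counts, file MD5s). Re-running with
#' the same configuration reproduces all tables bit-identically.
#'
#' @param config A [cohort_config()], a pipeline config list from
#'   [read_config()], or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @param plots Also write KM and ternary plots as PNG.
#' @return Invisibly, a list: `manifest`, plus the computed tables
#'   (`section_diversity`, `profiles`, `stratification`,
#'   `survival_univariate`, `survival_multivariate`, `stability`,
#'   `associations`, `validation`).
#' @export
run_pipeline <- function(config, out_dir, plots = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (inherits(config, "cohort_config")) {
    base <- pipeline_config(list())
    base$cohort <- config
    config <- base
  }
  cfg <- config$cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(x, path)
    files <<- c(files, path)
    x
  }

  cohort <- generate_cohort(cfg, cells = TRUE)
  emit(cohort$cells, "cells.tsv")
  emit(cohort$clinical, "clinical.tsv")
  emit(cohort$truth$sections, "truth_sections.tsv")

  secdiv <- emit(diversity_by_section(cohort$cells), "section_diversity.tsv")
  prof <- suppressWarnings(patient_profiles(secdiv))
  excluded <- prof[is.na(metdiv), patient_id]
  if (length(excluded) > 0) {
    message(sprintf("pipeline: excluding %d patient(s) without metastasis sections: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  prof <- prof[!is.na(metdiv)]
  if (nrow(prof) == 0) stopf("diversity stage: MetDiv undefined for every patient")
  emit(prof, "patient_profiles.tsv")

  dat <- merge(prof, cohort$clinical, by = "patient_id", sort = TRUE)

  # stratification: iterative cutpoint for MetDiv (median fallback),
  # median split for stromal ratio and age, lower-tertile for lymphocyte
  # ratio -- the grouping rules of the reference analysis
  ga_metdiv <- iterative_threshold(setNames(dat$metdiv, dat$patient_id),
                                   dat$os_months, dat$os_event,
                                   variable = "metdiv")
  ga_strom <- median_split(setNames(dat$ovary_stromal_ratio, dat$patient_id),
                           variable = "ovary_stromal_ratio")
  ga_lym <- tertile_split(setNames(dat$ovary_lym_ratio, dat$patient_id),
                          variable = "ovary_lym_ratio")
  ga_age <- median_split(setNames(dat$age, dat$patient_id), variable = "age")
  strata <- data.table(
    patient_id = dat$patient_id,
    metdiv_group = ga_metdiv$labels[dat$patient_id],
    stromal_group = ga_strom$labels[dat$patient_id],
    lym_group = ga_lym$labels[dat$patient_id],
    age_group = ga_age$labels[dat$patient_id]
  )
  emit(cbind(strata,
             data.table(metdiv_threshold = ga_metdiv$threshold,
                        stromal_threshold = ga_strom$threshold,
                        lym_threshold = ga_lym$threshold,
                        age_threshold = ga_age$threshold,
                        metdiv_method = ga_metdiv$method,
                        metdiv_fallback = isTRUE(ga_metdiv$fallback))),
       "stratification.tsv")
  dat <- cbind(dat, strata[, -1])

  uni <- list()
  for (ep in c("OS", "PFS")) {
    tm <- if (ep == "OS") dat$os_months else dat$pfs_months
    ev <- if (ep == "OS") dat$os_event else dat$pfs_event
    uni[[length(uni) + 1]] <- rbindlist(list(
      univariate_row("metdiv_group", dat$metdiv_group, tm, ev, ep),
      univariate_row("ovary_shannon", dat$ovary_shannon, tm, ev, ep),
      univariate_row("lym_group", dat$lym_group, tm, ev, ep),
      univariate_row("stromal_group", dat$stromal_group, tm, ev, ep),
      univariate_row("age_group", dat$age_group, tm, ev, ep),
      univariate_row("chemo_regimen", factor(dat$chemo_regimen), tm, ev, ep),
      univariate_row("debulking", factor(dat$debulking), tm, ev, ep),
      univariate_row("figo_stage", factor(dat$figo_stage), tm, ev, ep),
      univariate_row("metdiv_incl_ovary", dat$metdiv_incl_ovary, tm, ev, ep),
      univariate_row("n_sites", as.numeric(dat$n_sites), tm, ev, ep)
    ))
  }
  uni <- emit(rbindlist(uni), "survival_univariate.tsv")

  # multivariate: eligibility by univariate OS p < 0.05 plus forced covariates
  os_uni <- uni[endpoint == "OS"]
  eligible <- select_multivariate_factors(setNames(os_uni$p, os_uni$variable))
  force <- intersect(config$survival$force, names(dat))
  # the diversity grouping is the marker under study and is always carried
  # into the multivariate model alongside eligible and forced covariates
  mv_vars <- union("metdiv_group",
                   union(intersect(eligible,
                                   c("metdiv_group", "age_group",
                                     "stromal_group", "lym_group")),
                         force))
  multi <- rbindlist(lapply(c("OS", "PFS"), function(ep) {
    tm <- if (ep == "OS") dat$os_months else dat$pfs_months
    ev <- if (ep == "OS") dat$os_event else dat$pfs_event
    fit <- suppressWarnings(
      cox_fit(tm, ev, as.data.frame(dat)[, mv_vars, drop = FALSE],
              endpoint = ep))
    cbind(data.table(endpoint = ep, concordance = fit$concordance),
          fit$table)
  }))
  multi <- emit(multi, "survival_multivariate.tsv")

  rb <- config$robustness
  stab_uni <- resampling_stability(
    dat$os_months, dat$os_event, groups = dat$metdiv_group,
    fractions = rb$fractions, n_reps = rb$n_reps, alpha = rb$alpha,
    seed = derive_seed(cfg$seed, 101), endpoint = "OS")
  stab_multi <- resampling_stability(
    dat$os_months, dat$os_event,
    covariates = as.data.frame(dat)[, mv_vars, drop = FALSE],
    covariate = "metdiv_group",
    fractions = rb$fractions, n_reps = rb$n_reps, alpha = rb$alpha,
    seed = derive_seed(cfg$seed, 102), endpoint = "OS")
  stability <- emit(rbindlist(list(
    cbind(analysis = "univariate", stab_uni$curve),
    cbind(analysis = "multivariate", stab_multi$curve)
  )), "stability.tsv")

  # association and agreement summaries
  ov_strom <- compare_ovary_vs_metastases(prof, "stromal")
  ov_lym <- compare_ovary_vs_metastases(prof, "lymphocyte")
  agree <- index_agreement(secdiv)
  kw_site <- {
    keep <- secdiv[site != "ovary"]
    tab <- table(keep$site)
    keep <- keep[site %in% names(tab)[tab >= 2]]
    if (length(unique(keep$site)) >= 2) {
      kruskal_wallis(keep$shannon, keep$site)
    } else list(statistic = NA_real_, p = NA_real_)
  }
  chemo_tab <- table(factor(dat$chemo_regimen, levels = c("TC/TP", "CBP")),
                     dat$metdiv_group)
  fish <- if (all(dim(chemo_tab) == c(2, 2)) && all(rowSums(chemo_tab) > 0) &&
              all(colSums(chemo_tab) > 0)) {
    fisher_exact(chemo_tab)
  } else list(p = NA_real_)
  km_low <- km_estimate(dat$os_months[dat$metdiv_group == "low"],
                        dat$os_event[dat$metdiv_group == "low"])
  km_high <- km_estimate(dat$os_months[dat$metdiv_group == "high"],
                         dat$os_event[dat$metdiv_group == "high"])
  associations <- emit(data.table(
    quantity = c("ovary_vs_met_stromal_r", "ovary_vs_met_stromal_p",
                 "ovary_vs_met_lym_r", "ovary_vs_met_lym_p",
                 "shannon_vs_simpson_pearson_1mD", "shannon_vs_simpson_spearman",
                 "site_diversity_kruskal_p", "chemo_vs_metdiv_fisher_p",
                 "os_5yr_low_metdiv", "os_5yr_high_metdiv"),
    value = c(ov_strom$r, ov_strom$p, ov_lym$r, ov_lym$p,
              agree$pearson_one_minus_d, agree$spearman,
              kw_site$p, fish$p,
              as.numeric(landmark_survival(km_low, 60)),
              as.numeric(landmark_survival(km_high, 60)))
  ), "associations.tsv")

  validation <- NULL
  if (config$validation$simulate) {
    ann <- simulate_annotations(seed = derive_seed(cfg$seed, 103))
    validation <- emit(confusion_metrics(ann, by_site = TRUE),
                       "validation_metrics.tsv")
  }

  if (plots) {
    grDevices::png(file.path(out_dir, "km_metdiv_os.png"), 900, 700, res = 120)
    plot_km_groups(dat$os_months, dat$os_event, dat$metdiv_group,
                   main = "OS by MetDiv group")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "ternary_diversity.png"), 900, 800, res = 120)
    plot_ternary(secdiv)
    grDevices::dev.off()
  }

  manifest <- list(
    package = "metdiv",
    version = as.character(utils::packageVersion("metdiv")),
    seed = cfg$seed,
    stage_seeds = list(robustness_univariate = derive_seed(cfg$seed, 101),
                       robustness_multivariate = derive_seed(cfg$seed, 102),
                       validation = derive_seed(cfg$seed, 103)),
    config = config_snapshot(cfg),
    n_patients_input = nrow(cohort$clinical),
    n_patients_profiled = nrow(prof),
    excluded_patients = as.list(excluded),
    rows = lapply(setNames(files, basename(files)), function(f) {
      length(readLines(f)) - 1L
    }),
    md5 = as.list(tools::md5sum(files))
  )
  names(manifest$md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, section_diversity = secdiv,
                 profiles = prof, stratification = strata,
                 survival_univariate = uni, survival_multivariate = multi,
                 stability = stability, associations = associations,
                 validation = validation))
}

config_snapshot <- function(cfg) {
  list(
    n_patients = cfg$n_patients,
    site_frequencies = as.list(cfg$site_frequencies),
    sites_per_patient = as.list(cfg$sites_per_patient),
    composition_priors = lapply(cfg$composition_priors, as.list),
    cells_per_section = cfg$cells_per_section,
    count_multiplier = cfg$count_multiplier,
    patient_effect_sd = cfg$patient_effect_sd,
    spatial_mode = cfg$spatial_mode,
    section_size_um = cfg$section_size_um,
    cluster_params = cfg$cluster_params,
    survival_model = cfg$survival_model,
    seed = cfg$seed
  )
}
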