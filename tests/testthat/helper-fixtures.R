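# Programmatic fixtures: no data files, everything is generated in code.

make_section <- function(n, p, seed = 1, patient = "P1", section = "S1",
                         site = "omentum", L = 20000) {
  set.seed(seed)
  data.table::data.table(
    patient_id = patient, section_id = section, site = site,
    x = runif(n, 0, L), y = runif(n, 0, L),
    cell_class = sample(cell_classes(), n, replace = TRUE, prob = p)
  )
}

# A per-section diversity table built by hand (bypasses cell sampling) for
# aggregation arithmetic tests.
make_secdiv <- function(patient, site, shannon,
                        p_stromal = 0.2, p_lym = 0.1) {
  data.table::data.table(
    section_id = sprintf("%s_%s", patient, site),
    patient_id = patient, site = site, n_cells = 1000L,
    p_cancer = 1 - p_stromal - p_lym, p_lymphocyte = p_lym,
    p_stromal = p_stromal, shannon = shannon,
    simpson = NA_real_
  )
}

# Small, fast cohort configuration (tiny sections) for structural tests.
small_config <- function(...) {
  cohort_config(count_multiplier = 0.002, ...)
}

# Survival model list with selected overrides of the defaults.
surv_model <- function(...) {
  utils::modifyList(
    list(os_median = 43.33, pfs_median = 19.8, log_hr_os = log(3.18),
         log_hr_pfs = log(2.83), high_fraction = 0.5, censor_time = 120,
         censor_fraction = 0.33),
    list(...)
  )
}

pairs_from_matrix <- function(M) {
  cls <- cell_classes()
  idx <- which(M > 0, arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    data.frame(expert_class = cls[idx[k, 1]], predicted_class = cls[idx[k, 2]],
               n = M[idx[k, 1], idx[k, 2]])
  }))
  data.table::data.table(
    cell_id = seq_len(sum(M)),
    site = "omentum",
    expert_class = rep(rows$expert_class, rows$n),
    predicted_class = rep(rows$predicted_class, rows$n)
  )
}
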