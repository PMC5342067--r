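#' Dirichlet random deviates
#'
#' Standard gamma-ratio construction; used for sampling per-section
#' cell-type compositions from site-specific concentration triples.
#'
#' @param n Number of draws.
#' @param alpha Strictly positive concentration vector.
#' @return `n` x `length(alpha)` matrix; rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stopf("Dirichlet concentrations must be > 0")
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against all-zero rows for very small concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  x <- x / rowSums(x)
  colnames(x) <- names(alpha)
  x
}

#' Sample per-section cell counts for one class
#'
#' Draws whole-section counts from the configured log-normal model,
#' scaled by the desk-scale `count_multiplier`. Draws are
#' `mean * multiplier * exp(sdlog * Z - sdlog^2/2)` rounded to a positive
#' integer, so the arithmetic mean equals `mean * multiplier` and a zero
#' `sdlog` yields the constant configured mean.
#'
#' @param config A [cohort_config()].
#' @param class One of `cell_classes()`.
#' @param n Number of draws.
#' @param seed Optional seed for standalone use.
#' @return Integer vector of positive counts.
#' @export
sample_section_count <- function(config, class, n = 1, seed = NULL) {
  if (!class %in% names(config$cells_per_section)) {
    stopf("unknown cell class '%s'", class)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- config$cells_per_section[[class]]
  mu <- m$mean * config$count_multiplier
  pmax(1L, as.integer(round(mu * exp(m$sdlog * rnorm(n) - m$sdlog^2 / 2))))
}

# Place n cells in the square section footprint. Uniform mode scatters
# independently; clustered mode is a Matern-style parent-offspring process
# (parents uniform, Gaussian offspring, reflected into the footprint).
place_cells <- function(n, config) {
  L <- config$section_size_um
  if (config$spatial_mode == "uniform") {
    return(list(x = runif(n, 0, L), y = runif(n, 0, L)))
  }
  k <- max(1L, as.integer(config$cluster_params$n_clusters))
  spread <- config$cluster_params$spread_um
  px <- runif(k, 0, L)
  py <- runif(k, 0, L)
  parent <- sample.int(k, n, replace = TRUE)
  reflect <- function(v) {
    v <- abs(v)
    v <- ifelse(v > L, 2 * L - v, v)
    pmin(pmax(v, 0), L)
  }
  list(x = reflect(px[parent] + rnorm(n, 0, spread)),
       y = reflect(py[parent] + rnorm(n, 0, spread)))
}

# Core section sampler given an already-drawn composition.
generate_section_cells <- function(patient_id, section_id, site, p, config) {
  n <- sum(vapply(CELL_CLASSES, function(cl) {
    sample_section_count(config, cl)
  }, integer(1)))
  classes <- sample(CELL_CLASSES, n, replace = TRUE, prob = p)
  coords <- place_cells(n, config)
  data.table(
    patient_id = patient_id, section_id = section_id, site = site,
    x = coords$x, y = coords$y, cell_class = classes
  )
}

#' Generate a single synthetic tumor section
#'
#' Samples a cell-type composition from the site's Dirichlet prior, a cell
#' count from the per-class count models, and cell coordinates by the
#' configured spatial mode. The drawn (ground-truth) composition is attached
#' as attribute `"composition"`.
#'
#' @param site Site label present in `config$composition_priors`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param patient_id,section_id Identifiers stamped on the rows.
#' @return `data.table` of cell records (`patient_id`, `section_id`, `site`,
#'   `x`, `y`, `cell_class`).
#' @export
generate_section <- function(site, config, seed,
                             patient_id = "P1", section_id = "S1") {
  if (!site %in% names(config$composition_priors)) {
    stopf("unknown site label '%s' (no composition prior configured)", site)
  }
  set.seed(seed)
  p <- drop(rdirichlet(1, config$composition_priors[[site]]))
  cells <- generate_section_cells(patient_id, section_id, site, p, config)
  attr(cells, "composition") <- p
  cells
}

#' Generate a synthetic multi-site cohort with ground truth
#'
#' Generates `config$n_patients` patients, each with one ovary section plus
#' 1-4 distinct non-ovary sections (total sites drawn from
#' `config$sites_per_patient`), per-section ground-truth compositions from
#' the site priors (optionally tilted by a per-patient effect), clinical
#' covariates, and OS/PFS outcomes from an exponential proportional-hazards
#' model in which the top `high_fraction` of true MetDiv (mean true Shannon
#' diversity over non-ovary sections) carries the configured log hazard
#' ratios. Progression and death times are coupled so PFS never exceeds OS.
#'
#' @param config A [cohort_config()].
#' @param cells If `TRUE`, cell tables are generated for every section
#'   (per-section seeds derived from the root seed, so the clinical table and
#'   ground truth are identical whether or not cells are materialized).
#' @return Object of class `synthetic_cohort`: list with `cells` (one
#'   `data.table` of cell records, or `NULL`), `clinical` (`data.table`),
#'   `truth` (list with per-`sections` and per-`patients` ground truth),
#'   and `config`.
#' @export
generate_cohort <- function(config, cells = TRUE) {
  set.seed(config$seed)
  n <- config$n_patients
  sm <- config$survival_model

  pid <- sprintf("P%03d", seq_len(n))
  ks <- as.integer(sample(names(config$sites_per_patient), n, replace = TRUE,
                          prob = config$sites_per_patient))

  sec_list <- vector("list", n)
  for (i in seq_len(n)) {
    met <- sample(names(config$site_weights), ks[i] - 1L,
                  prob = config$site_weights)
    sites <- c("ovary", met)
    tilt <- if (config$patient_effect_sd > 0) {
      exp(rnorm(3, 0, config$patient_effect_sd))
    } else rep(1, 3)
    comp <- t(vapply(sites, function(s) {
      drop(rdirichlet(1, config$composition_priors[[s]] * tilt))
    }, numeric(3)))
    sec_list[[i]] <- data.table(
      patient_id = pid[i],
      section_id = sprintf("%s_%s", pid[i], sites),
      site = sites,
      true_cancer = comp[, 1], true_lymphocyte = comp[, 2],
      true_stromal = comp[, 3]
    )
  }
  sections <- rbindlist(sec_list)
  sections[, true_shannon := apply(
    as.matrix(.SD), 1, shannon_index, validate = FALSE),
    .SDcols = c("true_cancer", "true_lymphocyte", "true_stromal")]

  true_metdiv <- sections[site != "ovary",
                          .(true_metdiv = mean(true_shannon)), by = patient_id]
  thr <- quantile(true_metdiv$true_metdiv, 1 - sm$high_fraction,
                  names = FALSE, type = 7)
  true_metdiv[, true_group := ifelse(true_metdiv >= thr, "high", "low")]

  # clinical covariates emulating the cohort summary table
  age <- pmin(pmax(round(rnorm(n, 55, 11)), 22), 82)
  figo <- sample(c("IIIc", "IV"), n, replace = TRUE, prob = c(0.9, 0.1))
  debulk <- sample(c("optimal", "suboptimal"), n, replace = TRUE)
  chemo <- sample(c("TC/TP", "CBP"), n, replace = TRUE, prob = c(0.886, 0.114))

  high <- true_metdiv$true_group == "high"
  lam_os <- log(2) / sm$os_median * exp(sm$log_hr_os * high)
  lam_pfs <- log(2) / sm$pfs_median * exp(sm$log_hr_pfs * high)
  death <- rexp(n, lam_os)
  progression <- rexp(n, lam_pfs)

  cens <- rep(sm$censor_time, n)
  extra <- runif(n) < sm$censor_fraction
  if (any(extra)) {
    upper <- if (is.finite(sm$censor_time)) sm$censor_time else 2 * sm$os_median
    cens[extra] <- runif(sum(extra), 0, upper)
  }
  os_months <- pmin(death, cens)
  os_event <- as.integer(death <= cens)
  pfs_raw <- pmin(progression, death)
  pfs_months <- pmin(pfs_raw, cens)
  pfs_event <- as.integer(pfs_raw <= cens)
  # guard against zero-duration follow-up
  os_months <- pmax(os_months, 0.01)
  pfs_months <- pmax(pfs_months, 0.01)

  clinical <- data.table(
    patient_id = pid, age = age, figo_stage = figo, debulking = debulk,
    chemo_regimen = chemo, os_months = os_months, os_event = os_event,
    pfs_months = pfs_months, pfs_event = pfs_event
  )

  cell_tab <- NULL
  if (cells) {
    sec_seed <- derive_seed(config$seed, seq_len(nrow(sections)))
    parts <- vector("list", nrow(sections))
    for (j in seq_len(nrow(sections))) {
      set.seed(sec_seed[j])
      parts[[j]] <- generate_section_cells(
        sections$patient_id[j], sections$section_id[j], sections$site[j],
        c(sections$true_cancer[j], sections$true_lymphocyte[j],
          sections$true_stromal[j]),
        config
      )
    }
    cell_tab <- rbindlist(parts)
  }

  structure(list(
    cells = cell_tab,
    clinical = clinical,
    truth = list(sections = sections,
                 patients = true_metdiv,
                 metdiv_threshold = thr,
                 log_hr_os = sm$log_hr_os,
                 log_hr_pfs = sm$log_hr_pfs,
                 seed = config$seed),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d patients, %d sections%s\n",
              nrow(x$clinical), nrow(x$truth$sections),
              if (is.null(x$cells)) " (ground truth only, no cells)"
              else sprintf(", %d cells", nrow(x$cells))))
  cat(sprintf("  true OS HR (high vs low MetDiv): %.2f, seed %d\n",
              exp(x$truth$log_hr_os), x$truth$seed))
  invisible(x)
}
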