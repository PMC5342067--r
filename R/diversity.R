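#' Cell-type composition of a section
#'
#' The cell ratio of each class: its count divided by all classified cells
#' in the section. Absent classes get proportion 0.
#'
#' @param cells Character vector of cell classes, or a data.frame with a
#'   `cell_class` column.
#' @return Named numeric vector of proportions over
#'   `(cancer, lymphocyte, stromal)` with attribute `n_cells`.
#' @export
cell_composition <- function(cells) {
  cl <- if (is.data.frame(cells)) cells$cell_class else cells
  if (length(cl) == 0) stopf("empty section: composition undefined")
  bad <- setdiff(unique(cl), CELL_CLASSES)
  if (length(bad) > 0) stopf("unknown cell class(es): %s", paste(bad, collapse = ", "))
  counts <- vapply(CELL_CLASSES, function(k) sum(cl == k), numeric(1))
  p <- counts / sum(counts)
  attr(p, "n_cells") <- as.integer(sum(counts))
  p
}

check_composition <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stopf("invalid composition: proportions must be >= 0 and sum to 1")
  }
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `0 * log(0) := 0`. High values
#' indicate even mixtures of cell types; 0 indicates single-class dominance.
#' Bounded by `log(R)` for `R` classes.
#'
#' @param p Proportion vector (any length >= 1).
#' @param validate Check that `p` is a valid composition (default `TRUE`).
#' @return Shannon entropy in nats.
#' @export
shannon_index <- function(p, validate = TRUE) {
  if (validate) check_composition(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Simpson index
#'
#' `D = sum(p_i^2)`: the probability that two randomly drawn cells share a
#' class. 1 means a homogeneous section; `1/R` an even `R`-class mixture.
#'
#' @inheritParams shannon_index
#' @return Simpson index in `[1/R, 1]`.
#' @export
simpson_index <- function(p, validate = TRUE) {
  if (validate) check_composition(p)
  sum(p^2)
}

#' Per-section diversity scores
#'
#' Computes, for every section in a cell table, the class composition and
#' both diversity indices.
#'
#' @param cells Cell table (data.frame with `patient_id`, `section_id`,
#'   `site`, `cell_class`), e.g. from [generate_cohort()] or
#'   [read_cell_table()].
#' @return `data.table`, one row per section: identifiers, `n_cells`,
#'   `p_cancer`, `p_lymphocyte`, `p_stromal`, `shannon`, `simpson`.
#' @export
diversity_by_section <- function(cells) {
  cells <- as.data.table(cells)
  if (nrow(cells) == 0) stopf("empty cell table")
  out <- cells[, {
    p <- cell_composition(cell_class)
    list(patient_id = patient_id[1], site = site[1],
         n_cells = attr(p, "n_cells"),
         p_cancer = p[["cancer"]], p_lymphocyte = p[["lymphocyte"]],
         p_stromal = p[["stromal"]],
         shannon = shannon_index(p, validate = FALSE),
         simpson = simpson_index(p, validate = FALSE))
  }, by = section_id]
  setorder(out, patient_id, section_id)
  out[]
}

#' Per-patient diversity profiles (MetDiv and sibling aggregates)
#'
#' Aggregates per-section diversity into patient-level scores. MetDiv is the
#' unweighted mean Shannon diversity over all non-ovary sections. Patients
#' without a non-ovary section get `NA` MetDiv (excluded downstream with a
#' warning); more than one ovary section is an error.
#'
#' @param section_div Output of [diversity_by_section()].
#' @return `data.table`, one row per patient: `metdiv`, `metdiv_incl_ovary`,
#'   `shannon_sd` (sample SD over non-ovary sections; `NA` if fewer than 2),
#'   `ovary_shannon`, `ovary_stromal_ratio`, `ovary_lym_ratio`,
#'   `mean_met_stromal_ratio`, `mean_met_lym_ratio`, `n_sites`.
#' @export
patient_profiles <- function(section_div) {
  sd_dt <- as.data.table(section_div)
  n_ov <- sd_dt[site == "ovary", .N, by = patient_id]
  if (any(n_ov$N > 1)) {
    stopf("patient(s) with more than one ovary section: %s",
          paste(n_ov[N > 1, patient_id], collapse = ", "))
  }
  prof <- sd_dt[, {
    met <- site != "ovary"
    ov <- site == "ovary"
    list(
      metdiv = if (any(met)) mean(shannon[met]) else NA_real_,
      metdiv_incl_ovary = mean(shannon),
      shannon_sd = if (sum(met) >= 2) sd(shannon[met]) else NA_real_,
      ovary_shannon = if (any(ov)) shannon[ov] else NA_real_,
      ovary_stromal_ratio = if (any(ov)) p_stromal[ov] else NA_real_,
      ovary_lym_ratio = if (any(ov)) p_lymphocyte[ov] else NA_real_,
      mean_met_stromal_ratio = if (any(met)) mean(p_stromal[met]) else NA_real_,
      mean_met_lym_ratio = if (any(met)) mean(p_lymphocyte[met]) else NA_real_,
      n_sites = .N
    )
  }, by = patient_id]
  if (anyNA(prof$metdiv)) {
    warnf("%d patient(s) have no non-ovary section; MetDiv undefined: %s",
          sum(is.na(prof$metdiv)),
          paste(prof[is.na(metdiv), patient_id], collapse = ", "))
  }
  setorder(prof, patient_id)
  prof[]
}

#' Ovary vs metastasis cell-ratio correlation
#'
#' Pearson correlation (with two-sided p) across patients between a cell
#' ratio measured in the ovary section and the mean of the same ratio over
#' the patient's non-ovary sections.
#'
#' @param profiles Output of [patient_profiles()].
#' @param cell_class `"stromal"` or `"lymphocyte"`.
#' @return List: `r`, `p`, `n`, `cell_class`.
#' @export
compare_ovary_vs_metastases <- function(profiles,
                                        cell_class = c("stromal", "lymphocyte")) {
  cell_class <- match.arg(cell_class)
  prof <- as.data.table(profiles)
  ov <- if (cell_class == "stromal") prof$ovary_stromal_ratio else prof$ovary_lym_ratio
  met <- if (cell_class == "stromal") prof$mean_met_stromal_ratio else prof$mean_met_lym_ratio
  ok <- is.finite(ov) & is.finite(met)
  if (sum(ok) < 3) stopf("need >= 3 patients with both ovary and metastasis ratios")
  ct <- cor.test(ov[ok], met[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       cell_class = cell_class)
}

#' Agreement between Shannon and Simpson indices across sections
#'
#' Raw Simpson decreases as Shannon increases, so the correlation is
#' reported in both orientations (against `D` and against `1 - D`) for
#' Pearson, plus the Spearman rank correlation, leaving the orientation
#' choice explicit.
#'
#' @param section_div Output of [diversity_by_section()].
#' @return List: `pearson_d` (H vs D), `pearson_one_minus_d` (H vs 1-D),
#'   `spearman`, `n`.
#' @export
index_agreement <- function(section_div) {
  sd_dt <- as.data.table(section_div)
  if (nrow(sd_dt) < 3) stopf("need >= 3 sections")
  if (sd(sd_dt$shannon) == 0 || sd(sd_dt$simpson) == 0) {
    stopf("zero variance in diversity scores; correlation undefined")
  }
  list(
    pearson_d = cor(sd_dt$shannon, sd_dt$simpson, method = "pearson"),
    pearson_one_minus_d = cor(sd_dt$shannon, 1 - sd_dt$simpson,
                              method = "pearson"),
    spearman = cor(sd_dt$shannon, sd_dt$simpson, method = "spearman"),
    n = nrow(sd_dt)
  )
}

#' Shannon diversity over the 3-class simplex
#'
#' Evaluates Shannon entropy on a barycentric lattice of the 2-simplex, the
#' theoretical background used for ternary diversity plots.
#'
#' @param resolution Lattice subdivisions per edge (>= 2); the grid holds all
#'   integer triples `(i, j, k)` with `i + j + k = resolution`.
#' @return `data.table` with `p_cancer`, `p_lymphocyte`, `p_stromal`,
#'   `shannon`.
#' @export
shannon_simplex_field <- function(resolution = 100) {
  if (resolution < 2) stopf("resolution must be >= 2")
  res <- as.integer(resolution)
  grid <- as.data.table(expand.grid(i = 0:res, j = 0:res))
  grid <- grid[i + j <= res]
  grid[, k := res - i - j]
  out <- data.table(
    p_cancer = grid$i / res,
    p_lymphocyte = grid$j / res,
    p_stromal = grid$k / res
  )
  out[, shannon := apply(as.matrix(.SD), 1, shannon_index, validate = FALSE),
      .SDcols = c("p_cancer", "p_lymphocyte", "p_stromal")]
  out[]
}
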