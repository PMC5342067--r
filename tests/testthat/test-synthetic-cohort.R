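test_that("section and cohort generation are seed-deterministic", {
  cfg <- small_config(seed = 11)
  s1 <- generate_section("omentum", cfg, seed = 5)
  s2 <- generate_section("omentum", cfg, seed = 5)
  expect_identical(s1, s2)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  c1 <- generate_cohort(cfg, cells = TRUE)
  c2 <- generate_cohort(cfg, cells = TRUE)
  expect_identical(serialize(c1$cells, NULL), serialize(c2$cells, NULL))
  expect_identical(serialize(c1$clinical, NULL), serialize(c2$clinical, NULL))
  expect_identical(c1$truth$sections, c2$truth$sections)

  # clinical table does not depend on whether cells are materialized
  c3 <- generate_cohort(cfg, cells = FALSE)
  expect_identical(c1$clinical, c3$clinical)
  expect_null(c3$cells)
})

test_that("site priors produce the expected composition contrasts", {
  cfg <- small_config(seed = 3)
  lymph <- vapply(1:200, function(i) {
    mean(generate_section("lymph_node", cfg, seed = i)$cell_class == "lymphocyte")
  }, numeric(1))
  oment <- vapply(1:200, function(i) {
    mean(generate_section("omentum", cfg, seed = 1000 + i)$cell_class == "lymphocyte")
  }, numeric(1))
  expect_gt(mean(lymph), mean(oment))

  # degenerate prior concentrates all mass on cancer
  cfg_deg <- small_config(
    composition_priors = utils::modifyList(
      default_composition_priors(),
      list(omentum = c(cancer = 1e6, lymphocyte = 1e-3, stromal = 1e-3))),
    seed = 1)
  s <- generate_section("omentum", cfg_deg, seed = 2)
  expect_true(all(s$cell_class == "cancer"))

  expect_error(generate_section("brain", cfg, seed = 1), "unknown site")
})

test_that("every patient gets one ovary plus 1-4 distinct non-ovary sections, median 3 sites", {
  co <- generate_cohort(cohort_config(n_patients = 2000, seed = 21), cells = FALSE)
  secs <- co$truth$sections
  per_pat <- secs[, .(k = .N, n_ov = sum(site == "ovary"),
                      dup = anyDuplicated(site) > 0), by = patient_id]
  expect_true(all(per_pat$n_ov == 1))
  expect_true(all(per_pat$k >= 2 & per_pat$k <= 5))
  expect_false(any(per_pat$dup))
  expect_equal(median(per_pat$k), 3)
})

test_that("realized site frequencies match the configured frequencies within 3 SE", {
  cfg <- cohort_config(n_patients = 1000, seed = 31)
  co <- generate_cohort(cfg, cells = FALSE)
  met <- co$truth$sections[site != "ovary"]
  n <- nrow(met)
  for (s in names(cfg$site_frequencies)) {
    f_target <- cfg$site_frequencies[[s]]
    f_obs <- mean(met$site == s)
    se <- sqrt(f_target * (1 - f_target) / n)
    expect_lt(abs(f_obs - f_target), 3 * se)
  }
})

test_that("empirical section composition converges to the ground-truth mixture", {
  p <- c(0.55, 0.25, 0.20)
  cfg <- small_config(seed = 8)
  set.seed(99)
  cells <- metdiv:::generate_section_cells("P1", "S1", "omentum", p,
    cohort_config(count_multiplier = 1,
      cells_per_section = list(
        cancer = lognormal_count_model(60000, 60000, 60000),
        lymphocyte = lognormal_count_model(25000, 25000, 25000),
        stromal = lognormal_count_model(15000, 15000, 15000)),
      seed = 1))
  emp <- cell_composition(cells$cell_class)
  expect_lt(max(abs(unname(emp) - p)), 0.01)

  # cohort ground truth matches empirical composition of generated cells
  co <- generate_cohort(cohort_config(n_patients = 10, count_multiplier = 0.05,
                                      seed = 13), cells = TRUE)
  sd1 <- diversity_by_section(co$cells)
  m <- merge(sd1, co$truth$sections, by = c("section_id", "patient_id", "site"))
  expect_lt(max(abs(m$p_cancer - m$true_cancer)), 0.05)
  expect_lt(max(abs(m$p_lymphocyte - m$true_lymphocyte)), 0.05)
  expect_lt(max(abs(m$p_stromal - m$true_stromal)), 0.05)
})

test_that("per-class count sampler matches the configured mean and scales linearly", {
  cfg_full <- cohort_config(count_multiplier = 1, seed = 1)
  draws <- sample_section_count(cfg_full, "cancer", n = 10000, seed = 17)
  expect_equal(mean(draws), 362417, tolerance = 0.1)

  cfg_desk <- cohort_config(count_multiplier = 0.01, seed = 1)
  draws_d <- sample_section_count(cfg_desk, "cancer", n = 10000, seed = 17)
  expect_equal(mean(draws_d), 3624.17, tolerance = 0.1)

  # degenerate variance: constant count equal to the configured mean
  cfg_const <- cohort_config(
    count_multiplier = 1,
    cells_per_section = list(cancer = lognormal_count_model(500, 500, 500),
                             lymphocyte = lognormal_count_model(100, 100, 100),
                             stromal = lognormal_count_model(200, 200, 200)),
    seed = 1)
  expect_true(all(sample_section_count(cfg_const, "cancer", 50, seed = 1) == 500))
  expect_error(sample_section_count(cfg_full, "epithelial"), "unknown cell class")
})

test_that("survival generation honors censoring settings and couples PFS to OS", {
  cfg <- small_config(
    survival_model = surv_model(censor_fraction = 0, censor_time = Inf),
    seed = 41)
  co <- generate_cohort(cfg, cells = FALSE)
  expect_true(all(co$clinical$os_event == 1))
  expect_true(all(co$clinical$pfs_event == 1))
  expect_true(all(co$clinical$pfs_months <= co$clinical$os_months + 1e-12))

  cfg2 <- small_config(survival_model = surv_model(censor_time = 120),
                       seed = 42)
  co2 <- generate_cohort(cfg2, cells = FALSE)
  expect_true(all(co2$clinical$os_months <= 120))
  expect_true(any(co2$clinical$os_event == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(site_frequencies = c(omentum = 0.5, peritoneum = 0.4)),
               "sum to 1")
  expect_error(cohort_config(sites_per_patient = c("1" = 0.5, "3" = 0.5)),
               "2..5")
  expect_error(cohort_config(
    composition_priors = utils::modifyList(default_composition_priors(),
                                           list(ovary = c(1, 0, 1)))),
    "strictly positive")
  expect_error(cohort_config(survival_model = surv_model(os_median = -1)),
               "positive")
  expect_error(cohort_config(survival_model = surv_model(high_fraction = 1.5)),
               "high_fraction")
})

test_that("clustered spatial mode keeps cells inside the section footprint", {
  cfg <- small_config(spatial_mode = "clustered", seed = 5)
  s <- generate_section("omentum", cfg, seed = 9)
  expect_true(all(s$x >= 0 & s$x <= cfg$section_size_um))
  expect_true(all(s$y >= 0 & s$y <= cfg$section_size_um))
  # clustering induces more spatial aggregation than uniform: compare
  # variance of local counts on a coarse grid
  cfg_u <- small_config(spatial_mode = "uniform", seed = 5)
  su <- generate_section("omentum", cfg_u, seed = 9)
  bin_var <- function(d) {
    gx <- floor(d$x / 2000); gy <- floor(d$y / 2000)
    counts <- table(paste(gx, gy))
    var(as.numeric(counts)) / mean(counts)
  }
  expect_gt(bin_var(s), bin_var(su))
})
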