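test_that("shannon and simpson match closed forms on canonical compositions", {
  u <- rep(1 / 3, 3)
  expect_equal(shannon_index(u), log(3), tolerance = 1e-14)
  expect_equal(simpson_index(u), 1 / 3, tolerance = 1e-14)
  expect_identical(shannon_index(c(1, 0, 0)), 0)
  expect_identical(simpson_index(c(1, 0, 0)), 1)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_index(p), 1.5 * log(2), tolerance = 1e-14)
  expect_equal(simpson_index(p), 0.375, tolerance = 1e-14)
  expect_equal(shannon_index(c(0.5, 0.5, 0)), log(2), tolerance = 1e-14)
})

test_that("indices agree with direct-summation oracle, respect bounds and label permutations", {
  set.seed(42)
  comps <- rbind(
    rdirichlet(400, c(1, 1, 1)),
    rdirichlet(300, c(0.2, 0.2, 0.2)),   # sparse, near-vertex
    rdirichlet(300, c(8, 3, 2)),
    c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0)
  )
  for (i in seq_len(nrow(comps))) {
    p <- comps[i, ]
    h <- shannon_index(p)
    d <- simpson_index(p)
    expect_equal(h, oracle_shannon(p), tolerance = 1e-12)
    expect_equal(d, oracle_simpson(p), tolerance = 1e-12)
    expect_true(h >= 0 && h <= log(3) + 1e-12)
    expect_true(d >= 1 / 3 - 1e-12 && d <= 1)
    perm <- sample(3)
    expect_equal(shannon_index(p[perm]), h, tolerance = 1e-12)
    expect_equal(simpson_index(p[perm]), d, tolerance = 1e-12)
    # dominance equivalence
    expect_equal(h == 0, d == 1)
    expect_equal(d == 1, any(p == 1))
  }
})

test_that("cell_composition returns plug-in ratios and rejects empty sections", {
  p <- cell_composition(rep(c("cancer", "lymphocyte", "stromal"), c(2, 1, 1)))
  expect_equal(as.numeric(p), c(0.5, 0.25, 0.25))
  expect_equal(attr(p, "n_cells"), 4L)
  expect_error(cell_composition(character(0)), "empty")
  expect_error(cell_composition(c("cancer", "epithelial")), "epithelial")
  # mean per-class counts of the reference cohort
  p2 <- cell_composition(rep(c("cancer", "lymphocyte", "stromal"),
                             c(362417, 67433, 92861)))
  expect_equal(as.numeric(p2), c(0.6933, 0.1290, 0.1777), tolerance = 1e-4)
})

test_that("per-section diversity recovers the generating mixture", {
  p <- c(0.6, 0.2, 0.2)
  cells <- make_section(1e5, p, seed = 7)
  sd1 <- diversity_by_section(cells)
  expect_equal(nrow(sd1), 1L)
  expect_equal(sd1$shannon, -(0.6 * log(0.6) + 0.4 * log(0.2)),
               tolerance = 0.005)
  expect_true(max(abs(c(sd1$p_cancer, sd1$p_lymphocyte, sd1$p_stromal) - p)) < 0.01)

  # single-class dominance and equality of identical compositions
  mono <- make_section(500, c(1, 0, 0), seed = 1, section = "S2")
  sd2 <- diversity_by_section(mono)
  expect_identical(sd2$shannon, 0)
  expect_identical(sd2$simpson, 1)

  dup <- data.table::copy(cells)[, section_id := "S3"]
  sd3 <- diversity_by_section(rbind(cells, dup))
  expect_equal(sd3$shannon[1], sd3$shannon[2])
  expect_equal(sd3$simpson[1], sd3$simpson[2])
})

test_that("patient profiles aggregate Shannon scores per the MetDiv definition", {
  sec <- rbind(make_secdiv("P1", "ovary", 0.2),
               make_secdiv("P1", "omentum", 0.9),
               make_secdiv("P1", "peritoneum", 1.1))
  prof <- patient_profiles(sec)
  expect_equal(prof$metdiv, 1.0)
  expect_equal(prof$metdiv_incl_ovary, 0.7333333, tolerance = 1e-6)
  expect_equal(prof$shannon_sd, sd(c(0.9, 1.1)))
  expect_equal(prof$ovary_shannon, 0.2)
  expect_equal(prof$n_sites, 3L)

  # permuting section order leaves the profile unchanged
  prof2 <- patient_profiles(sec[c(3, 1, 2)])
  expect_equal(prof, prof2)

  single <- rbind(make_secdiv("P2", "ovary", 0.3),
                  make_secdiv("P2", "omentum", 0.7))
  prof3 <- patient_profiles(single)
  expect_equal(prof3$metdiv, 0.7)
  expect_true(is.na(prof3$shannon_sd))

  # no non-ovary section: NA MetDiv with warning; duplicate ovary: error
  expect_warning(p4 <- patient_profiles(make_secdiv("P3", "ovary", 0.5)),
                 "MetDiv undefined")
  expect_true(is.na(p4$metdiv))
  expect_error(patient_profiles(rbind(make_secdiv("P5", "ovary", 0.1),
                                      make_secdiv("P5", "ovary", 0.2))),
               "more than one ovary")
})

test_that("MetDiv is invariant to duplicating a section's cells", {
  cells <- rbind(make_section(2000, c(0.6, 0.2, 0.2), seed = 2,
                              site = "ovary", section = "P1_ov"),
                 make_section(2000, c(0.4, 0.3, 0.3), seed = 3,
                              site = "omentum", section = "P1_om"))
  prof1 <- patient_profiles(diversity_by_section(cells))
  doubled <- rbind(cells, cells[section_id == "P1_om"])
  prof2 <- patient_profiles(diversity_by_section(doubled))
  expect_equal(prof1$metdiv, prof2$metdiv, tolerance = 1e-12)
})

test_that("ovary-vs-metastasis correlation handles exact and sampled cases", {
  x <- seq(0.1, 0.7, length.out = 10)
  prof <- data.table::data.table(ovary_stromal_ratio = x,
                                 mean_met_stromal_ratio = x,
                                 ovary_lym_ratio = x,
                                 mean_met_lym_ratio = 0.8 - x)
  expect_equal(compare_ovary_vs_metastases(prof, "stromal")$r, 1)
  expect_equal(compare_ovary_vs_metastases(prof, "lymphocyte")$r, -1)
  expect_error(compare_ovary_vs_metastases(prof[1:2], "stromal"), ">= 3")

  # sampling distribution of Pearson r at rho = 0.3, n = 61
  set.seed(99)
  rho <- 0.3
  rs <- replicate(2000, {
    z <- rnorm(61)
    y <- rho * z + sqrt(1 - rho^2) * rnorm(61)
    compare_ovary_vs_metastases(
      data.table::data.table(ovary_stromal_ratio = z,
                             mean_met_stromal_ratio = y), "stromal")$r
  })
  expect_equal(mean(rs), rho, tolerance = 0.02)
})

test_that("Shannon-Simpson agreement is reported in both orientations", {
  # two-class gradient: both indices monotone in t
  ts <- seq(0.5, 0.99, by = 0.01)
  sec <- data.table::data.table(
    section_id = sprintf("S%02d", seq_along(ts)), patient_id = "P1",
    site = "omentum", n_cells = 1000L,
    p_cancer = ts, p_lymphocyte = 1 - ts, p_stromal = 0,
    shannon = vapply(ts, function(t) shannon_index(c(t, 1 - t, 0)), numeric(1)),
    simpson = vapply(ts, function(t) simpson_index(c(t, 1 - t, 0)), numeric(1))
  )
  ia <- index_agreement(sec)
  expect_equal(abs(ia$spearman), 1)
  expect_equal(ia$pearson_one_minus_d, -ia$pearson_d, tolerance = 1e-12)

  same <- sec[rep(1, 5)][, section_id := sprintf("R%d", 1:5)]
  expect_error(index_agreement(same), "zero variance")

  set.seed(5)
  comps <- rdirichlet(192, c(1, 1, 1))
  rand <- data.table::data.table(
    section_id = sprintf("S%03d", 1:192), patient_id = "P1", site = "omentum",
    n_cells = 1000L, p_cancer = comps[, 1], p_lymphocyte = comps[, 2],
    p_stromal = comps[, 3],
    shannon = apply(comps, 1, shannon_index),
    simpson = apply(comps, 1, simpson_index)
  )
  expect_gt(abs(index_agreement(rand)$pearson_d), 0.9)
})

test_that("the simplex Shannon field hits the analytic landmarks", {
  f <- shannon_simplex_field(60)
  expect_true(all(abs(f$p_cancer + f$p_lymphocyte + f$p_stromal - 1) < 1e-12))
  center <- f[abs(p_cancer - 1 / 3) < 1e-9 & abs(p_lymphocyte - 1 / 3) < 1e-9]
  expect_equal(center$shannon, log(3), tolerance = 1e-12)
  vertex <- f[p_cancer == 1]
  expect_identical(vertex$shannon, 0)
  edge_mid <- f[p_cancer == 0.5 & p_lymphocyte == 0.5]
  expect_equal(edge_mid$shannon, log(2), tolerance = 1e-12)
  expect_error(shannon_simplex_field(1), ">= 2")
})
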