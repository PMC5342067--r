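make_survival_cohort <- function(n, hr, seed, censor = 0.25) {
  set.seed(seed)
  grp <- factor(rep(c("low", "high"), length.out = n), levels = c("low", "high"))
  rate <- ifelse(grp == "high", hr, 1) * log(2) / 43
  death <- rexp(n, rate)
  cens <- ifelse(runif(n) < censor, runif(n, 0, 120), 120)
  list(times = pmin(death, cens), events = as.integer(death <= cens),
       groups = grp)
}

test_that("resampling at fraction 1 reproduces the full-cohort test exactly", {
  co <- make_survival_cohort(80, hr = 2.5, seed = 21)
  sc <- resampling_stability(co$times, co$events, co$groups,
                             fractions = 1.0, n_reps = 25, seed = 3)
  full_p <- logrank_test(co$times, co$events, co$groups)$p
  expect_true(sc$curve$pct_significant %in% c(0, 100))
  expect_equal(sc$curve$pct_significant, if (full_p < 0.05) 100 else 0)
})

test_that("resampling stability is seed-deterministic and reports its seed", {
  co <- make_survival_cohort(60, hr = 2, seed = 22)
  a <- resampling_stability(co$times, co$events, co$groups,
                            fractions = c(0.7, 0.9), n_reps = 50, seed = 7)
  b <- resampling_stability(co$times, co$events, co$groups,
                            fractions = c(0.7, 0.9), n_reps = 50, seed = 7)
  expect_identical(a$curve, b$curve)
  expect_equal(a$seed, 7)
  c2 <- resampling_stability(co$times, co$events, co$groups,
                             fractions = c(0.7, 0.9), n_reps = 50, seed = 8)
  expect_false(identical(a$curve$pct_significant, c2$curve$pct_significant))
})

test_that("a strong marker stays significant under patient resampling", {
  co <- make_survival_cohort(150, hr = 6, seed = 23)
  sc <- resampling_stability(co$times, co$events, co$groups,
                             fractions = c(0.7, 0.85, 1.0), n_reps = 100,
                             seed = 5)
  expect_true(all(sc$curve$pct_significant >= 95))
})

test_that("multivariate resampling monitors the requested covariate's Wald p", {
  co <- make_survival_cohort(150, hr = 4, seed = 24)
  covs <- data.frame(group = co$groups, noise = rnorm(150))
  sc <- resampling_stability(co$times, co$events, covariates = covs,
                             covariate = "group", fractions = c(0.8, 1.0),
                             n_reps = 40, seed = 6)
  expect_equal(sc$analysis, "multivariate")
  expect_true(all(sc$curve$pct_significant >= 90))
  full <- cox_fit(co$times, co$events, covs)
  expect_equal(sc$curve[fraction == 1.0, pct_significant],
               if (full$table$p[grep("group", full$table$covariate)] < 0.05) 100 else 0)
})

test_that("group labels can be re-derived per draw when requested", {
  co <- make_survival_cohort(100, hr = 3, seed = 25)
  scores <- as.numeric(co$groups == "high") + rnorm(100, 0, 0.1)
  sc <- resampling_stability(co$times, co$events, rederive = TRUE,
                             scores = scores, fractions = 0.8, n_reps = 40,
                             seed = 9)
  expect_true(sc$curve$pct_significant > 50)
})

test_that("cell subsampling SD is zero at full fraction and grows as cells shrink", {
  cells <- make_section(20000, c(0.6, 0.2, 0.2), seed = 26)
  rep_tab <- cell_subsampling_stability(cells, fractions = c(1, 0.75, 0.5),
                                        n_reps = 120, seed = 4)
  expect_identical(rep_tab[fraction == 1, shannon_sd], 0)
  expect_gt(rep_tab[fraction == 0.5, shannon_sd],
            rep_tab[fraction == 0.75, shannon_sd])

  # delta-method magnitude check at moderate N
  p_true <- c(0.6, 0.2, 0.2)
  approx_sd <- oracle_subsample_sd(p_true, 20000, 0.5)
  obs <- rep_tab[fraction == 0.5, shannon_sd]
  expect_gt(obs, approx_sd / 2)
  expect_lt(obs, approx_sd * 2)

  expect_error(cell_subsampling_stability(cells, fractions = 1e-6), "no cells")
  expect_error(cell_subsampling_stability(cells[1:5]), ">= 10")
})

test_that("half-tissue splits reproduce constructed segregation exactly", {
  # all cancer on the left half, all stromal on the right
  seg <- data.table::data.table(
    patient_id = "P1", section_id = "S1", site = "omentum",
    x = c(runif(500, 0, 900), runif(500, 1100, 2000)),
    y = runif(1000, 0, 2000),
    cell_class = rep(c("cancer", "stromal"), each = 500)
  )
  sp <- half_split_stability(seg, "vertical")
  expect_equal(sp$h_whole, log(2), tolerance = 1e-12)
  expect_identical(sp$h_half1, 0)
  expect_identical(sp$h_half2, 0)
  expect_equal(unname(sp$abs_diff), rep(log(2), 2), tolerance = 1e-12)

  # single-class section: both halves trivially match the whole
  mono <- make_section(400, c(1, 0, 0), seed = 27)
  for (orient in c("horizontal", "vertical")) {
    sm <- half_split_stability(mono, orient)
    expect_identical(unname(sm$abs_diff), c(0, 0))
  }

  # degenerate geometry: all cells at one coordinate
  flat <- make_section(50, c(0.5, 0.5, 0), seed = 28)
  flat$y <- 100
  expect_true(half_split_stability(flat, "horizontal")$degenerate)
  expect_false(half_split_stability(flat, "vertical")$degenerate)
})

test_that("spatially homogeneous sections give near-identical half scores", {
  cells <- make_section(20000, c(0.6, 0.2, 0.2), seed = 29)
  for (orient in c("horizontal", "vertical")) {
    sp <- half_split_stability(cells, orient)
    expect_lt(max(sp$abs_diff), 0.02)
    expect_false(sp$degenerate)
  }
})
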