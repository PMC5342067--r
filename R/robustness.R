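#' Patient-fraction resampling stability of a survival marker
#'
#' Redraws `floor(f * n)` patients without replacement `n_reps` times per
#' fraction, reruns the survival test, and records the percentage of
#' resamples in which the marker stays significant at level `alpha`. Group
#' labels are taken as fixed from the full cohort (marker-stability reading);
#' set `rederive = TRUE` to re-derive the dichotomization by median split of
#' `scores` inside every draw.
#'
#' Univariate mode (default) uses the two-group log-rank p; if `covariates`
#' is supplied, the Cox Wald p of `covariate` from the multivariate fit is
#' used instead.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param groups Fixed full-cohort group labels (factor with levels
#'   low/high, or any 2-level labels).
#' @param covariates Optional data.frame of covariates for a multivariate
#'   Cox model (must contain `covariate`).
#' @param covariate Column of `covariates` whose Wald p is monitored.
#' @param fractions Cohort fractions to draw (default 0.70 to 1.00 by 0.05).
#' @param n_reps Resamples per fraction.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param rederive Re-derive groups per draw by median split of `scores`.
#' @param scores Continuous scores (required when `rederive = TRUE`).
#' @param endpoint Label recorded in the result.
#' @return Object of class `stability_curve`: data.table `curve` with
#'   `fraction`, `n_sub`, `pct_significant`, `n_failed`; plus `n_reps`,
#'   `alpha`, `seed`, `analysis`, `endpoint`.
#' @export
resampling_stability <- function(times, events, groups = NULL,
                                 covariates = NULL, covariate = NULL,
                                 fractions = seq(0.70, 1.00, by = 0.05),
                                 n_reps = 1000, alpha = 0.05, seed = 1L,
                                 rederive = FALSE, scores = NULL,
                                 endpoint = "OS") {
  n <- length(times)
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (any(fractions <= 0 | fractions > 1)) stopf("fractions must be in (0, 1]")
  multivariate <- !is.null(covariates)
  if (multivariate) {
    covariates <- as.data.frame(covariates)
    if (is.null(covariate) || !covariate %in% names(covariates)) {
      stopf("covariate must name a column of covariates")
    }
  } else if (!rederive && is.null(groups)) {
    stopf("supply groups (or covariates, or rederive + scores)")
  }
  if (rederive && is.null(scores)) stopf("rederive = TRUE requires scores")

  one_p <- function(idx) {
    g <- if (rederive) {
      ms <- median_split(scores[idx])
      as.character(ms$labels)
    } else if (!multivariate) as.character(groups[idx]) else NULL
    if (multivariate) {
      cv <- covariates[idx, , drop = FALSE]
      if (is.factor(cv[[covariate]]) &&
          nlevels(droplevels(cv[[covariate]])) < 2) return(NA_real_)
      fit <- tryCatch(
        suppressWarnings(cox_fit(times[idx], events[idx], cv)),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      row <- grep(covariate, fit$table$covariate, fixed = TRUE)
      if (length(row) == 0) return(NA_real_)
      fit$table$p[row[1]]
    } else {
      if (length(unique(g)) < 2) return(NA_real_)
      logrank_test(times[idx], events[idx], g)$p
    }
  }

  set.seed(seed)
  curve <- rbindlist(lapply(fractions, function(f) {
    m <- floor(f * n)
    if (m < 2) stopf("fraction %.2f leaves fewer than 2 patients", f)
    ps <- vapply(seq_len(n_reps), function(r) {
      one_p(sample.int(n, m))
    }, numeric(1))
    failed <- sum(is.na(ps))
    if (failed > n_reps / 2) {
      warnf("fraction %.2f: %d/%d resamples degenerate; percentage unreliable",
            f, failed, n_reps)
    }
    data.table(fraction = f, n_sub = m,
               pct_significant = 100 * mean(ps < alpha, na.rm = TRUE),
               n_failed = failed)
  }))
  structure(list(curve = curve[], n_reps = n_reps, alpha = alpha, seed = seed,
                 analysis = if (multivariate) "multivariate" else "univariate",
                 endpoint = endpoint),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %s %s, %d reps, alpha=%g, seed=%d\n",
              x$analysis, x$endpoint, x$n_reps, x$alpha, x$seed))
  print(x$curve)
  invisible(x)
}

#' Cell-subsampling stability of the Shannon score
#'
#' Per fraction, draws that share of a section's cells without replacement
#' `n_reps` times, recomputes Shannon diversity, and reports the standard
#' deviation over replicates (0 at fraction 1 by construction).
#'
#' @param cells Cell table of a single section (or a `cell_class` vector).
#' @param fractions Fractions of cells to keep (default 1, 0.75, 0.5).
#' @param n_reps Replicates per fraction.
#' @param seed Integer seed.
#' @return `data.table`: `fraction`, `n_cells_sub`, `shannon_sd`,
#'   `shannon_mean`, `n_reps`; attribute `shannon_full`.
#' @export
cell_subsampling_stability <- function(cells, fractions = c(1, 0.75, 0.5),
                                       n_reps = 100, seed = 1L) {
  cl <- if (is.data.frame(cells)) cells$cell_class else cells
  n <- length(cl)
  if (n < 10) stopf("need >= 10 cells")
  if (any(floor(fractions * n) < 1)) stopf("fraction leaves no cells")
  set.seed(seed)
  h_full <- shannon_index(cell_composition(cl), validate = FALSE)
  out <- rbindlist(lapply(fractions, function(f) {
    m <- floor(f * n)
    hs <- vapply(seq_len(n_reps), function(r) {
      sub <- if (m == n) cl else cl[sample.int(n, m)]
      shannon_index(cell_composition(sub), validate = FALSE)
    }, numeric(1))
    data.table(fraction = f, n_cells_sub = m, shannon_sd = sd(hs),
               shannon_mean = mean(hs), n_reps = n_reps)
  }))
  setattr(out, "shannon_full", h_full)
  out[]
}

#' Half-tissue split stability of the Shannon score
#'
#' Splits a section at the midpoint of its cell bounding box along the
#' chosen axis (a `"horizontal"` dividing line splits top/bottom on y; a
#' `"vertical"` line splits left/right on x), recomputes Shannon diversity
#' in each half, and reports the absolute differences from the whole-section
#' score.
#'
#' @param cells Cell table of one section with `x`, `y`, `cell_class`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return List: `orientation`, `split_at`, `h_whole`, `h_half1`, `h_half2`,
#'   `abs_diff` (length 2), `n_half` (cells per half), `degenerate`.
#' @export
half_split_stability <- function(cells, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  cells <- as.data.table(cells)
  if (nrow(cells) < 2) stopf("need >= 2 cells")
  coord <- if (orientation == "horizontal") cells$y else cells$x
  lo <- min(coord); hi <- max(coord)
  h_whole <- shannon_index(cell_composition(cells$cell_class), validate = FALSE)
  if (hi - lo <= 0) {
    return(list(orientation = orientation, split_at = lo, h_whole = h_whole,
                h_half1 = NA_real_, h_half2 = NA_real_,
                abs_diff = c(NA_real_, NA_real_), n_half = c(nrow(cells), 0L),
                degenerate = TRUE))
  }
  mid <- (lo + hi) / 2
  first <- coord <= mid
  halves <- list(cells$cell_class[first], cells$cell_class[!first])
  degenerate <- any(lengths(halves) == 0)
  h <- vapply(halves, function(cl) {
    if (length(cl) == 0) NA_real_
    else shannon_index(cell_composition(cl), validate = FALSE)
  }, numeric(1))
  list(orientation = orientation, split_at = mid, h_whole = h_whole,
       h_half1 = h[1], h_half2 = h[2], abs_diff = abs(h - h_whole),
       n_half = lengths(halves), degenerate = degenerate)
}
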