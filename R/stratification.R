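new_group_assignment <- function(variable, method, threshold, labels, ids,
                                 fallback = FALSE, note = NULL) {
  labels <- factor(labels, levels = c("low", "high"))
  structure(list(
    variable = variable, method = method, threshold = threshold,
    labels = setNames(labels, ids),
    sizes = c(low = sum(labels == "low"), high = sum(labels == "high")),
    fallback = fallback, note = note
  ), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %s by %s split at %.4g: low %d / high %d\n",
              x$variable, x$method, x$threshold, x$sizes["low"], x$sizes["high"]))
  if (isTRUE(x$fallback)) cat("  (fell back to median split)\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

check_scores <- function(scores, min_n) {
  if (anyNA(scores)) stopf("scores contain NA; drop undefined patients first")
  if (length(scores) < min_n) stopf("need >= %d defined scores", min_n)
  if (length(unique(scores)) == 1) stopf("all scores identical; split degenerate")
}

#' Median dichotomization
#'
#' Splits at the sample median; ties at the threshold go to the high group
#' (`high` means `score >= threshold`, matching the `>=` convention of the
#' ratio-based groupings).
#'
#' @param scores Numeric scores, optionally named by patient.
#' @param variable Variable name recorded in the result.
#' @return A `group_assignment`.
#' @export
median_split <- function(scores, variable = "score") {
  check_scores(scores, 4)
  thr <- median(scores)
  new_group_assignment(variable, "median", thr,
                       ifelse(scores >= thr, "high", "low"),
                       names(scores) %||% seq_along(scores))
}

#' Lower-tertile dichotomization
#'
#' Low group = scores below the 33rd percentile (linear-interpolation
#' percentile, `quantile` type 7); high = the upper two thirds.
#'
#' @inheritParams median_split
#' @export
tertile_split <- function(scores, variable = "score") {
  check_scores(scores, 6)
  thr <- quantile(scores, 1 / 3, names = FALSE, type = 7)
  new_group_assignment(variable, "tertile_33_67", thr,
                       ifelse(scores >= thr, "high", "low"),
                       names(scores) %||% seq_along(scores))
}

#' Iterative (optimal-cutpoint) dichotomization against survival
#'
#' Scans every candidate cutpoint (midpoints between consecutive sorted
#' unique scores) whose induced groups both contain at least
#' `min_group_frac * n` patients, and returns the cutpoint minimizing the
#' two-group log-rank p-value. If no candidate satisfies the size
#' constraint, falls back to [median_split()] and flags the fallback. The
#' selected p-value is a minimum over scans and therefore optimistic; the
#' result carries a note saying so and no multiplicity correction is
#' applied.
#'
#' @inheritParams median_split
#' @param times,events Survival times and 0/1 event indicators, aligned with
#'   `scores`.
#' @param min_group_frac Minimum group size as a fraction of n (default 0.1).
#' @return A `group_assignment` with extra fields `logrank_p` (at the chosen
#'   cutpoint) and `scan` (data.table of candidate thresholds and p-values).
#' @export
iterative_threshold <- function(scores, times, events, min_group_frac = 0.1,
                                variable = "score") {
  if (length(scores) < 10) stopf("need >= 10 patients for cutpoint scanning")
  if (length(times) != length(scores) || length(events) != length(scores)) {
    stopf("scores, times and events must be aligned")
  }
  check_scores(scores, 10)
  u <- sort(unique(scores))
  cand <- (head(u, -1) + u[-1]) / 2
  n <- length(scores)
  min_size <- min_group_frac * n
  ok <- vapply(cand, function(thr) {
    k <- sum(scores >= thr)
    k >= min_size && (n - k) >= min_size
  }, logical(1))
  if (!any(ok)) {
    ga <- median_split(scores, variable)
    ga$fallback <- TRUE
    ga$note <- "no admissible cutpoint; median split used"
    return(ga)
  }
  cand <- cand[ok]
  pvals <- vapply(cand, function(thr) {
    logrank_test(times, events, ifelse(scores >= thr, "high", "low"))$p
  }, numeric(1))
  best <- which.min(pvals)
  ga <- new_group_assignment(
    variable, "iterative", cand[best],
    ifelse(scores >= cand[best], "high", "low"),
    names(scores) %||% seq_along(scores),
    note = "p-value minimized over cutpoint scan; optimistic without correction"
  )
  ga$logrank_p <- pvals[best]
  ga$scan <- data.table(threshold = cand, logrank_p = pvals)
  ga
}

#' Kruskal-Wallis association test
#'
#' Rank-based test of association between a continuous variable and a
#' categorical grouping (tie-corrected H statistic, chi-square p). Every
#' group must contain at least 2 values.
#'
#' @param values Numeric values.
#' @param groups Group labels aligned with `values`.
#' @return List: `test`, `statistic`, `df`, `p`, `group_n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need >= 2 groups")
  tab <- table(droplevels(groups))
  if (any(tab < 2)) {
    stopf("group(s) with < 2 values: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  }
  kt <- kruskal.test(values, groups)
  list(test = "kruskal_wallis", statistic = unname(kt$statistic),
       df = unname(kt$parameter), p = kt$p.value, group_n = as.vector(tab))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' the observed table's.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List: `test`, `p`, `odds_ratio`, `table`.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stopf("counts must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("both margins must be positive")
  }
  ft <- fisher.test(counts, alternative = "two.sided")
  list(test = "fisher_exact", p = ft$p.value,
       odds_ratio = unname(ft$estimate), table = counts)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' The bias-adjusted third standardized moment
#' `G1 = g1 * sqrt(n(n-1))/(n-2)`.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @return Skewness value.
#' @export
skewness_adj <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stopf("need >= 3 values")
  if (sd(x) == 0) stopf("constant input; skewness undefined")
  unname(e1071::skewness(x, type = 2))
}
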