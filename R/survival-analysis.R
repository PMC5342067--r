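#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return Object of class `km_estimate`: `time` (event-time grid), `surv`
#'   (step-function values), `n_risk`, `n_event`, `n_censor`, plus the
#'   underlying `survival::survfit` in `$fit`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stopf("empty input")
  if (any(times <= 0)) stopf("times must be positive")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor, fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %d subjects, %d events, median %.3g\n",
              x$n_risk[1], sum(x$n_event),
              unname(summary(x$fit)$table["median"])))
  invisible(x)
}

#' Survival probability at a landmark time
#'
#' Reads `S(t)` off the Kaplan-Meier step function. Beyond the last observed
#' time with no subjects left at risk the estimate is undefined and `NA` is
#' returned with attribute `defined = FALSE`.
#'
#' @param km A [km_estimate()].
#' @param t_months Landmark time (same units as the fit).
#' @return Survival probability (numeric scalar, possibly `NA`).
#' @export
landmark_survival <- function(km, t_months) {
  if (t_months < 0) stopf("t must be >= 0")
  if (t_months > max(km$time)) {
    last_surv <- km$surv[length(km$surv)]
    if (last_surv > 0) {
      # follow-up ended (by censoring) before t with survivors remaining:
      # the product-limit estimate at t is undefined
      out <- NA_real_
      attr(out, "defined") <- FALSE
      return(out)
    }
    out <- 0
    attr(out, "defined") <- TRUE
    return(out)
  }
  idx <- which(km$time <= t_months)
  out <- if (length(idx) == 0) 1 else km$surv[max(idx)]
  attr(out, "defined") <- TRUE
  out
}

#' Log-rank test
#'
#' Chi-square log-rank comparison of k survival curves (k-1 degrees of
#' freedom).
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param groups Group labels aligned with `times`.
#' @return List: `statistic`, `df`, `p`, `n` per group.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stopf("need >= 2 non-empty groups")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_fit$n) - 1
  list(statistic = unname(sd_fit$chisq), df = df,
       p = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       n = as.vector(sd_fit$n))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) with per-covariate hazard
#' ratios, Wald 95% confidence intervals and p-values, and Harrell's
#' concordance. Factor/character covariates are modelled with their first
#' level as reference; pass dichotomized groupings as factors with levels
#' `c("low", "high")` to get the high-vs-low hazard ratio.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param covariates data.frame of covariates (one column per model term).
#' @param endpoint Label stored in the result (e.g. `"OS"`, `"PFS"`).
#' @return Object of class `survival_fit`: `table` (data.table with
#'   `covariate`, `hr`, `ci_low`, `ci_high`, `p`), `concordance`, `n`,
#'   `n_events`, `endpoint`, and the `coxph` object in `$fit`.
#' @export
cox_fit <- function(times, events, covariates, endpoint = "OS") {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1) stopf("need >= 1 covariate")
  if (nrow(covariates) != length(times)) stopf("covariates misaligned with times")
  if (length(times) < 2) stopf("need >= 2 subjects")
  n_events <- sum(events)
  if (n_events < 5 * ncol(covariates)) {
    warnf("only %d events for %d covariate(s); estimates may be unstable",
          n_events, ncol(covariates))
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    error = function(e) stopf("Cox fit failed: %s", conditionMessage(e))
  )
  if (!is.null(fit$info) || any(!is.finite(coef(fit)))) {
    stopf("Cox fit did not converge to finite estimates")
  }
  if (any(sqrt(diag(fit$var)) > 50)) {
    warnf("very large coefficient standard error; possible complete separation")
  }
  s <- summary(fit)
  tab <- data.table(
    covariate = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    ci_low = s$conf.int[, "lower .95"],
    ci_high = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"]
  )
  structure(list(table = tab,
                 concordance = unname(s$concordance["C"]),
                 n = s$n, n_events = n_events, endpoint = endpoint,
                 fit = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s: n=%d, events=%d, concordance=%.3f\n",
              x$endpoint, x$n, x$n_events, x$concordance))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-28s HR %.3g (%.3g-%.3g) p=%.3g\n",
                x$table$covariate[i], x$table$hr[i], x$table$ci_low[i],
                x$table$ci_high[i], x$table$p[i]))
  }
  invisible(x)
}

#' Univariate-eligibility rule for multivariate Cox models
#'
#' Returns, in input order, the covariates whose univariate p-value is
#' strictly below the significance level (default 0.05).
#'
#' @param p_values Named numeric vector of univariate p-values.
#' @param alpha Eligibility level.
#' @return Character vector of covariate names (possibly empty).
#' @export
select_multivariate_factors <- function(p_values, alpha = 0.05) {
  if (length(p_values) < 1) stopf("need >= 1 univariate result")
  names(p_values)[p_values < alpha]
}

#' Harrell's concordance index for a risk score
#'
#' Probability, over usable pairs, that the subject with the higher risk
#' score has the shorter survival. 0.5 is chance; 1 a perfect risk ranking.
#'
#' @param score Risk score (higher = worse expected outcome).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(score, times, events) {
  if (sum(events) == 0) stopf("no events: no comparable pairs")
  cc <- survival::concordance(survival::Surv(times, events) ~ score,
                              reverse = TRUE)
  unname(cc$concordance)
}
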