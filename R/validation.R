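#' Per-class classifier agreement metrics
#'
#' One-vs-rest sensitivity and specificity of automated labels against
#' expert labels, plus the balanced average (arithmetic mean of the two),
#' per cell class, optionally stratified by anatomical site.
#'
#' @param pairs Annotation pairs: data.frame with `expert_class`,
#'   `predicted_class`, and `site` (needed when `by_site = TRUE`).
#' @param by_site Also compute metrics within each site.
#' @return `data.table`: `site` (`"all"` for pooled), `cell_class`,
#'   `sensitivity`, `specificity`, `balanced_average`, `n_expert` (expert
#'   support), `n`. Classes absent from the expert labels get `NA`
#'   sensitivity.
#' @export
confusion_metrics <- function(pairs, by_site = FALSE) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) < 1) stopf("need >= 1 annotation pair")
  one_block <- function(dt, site_label) {
    rbindlist(lapply(CELL_CLASSES, function(cl) {
      tp <- sum(dt$expert_class == cl & dt$predicted_class == cl)
      fn <- sum(dt$expert_class == cl & dt$predicted_class != cl)
      fp <- sum(dt$expert_class != cl & dt$predicted_class == cl)
      tn <- sum(dt$expert_class != cl & dt$predicted_class != cl)
      sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      data.table(site = site_label, cell_class = cl, sensitivity = sens,
                 specificity = spec, balanced_average = (sens + spec) / 2,
                 n_expert = tp + fn, n = nrow(dt))
    }))
  }
  out <- one_block(pairs, "all")
  if (by_site) {
    per_site <- rbindlist(lapply(split(pairs, pairs$site), function(dt) {
      one_block(dt, dt$site[1])
    }))
    out <- rbindlist(list(out, per_site))
  }
  out[]
}

#' Field-of-view proportion agreement
#'
#' Correlation, per cell class, between automated and expert cell-ratio
#' scores over fields of view, with a two-sided p-value. Pearson is the
#' default; Spearman is available as an explicit alternative.
#'
#' @param scores Long-format data.frame with columns `fov_id`, `cell_class`,
#'   `automated`, `expert` (one row per field of view and class).
#' @param method `"pearson"` or `"spearman"`.
#' @return `data.table`: `cell_class`, `r`, `p`, `method`, `n`. Zero
#'   variance in either vector yields `NA` with a warning.
#' @export
proportion_agreement <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- as.data.table(scores)
  need <- c("fov_id", "cell_class", "automated", "expert")
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) stopf("missing column(s): %s", paste(missing, collapse = ", "))
  out <- scores[, {
    if (.N < 3) stopf("cell class '%s': need >= 3 fields of view", cell_class[1])
    if (sd(automated) == 0 || sd(expert) == 0) {
      warnf("cell class '%s': zero variance; correlation undefined", cell_class[1])
      list(r = NA_real_, p = NA_real_, method = method, n = .N)
    } else {
      ct <- suppressWarnings(cor.test(automated, expert, method = method,
                                      exact = FALSE))
      list(r = unname(ct$estimate), p = ct$p.value, method = method, n = .N)
    }
  }, by = cell_class]
  out[]
}

#' Simulate expert-vs-automated annotation pairs (synthetic)
#'
#' Generates a synthetic single-cell annotation set: expert labels with
#' given per-class counts, and automated labels drawn from a row-stochastic
#' confusion matrix (rows = expert class, columns = predicted class). The
#' default counts follow the reference validation set (2,668 cancer, 1,120
#' lymphocyte, 845 stromal annotations over six non-ovary sites) and the
#' default confusion rates represent a good but imperfect classifier.
#'
#' @param n_per_class Named integer vector of expert annotations per class.
#' @param confusion 3x3 row-stochastic matrix in `cell_classes()` order.
#' @param sites Site labels to distribute annotations over.
#' @param seed Integer seed.
#' @return `data.table` with `cell_id`, `site`, `expert_class`,
#'   `predicted_class`.
#' @export
simulate_annotations <- function(n_per_class = c(cancer = 2668,
                                                 lymphocyte = 1120,
                                                 stromal = 845),
                                 confusion = default_confusion(),
                                 sites = MET_SITES,
                                 seed = 1L) {
  if (any(n_per_class < 1)) stopf("n_per_class must be positive")
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3, 3)) ||
      any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0)) {
    stopf("confusion must be a 3x3 row-stochastic matrix")
  }
  set.seed(seed)
  expert <- rep(CELL_CLASSES, times = n_per_class[CELL_CLASSES])
  n <- length(expert)
  predicted <- vapply(expert, function(cl) {
    sample(CELL_CLASSES, 1, prob = confusion[match(cl, CELL_CLASSES), ])
  }, character(1))
  data.table(
    cell_id = sprintf("cell_%05d", seq_len(n)),
    site = sample(sites, n, replace = TRUE),
    expert_class = expert,
    predicted_class = unname(predicted)
  )
}

# Default synthetic confusion rates: strong diagonal with the main error
# modes of H&E nucleus classification (cancer <-> stromal shape overlap,
# lymphocyte <-> stromal small-nucleus overlap).
default_confusion <- function() {
  m <- matrix(c(
    0.90, 0.03, 0.07,
    0.05, 0.85, 0.10,
    0.06, 0.06, 0.88
  ), nrow = 3, byrow = TRUE, dimnames = list(CELL_CLASSES, CELL_CLASSES))
  m
}
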