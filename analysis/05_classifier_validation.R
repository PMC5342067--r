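#!/usr/bin/env Rscript
# Classifier-agreement metrics on the synthetic annotation set: per-class
# sensitivity/specificity/balanced average (pooled and per site) and
# field-of-view proportion correlations.

suppressPackageStartupMessages({
  library(metdiv)
  library(data.table)
})

ann <- simulate_annotations(seed = 81)
cat(sprintf("synthetic annotation set: %d cells (%s)\n", nrow(ann),
            paste(sprintf("%s %d", names(table(ann$expert_class)),
                          table(ann$expert_class)), collapse = ", ")))

cm <- confusion_metrics(ann, by_site = TRUE)
write_table(cm, "results/validation_metrics.tsv")
cat("\npooled per-class metrics:\n")
print(cm[site == "all"])

# field-of-view agreement: 24 synthetic fields, automated = expert + noise
set.seed(82)
fovs <- rbindlist(lapply(cell_classes(), function(cl) {
  expert <- pmin(pmax(rnorm(24, c(cancer = 0.65, lymphocyte = 0.12,
                                  stromal = 0.23)[cl], 0.12), 0.01), 0.99)
  data.table(fov_id = 1:24, cell_class = cl, expert = expert,
             automated = pmin(pmax(expert + rnorm(24, 0, 0.06), 0), 1))
}))
pa_p <- proportion_agreement(fovs, "pearson")
pa_s <- proportion_agreement(fovs, "spearman")
write_table(rbind(pa_p, pa_s), "results/proportion_agreement.tsv")
cat("\nproportion agreement per class (both methods):\n")
print(rbind(pa_p, pa_s))
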