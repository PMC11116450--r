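#!/usr/bin/env Rscript
# Stage 4 — the 21 classification tasks.
#
# For every retained descriptor, trains nested leave-one-out linear
# SVMs on three input sets (remaining clinical descriptors after the
# |r| > 0.7 prune; the 11 synovial fluid analytes; the 8 simulated TF
# activations) and writes the normalized importance matrices, the
# pooled held-out ROC-AUCs and the fit-count manifest.

suppressMessages(library(oastratify))
cohort <- read_cohort("results/cohort.csv")
tf <- read_cohort("results/tf_activations.csv")
thresholds <- read_thresholds("results/thresholds.yaml")
cfg <- svm_config(C_grid = c(0.01, 1, 100), seed = 1)

retained <- names(thresholds)[sapply(thresholds, `[[`, "retained")]
reports <- list()
for (target in retained) {
  for (set in c("clinical", "sf", "tf")) {
    r <- run_task(cohort, target, set, thresholds, cfg, tf_table = tf)
    reports[[r$task]] <- r
    cat(sprintf("%-14s AUC %.3f  (%d folds, %d subjects)\n",
                r$task, r$auc, length(r$folds), r$n_subjects))
  }
}

for (set in c("clinical", "sf", "tf")) {
  rs <- Filter(function(r) r$input_set == set, reports)
  importance_matrix(rs, path = sprintf("results/importance_%s.csv", set))
}
auc_tab <- data.frame(task = names(reports),
                      auc = sapply(reports, `[[`, "auc"),
                      folds = sapply(reports, function(r) length(r$folds)))
write.csv(auc_tab, "results/auc.csv", row.names = FALSE)

total <- sum(auc_tab$folds)
cat(sprintf("\n%d tasks, %d SVM fits in total\n", nrow(auc_tab), total))
cat(sprintf("mean AUC by input set: clinical %.3f, sf %.3f, tf %.3f\n",
            mean(auc_tab$auc[grep("/clinical", auc_tab$task)]),
            mean(auc_tab$auc[grep("/sf", auc_tab$task)]),
            mean(auc_tab$auc[grep("/tf", auc_tab$task)])))
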