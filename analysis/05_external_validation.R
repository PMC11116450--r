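#!/usr/bin/env Rscript
# Stage 5 — threshold transfer to the external registry table.
#
# Applies the cohort-derived mid-scale thresholds to the six WOMAC-style
# targets of the external table, then runs the validation protocol:
# surgery exclusions -> 80% completeness filter -> pairwise |r| > 0.7
# prune -> information-gain top-50 -> tuned linear SVM -> stratified
# 5-fold CV accuracy per target.

suppressMessages(library(oastratify))
external <- read_cohort("results/external.csv")

# transferred thresholds: the cohort descriptors and the registry's
# WOMAC columns share the standard scorings, so the mid-scale cuts
# carry over directly
transfer <- list(
  womac_pain_left = list(threshold = 10.5),
  womac_pain_right = list(threshold = 10.5),
  womac_func_left = list(threshold = 34.5),
  womac_func_right = list(threshold = 34.5),
  womac_rigidity_left = list(threshold = 4.5),
  womac_rigidity_right = list(threshold = 4.5))

cfg <- validation_config(svm_cfg = svm_config(C_grid = c(0.01, 0.1, 1),
                                              seed = 1))
report <- validate_external(external, transfer, cfg)
print(report)
cat(sprintf("subjects: %d -> %d after exclusions (%d flagged, %d incomplete)\n",
            report$counts["input"], report$counts["after_exclusions"],
            report$removal_counts["flagged"],
            report$removal_counts["incomplete"]))
cat(sprintf("features: %d -> %d after pairwise pruning\n",
            report$counts["features_input"],
            report$counts["features_after_prune"]))
write.csv(data.frame(target = names(report$accuracy),
                     accuracy = report$accuracy),
          "results/external_accuracy.csv", row.names = FALSE)
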