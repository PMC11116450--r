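#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# Generates the canonical synthetic cohort (51 subjects, 7 ordinal
# descriptors with planted mid-scale splits, 25-subject synovial fluid
# subset) and an OAI-like external registry table (4796 rows, 300
# correlated features, knee-surgery flags, 2% cell missingness), and
# writes both as CSV + sidecar YAML under results/.

suppressMessages(library(oastratify))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(synthetic_study_config(seed = 1))
write_cohort(cohort, "results/cohort.csv")
cat(sprintf("cohort: %d subjects, %d with synovial fluid\n",
            nrow(cohort$data),
            sum(complete.cases(cohort_features(cohort, "analyte")))))

external <- generate_external_table(n_rows = 4796, n_features = 300,
                                    missing_rate = 0.02, n_surgery = 360,
                                    effect_size = 14, seed = 2)
write_cohort(external, "results/external.csv")
cat(sprintf("external table: %d rows, %d feature columns, %d flagged\n",
            nrow(external$data), sum(external$kinds == "analyte"),
            sum(external$data$surgery_history)))
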