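# oastratify

Stratification of knee osteoarthritis (OA) patients from clinical
questionnaire descriptors, synovial fluid analyte panels, and simulated
transcription factor (TF) activities.

Knee OA is diagnosed largely from symptoms, but symptom scores track the
joint phenotype imperfectly, which motivates looking for molecular
correlates of the clinical presentation. This package implements that
analysis as a tested pipeline for researchers working with small,
deeply-phenotyped cohorts:

1. **Supervised binarization.** Each ordinal clinical descriptor
   (joint pain JP, functionality FU, rigidity RI, sensitization SE,
   depression DE, catastrophism CA, synovitis SY) is cut into a binary
   target by a grid search over midpoint thresholds maximizing Youden's
   index `J = sensitivity + specificity - 1` on pooled held-out SVM
   predictions, with a 0.75 mean-train-accuracy retention gate.
2. **Regulatory network simulation.** A signed interaction graph
   becomes an ODE system `dx_i/dt = s(omega_i; h) - gamma x_i` on
   [0, 1]^n with a normalized sigmoid `s` (s(0)=0, s(0.5)=0.5, s(1)=1)
   and a saturating, normalized drive `omega` aggregating activators
   and inhibitors. Per-patient synovial fluid analytes, min-max
   rescaled to [0, 1], are clamped onto the input nodes; steady-state
   activations of the 8 output TFs become classifier features.
3. **Nested leave-one-out linear SVM.** For each retained descriptor
   and each input set (clinical / synovial fluid / TF), an outer
   leave-one-out loop with inner 5-fold penalty tuning yields
   fold-averaged normalized feature importances (`|mean weight|`,
   min-max to [0, 1]) and a pooled held-out Mann-Whitney ROC-AUC.
4. **External threshold validation.** Cohort-derived thresholds are
   transferred to a wide registry-style table and evaluated through
   the protocol: surgery-history exclusions, 80% completeness filter,
   pairwise `|r| > 0.7` pruning, information-gain top-50, tuned SVM,
   stratified 5-fold CV accuracy per WOMAC-style target.

Because cohorts of this kind are access-restricted, a synthetic-data
module generates cohorts and registry tables with the structure the
analysis assumes (ordinal descriptors from latent Gaussian scores,
planted two-subgroup splits, log-normal analytes, correlated feature
blocks), so the whole pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the full study on the
canonical synthetic cohort (51 subjects, 25 with synovial fluid):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_binarize.R
Rscript analysis/03_network_simulation.R
Rscript analysis/04_classification_tasks.R
Rscript analysis/05_external_validation.R
```

Stage 2 prints the selected thresholds, e.g.

```
FU  threshold  45.5  J 0.96  train acc 1.00  retained
JP  threshold  13.0  J 0.76  train acc 0.91  retained
RI  threshold   6.5  J 0.84  train acc 0.94  retained
SE  threshold   1.5  J 0.76  train acc 0.90  retained
DE  threshold   9.5  J 0.86  train acc 0.96  retained
CA  threshold  26.0  J 0.92  train acc 0.96  retained
SY  threshold   1.5  J 0.56  train acc 0.82  retained
```

Every descriptor clears the 0.75 retention gate (the synthetic study
plants a two-subgroup split in each descriptor, and the remaining
descriptors carry enough signal to recover it; FU's threshold 45.5 sits
at its planted mid-scale boundary). Stage 4 then reports the 21
classification tasks — 7 targets x 3 input sets, 50 fitted models per
clinical task and 24 per synovial-fluid or TF task, 686 fits in total —
with their pooled held-out AUCs; clinical inputs recover their planted
associations (e.g. `FU/clinical AUC 0.984`), while the analyte- and
TF-input tasks are weaker, as only SY is driven by an analyte in this
design, and pooled LOO AUCs on near-null tasks fall below 0.5 by the
estimator's leave-one-out pessimism (see the methods vignette). Stage 5
transfers mid-scale thresholds to a 4796-row synthetic registry table
and prints per-target stratified 5-fold CV accuracies with the audit
counts:

```
<validation_report> stratified 5-fold CV accuracy; mean accuracy = 0.963
subjects: 4796 -> 4436 after exclusions (360 flagged, 0 incomplete)
features: 300 -> 300 after pairwise pruning
```

Programmatic equivalent:

```r
library(oastratify)
res <- run_all(cohort_cfg = synthetic_study_config(seed = 1),
               svm_cfg = svm_config(C_grid = c(0.01, 1, 100), seed = 1))
res$manifest$n_tasks     # 21
res$manifest$total_fits  # 686
res$importance$clinical  # targets x features importance matrix
```

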