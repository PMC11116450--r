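two_blobs <- function(n_per = 10, sep = 6, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}

test_that("tune_C breaks ties toward the smallest penalty", {
  d <- two_blobs(sep = 6)
  C <- tune_C(d$x, d$y, svm_config())
  expect_equal(as.numeric(C), 1e-3)           # every C separates: tie rule
  expect_true(all(attr(C, "cv_accuracy") == 1))

  C1 <- tune_C(d$x, d$y, svm_config(C_grid = 7))
  expect_equal(as.numeric(C1), 7)

  set.seed(5)
  x <- matrix(rnorm(60), 30, 2); y <- sample(0:1, 30, replace = TRUE)
  ca <- tune_C(x, y, svm_config(seed = 4))
  cb <- tune_C(x, y, svm_config(seed = 4))
  expect_identical(as.numeric(ca), as.numeric(cb))
  expect_error(tune_C(x, rep(1, 30), svm_config()),
               class = "oastratify_degenerate_error")
})

test_that("nested LOO produces the expected fold counts in both modes", {
  d51 <- two_blobs(n_per = 26, sep = 4, seed = 2)
  d51$x <- d51$x[1:51, , drop = FALSE]; d51$y <- d51$y[1:51]
  cfg <- svm_config(C_grid = 1, fold_mode = "n_minus_one")
  folds <- nested_loo(d51$x, d51$y, cfg)
  expect_length(folds, 50)

  d25 <- two_blobs(n_per = 13, sep = 4, seed = 3)
  d25$x <- d25$x[1:25, , drop = FALSE]; d25$y <- d25$y[1:25]
  expect_length(nested_loo(d25$x, d25$y, cfg), 24)

  cfg_std <- svm_config(C_grid = 1, fold_mode = "standard")
  expect_length(nested_loo(d25$x, d25$y, cfg_std), 25)
})

test_that("held-out decisions are correctly signed on a separable toy", {
  d <- two_blobs(n_per = 5, sep = 8, seed = 6)
  folds <- nested_loo(d$x, d$y, svm_config(C_grid = c(0.1, 1),
                                           fold_mode = "standard"))
  pred <- sapply(folds, function(f) as.integer(f$decision > 0))
  truth <- sapply(folds, `[[`, "truth")
  expect_equal(pred, truth)
  expect_true(all(sapply(folds, `[[`, "train_accuracy") == 1))
})

test_that("importance follows the absolute-mean-weight min-max convention", {
  f1 <- fake_folds(c(1, -1), c(1, 0),
                   weights = rbind(c(a = 2, b = -2), c(a = 2, b = -2)))
  imp <- importance(f1)
  expect_equal(unname(imp), c(1, 1), ignore_attr = TRUE)  # equal |mean|: max-normalization

  f2 <- fake_folds(0, 1, weights = rbind(c(a = 0, b = 0)))
  imp2 <- importance(f2)
  expect_equal(unname(imp2), c(0, 0), ignore_attr = TRUE)
  expect_true(attr(imp2, "degenerate"))

  f3 <- fake_folds(c(0, 0), c(1, 0),
                   weights = rbind(c(a = 4, b = -1, c = 2),
                                   c(a = 4, b = 1, c = 2)))
  imp3 <- importance(f3)
  expect_equal(unname(imp3), c(1, 0, 0.5), ignore_attr = TRUE)
  expect_equal(unname(attr(imp3, "mean_weight")), c(4, 0, 2))
})

test_that("pooled AUC equals brute-force pair counting", {
  expect_equal(pooled_auc(fake_folds(1:4, c(0, 0, 1, 1))), 1.0)
  expect_equal(pooled_auc(fake_folds(4:1, c(0, 0, 1, 1))), 0.0)
  expect_equal(pooled_auc(fake_folds(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))),
               0.75)
  expect_error(pooled_auc(fake_folds(1:3, c(1, 1, 1))),
               class = "oastratify_degenerate_error")

  set.seed(7)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    d <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # forces ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(pooled_auc(fake_folds(d, y)), oracle_auc(d, y))
  }
})

test_that("pooled AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  d <- rnorm(40); y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(pooled_auc(fake_folds(d, y)),
               as.numeric(pROC::auc(pROC::roc(y, d, quiet = TRUE,
                                              direction = "<"))))
})

test_that("run_task guards against target leakage and reports per input set", {
  cfg <- cohort_config(
    n_subjects = 26, n_sf_subset = 26,
    descriptor_specs = list(FU = 1:5, JP = 1:4, RI = 1:3),
    analyte_names = c("IL6", "leptin"),
    planted_effects = list(list(feature = "FU", descriptor = "JP", effect = 2.5),
                           list(feature = "leptin", descriptor = "RI",
                                effect = 2.5)),
    seed = 31)
  ct <- generate_cohort(cfg)
  thr <- list(JP = list(threshold = 2.5), RI = list(threshold = 1.5))
  scfg <- fast_svm_cfg(seed = 5)

  rc <- run_task(ct, "JP", "clinical", thr, scfg)
  expect_false("JP" %in% rc$features_used)
  expect_false("JP" %in% rc$features_omitted)  # reported omissions exclude target
  expect_length(rc$folds, 25)

  rs <- run_task(ct, "RI", "sf", thr, scfg)
  expect_setequal(rs$features_used, c("IL6", "leptin"))
  expect_gt(rs$auc, 0.7)                       # planted leptin -> RI signal
  expect_equal(names(which.max(rs$importance)), "leptin")
})

test_that("the importance matrix marks omitted features and keeps rows in [0,1]", {
  r1 <- structure(list(task = "A/clinical", target = "A",
                       input_set = "clinical",
                       importance = c(x = 1, y = 0.2),
                       features_used = c("x", "y")),
                  class = "classifier_report")
  r2 <- structure(list(task = "B/clinical", target = "B",
                       input_set = "clinical",
                       importance = c(y = 0, z = 1),
                       features_used = c("y", "z")),
                  class = "classifier_report")
  M <- importance_matrix(list(r1, r2))
  expect_equal(dim(M), c(2, 3))
  expect_true(is.na(M["A", "z"]) && is.na(M["B", "x"]))
  expect_equal(unname(apply(M, 1, max, na.rm = TRUE)), c(1, 1))
  r3 <- structure(list(task = "C/sf", target = "C", input_set = "sf",
                       importance = c(x = 1), features_used = "x"),
                  class = "classifier_report")
  expect_error(importance_matrix(list(r1, r3)),
               class = "oastratify_config_error")
})

test_that("duplicating a feature does not inflate AUC on a separable toy", {
  d <- two_blobs(n_per = 8, sep = 6, seed = 10, p = 1)
  cfg <- svm_config(C_grid = 1, fold_mode = "standard")
  auc1 <- pooled_auc(nested_loo(d$x, d$y, cfg))
  xdup <- cbind(d$x, f2 = d$x[, 1])
  auc2 <- pooled_auc(nested_loo(xdup, d$y, cfg))
  expect_lte(auc2, auc1 + 1e-12)
})
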