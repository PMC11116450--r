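# End-to-end driver: cohort simulation -> binarization -> network
# simulation -> the 7 x 3 classification tasks -> optional external
# validation, with a manifest recording seeds, counts and fit totals.

#' Run the full stratification pipeline
#'
#' Stages: (1) generate (or accept) a cohort; (2) select binarization
#' thresholds per descriptor; (3) rescale analytes and simulate the
#' regulatory network per patient; (4) run the classification tasks
#' (each retained descriptor times the clinical / synovial fluid / TF
#' input sets); (5) optionally validate thresholds on an external
#' table. The manifest records the seed, per-stage counts and the
#' per-task and total SVM fit counts.
#'
#' @param cohort_cfg a \code{\link{cohort_config}}, or an existing
#'   \code{\link{cohort_table}}.
#' @param svm_cfg an \code{\link{svm_config}}.
#' @param network a \code{\link{network_spec}} (default: the bundled
#'   example network). \code{NULL} disables the TF stage and its tasks.
#' @param analyte_map named analyte -> input node mapping (default: the
#'   bundled example mapping).
#' @param external_table optional external \code{\link{cohort_table}}
#'   for threshold validation.
#' @param validation_cfg a \code{\link{validation_config}}.
#' @param retain_gate train-accuracy retention gate (default 0.75).
#' @param binarization_features which feature block feeds the Youden
#'   search (\code{"clinical"}: the remaining descriptors; default).
#' @return list with \code{cohort}, \code{thresholds},
#'   \code{tf_table}, \code{reports} (named by task),
#'   \code{importance} (one matrix per input set), \code{validation}
#'   (or NULL) and \code{manifest}.
#' @export
run_all <- function(cohort_cfg = cohort_config(),
                    svm_cfg = svm_config(),
                    network = parse_network(example_network_path("sif"),
                                            example_network_path("roles")),
                    analyte_map = yaml::read_yaml(example_network_path("map")),
                    external_table = NULL,
                    validation_cfg = validation_config(svm_cfg = svm_cfg),
                    retain_gate = 0.75,
                    binarization_features = "clinical") {
  ct <- if (inherits(cohort_cfg, "cohort_table")) cohort_cfg
        else generate_cohort(cohort_cfg)

  thresholds <- binarize_cohort(ct, svm_cfg)
  retained <- names(thresholds)[vapply(thresholds, function(r)
    r$mean_train_accuracy >= retain_gate, logical(1))]

  tf_table <- NULL
  input_sets <- c("clinical", "sf")
  if (!is.null(network)) {
    analytes <- cohort_features(ct, "analyte", drop_incomplete = TRUE)
    inputs <- rescale_inputs(analytes, analyte_map, spec = network)
    tf_table <- batch_simulate(network, inputs)
    input_sets <- c(input_sets, "tf")
  }

  reports <- list()
  for (target in retained) {
    for (set in input_sets) {
      rep_ <- run_task(ct, target, set, thresholds, svm_cfg,
                       tf_table = tf_table)
      reports[[rep_$task]] <- rep_
    }
  }

  imp <- lapply(stats::setNames(input_sets, input_sets), function(set) {
    rs <- Filter(function(r) r$input_set == set, reports)
    if (length(rs)) importance_matrix(rs) else NULL
  })

  validation <- if (!is.null(external_table))
    validate_external(external_table, thresholds, validation_cfg) else NULL

  fits_per_task <- vapply(reports, function(r) length(r$folds), integer(1))
  manifest <- list(
    seed = svm_cfg$seed,
    fold_mode = svm_cfg$fold_mode,
    n_subjects = nrow(ct$data),
    n_sf_subset = if (!is.null(tf_table)) nrow(tf_table$data)
                  else sum(stats::complete.cases(cohort_features(ct, "analyte"))),
    descriptors = names(thresholds),
    retained = retained,
    thresholds = lapply(thresholds, function(r)
      list(threshold = r$threshold, youden = r$youden,
           mean_train_accuracy = r$mean_train_accuracy,
           retained = r$retained)),
    n_tasks = length(reports),
    fits_per_task = as.list(fits_per_task),
    total_fits = sum(fits_per_task),
    tf_converged = if (!is.null(tf_table)) all(attr(tf_table, "converged"))
                   else NA,
    auc = lapply(reports, `[[`, "auc")
  )
  list(cohort = ct, thresholds = thresholds, tf_table = tf_table,
       reports = reports, importance = imp, validation = validation,
       manifest = manifest)
}

#' Write a run manifest as JSON
#'
#' @param manifest the \code{manifest} element of \code{\link{run_all}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
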