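# Synthetic cohort generation.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a cohort of women with knee OA described by 7 ordinal clinical
# descriptors (WOMAC-style questionnaire totals and graded scales), a
# subset with an 11-analyte synovial fluid panel, and planted monotone
# feature -> descriptor associations of configurable effect size. Ordinal
# values arise by discretizing a Gaussian latent variable at fixed
# population quantile cuts, so a "planted split" at a given ordinal
# boundary is well defined and recoverable.

#' Default clinical descriptor specifications
#'
#' Seven descriptors on their conventional scales: joint pain (JP, 5
#' WOMAC pain items on 1-5 Likert scales, total 5-25), functionality
#' (FU, 17 items, total 17-85), rigidity (RI, 2 items, total 2-10),
#' central sensitization grade (SE, 0-3), depression/anxiety (DE, HADS
#' 0-21), pain catastrophism (CA, PCS 0-52) and synovitis grade (SY,
#' 0-3).
#'
#' @return named list of integer level vectors.
#' @export
default_descriptor_specs <- function() {
  list(
    JP = 5:25,
    FU = 17:85,
    RI = 2:10,
    SE = 0:3,
    DE = 0:21,
    CA = 0:52,
    SY = 0:3
  )
}

#' Default synovial fluid analyte panel
#'
#' @return character vector of the 11 analytes measured by the multiplex
#'   immunoassay panel.
#' @export
default_analyte_names <- function() {
  c("IL6", "IL8", "IL4", "TNFa", "IL18", "IFNg", "IL17",
    "IL1RA", "MCP1", "VEGFA", "leptin")
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects cohort size (default 51).
#' @param n_sf_subset number of subjects with synovial fluid analyte
#'   measurements (default 25, must not exceed \code{n_subjects}). The
#'   first \code{n_sf_subset} subjects form the subset.
#' @param descriptor_specs named list mapping descriptor name to the
#'   integer vector of its ordinal levels (ascending).
#' @param analyte_names character vector of analyte column names.
#' @param planted_effects list of planted monotone associations, each a
#'   list with elements \code{feature} (an analyte, or a descriptor
#'   generated earlier in \code{descriptor_specs} order),
#'   \code{descriptor}, \code{effect} (shift on the latent scale, in SD
#'   units of the standardized feature) and optional \code{direction}
#'   (+1/-1, default +1).
#' @param planted_splits list of planted two-subgroup structures, each a
#'   list with \code{descriptor} and \code{boundary} (an ordinal level;
#'   the split separates values <= boundary from values > boundary).
#'   The subject's subgroup is the thresholded latent score, and the
#'   ordinal value is then drawn uniformly within the subgroup's level
#'   range: the descriptor is graded *between* subgroups but not within
#'   them, so the boundary is the one separable cut.
#' @param noise_sd standard deviation of the latent Gaussian noise added
#'   to each descriptor's latent score (default 1).
#' @param analyte_meanlog,analyte_sdlog log-normal parameters for analyte
#'   concentrations (right-skewed, strictly positive).
#' @param seed integer global seed; expanded to per-column child seeds via
#'   \code{\link{child_seed}}.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 51, n_sf_subset = 25,
                          descriptor_specs = default_descriptor_specs(),
                          analyte_names = default_analyte_names(),
                          planted_effects = list(),
                          planted_splits = list(),
                          noise_sd = 1,
                          analyte_meanlog = 2, analyte_sdlog = 1,
                          seed = 1) {
  if (n_subjects < 1) stop_config("n_subjects must be positive")
  if (n_sf_subset < 1 || n_sf_subset > n_subjects)
    stop_config("n_sf_subset must be in [1, n_subjects]")
  if (noise_sd < 0) stop_config("noise_sd must be nonnegative")
  if (is.null(names(descriptor_specs)) || anyDuplicated(names(descriptor_specs)))
    stop_config("descriptor_specs must be a uniquely named list")
  for (nm in names(descriptor_specs)) {
    lv <- descriptor_specs[[nm]]
    if (length(lv) < 2) stop_config("descriptor '%s' needs >= 2 ordinal levels", nm)
    if (is.unsorted(lv, strictly = TRUE))
      stop_config("levels of descriptor '%s' must be strictly ascending", nm)
  }
  if (anyDuplicated(analyte_names)) stop_config("duplicated analyte names")
  known <- c(analyte_names, names(descriptor_specs))
  for (pe in planted_effects) {
    if (is.null(pe$feature) || is.null(pe$descriptor) || is.null(pe$effect))
      stop_config("each planted effect needs feature, descriptor, effect")
    if (!pe$feature %in% known)
      stop_config("planted feature '%s' names no column", pe$feature)
    if (!pe$descriptor %in% names(descriptor_specs))
      stop_config("planted descriptor '%s' names no descriptor", pe$descriptor)
  }
  for (ps in planted_splits) {
    if (is.null(ps$descriptor) || is.null(ps$boundary))
      stop_config("each planted split needs descriptor and boundary")
    lv <- descriptor_specs[[ps$descriptor]]
    if (is.null(lv))
      stop_config("planted split descriptor '%s' names no descriptor",
                  ps$descriptor)
    if (!ps$boundary %in% lv[-length(lv)])
      stop_config("split boundary %s is not an interior level of '%s'",
                  format(ps$boundary), ps$descriptor)
  }
  structure(list(n_subjects = n_subjects, n_sf_subset = n_sf_subset,
                 descriptor_specs = descriptor_specs,
                 analyte_names = analyte_names,
                 planted_effects = planted_effects,
                 planted_splits = planted_splits,
                 noise_sd = noise_sd,
                 analyte_meanlog = analyte_meanlog,
                 analyte_sdlog = analyte_sdlog,
                 seed = seed),
            class = "cohort_config")
}

#' Construct a cohort table
#'
#' A cohort table is a data frame of subjects by features plus a per-column
#' kind tag (\code{clinical}, \code{analyte}, \code{tf} or \code{admin})
#' and, for ordinal clinical columns, the declared level set.
#'
#' @param data data frame with a \code{subject_id} column.
#' @param kinds named character vector, one entry per non-id column.
#' @param levels named list of integer level vectors for ordinal columns.
#' @return object of class \code{cohort_table}.
#' @export
cohort_table <- function(data, kinds, levels = list()) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  if (anyDuplicated(data$subject_id)) stop_config("duplicated subject ids")
  feat <- setdiff(names(data), "subject_id")
  if (!setequal(names(kinds), feat))
    stop_config("kinds must name every non-id column")
  ok <- kinds %in% c("clinical", "analyte", "tf", "admin")
  if (!all(ok)) stop_config("unknown column kind: %s",
                            paste(unique(kinds[!ok]), collapse = ", "))
  structure(list(data = data, kinds = kinds[feat], levels = levels),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects x %d features\n",
              nrow(x$data), length(x$kinds)))
  for (k in unique(x$kinds))
    cat(sprintf("  %s: %s\n", k,
                paste(names(x$kinds)[x$kinds == k], collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) x$data

#' Extract feature columns of a given kind
#'
#' @param ct a \code{cohort_table}.
#' @param kind one of \code{"clinical"}, \code{"analyte"}, \code{"tf"},
#'   \code{"admin"}.
#' @param drop_incomplete drop subjects with any missing value in the
#'   selected columns.
#' @return data frame of the selected columns (subject ids as rownames).
#' @export
cohort_features <- function(ct, kind, drop_incomplete = FALSE) {
  cols <- names(ct$kinds)[ct$kinds == kind]
  out <- ct$data[, cols, drop = FALSE]
  rownames(out) <- ct$data$subject_id
  if (drop_incomplete) out <- out[stats::complete.cases(out), , drop = FALSE]
  out
}

# Latent SD of a descriptor: planted effects act on standardized features,
# so the marginal latent variance is sum(effect^2) + noise_sd^2. Cuts are
# the (1:(L-1))/L quantiles of that marginal normal -- fixed population
# cuts, never re-estimated from the sample.
latent_cuts <- function(n_levels, effects, noise_sd) {
  sd_tot <- sqrt(sum(effects^2) + noise_sd^2)
  if (sd_tot == 0) sd_tot <- 1
  stats::qnorm(seq_len(n_levels - 1) / n_levels, mean = 0, sd = sd_tot)
}

#' Generate a synthetic cohort
#'
#' Analyte concentrations are drawn log-normal for every subject, then
#' masked to missing outside the synovial-fluid subset (the analyte exists
#' in every joint; it is simply unmeasured outside the subset, so planted
#' analyte effects act cohort-wide). Each descriptor's latent score is the
#' sum of its planted effects (on standardized feature values) plus
#' Gaussian noise, discretized to the declared ordinal levels at fixed
#' population quantile cuts. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return a \code{\link{cohort_table}} with clinical and analyte columns.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  dat <- data.frame(subject_id = ids, stringsAsFactors = FALSE)

  # analytes first (fixed column-indexed child seeds)
  analytes <- list()
  for (j in seq_along(config$analyte_names)) {
    set.seed(child_seed(config$seed, j))
    analytes[[config$analyte_names[j]]] <-
      stats::rlnorm(n, meanlog = config$analyte_meanlog,
                    sdlog = config$analyte_sdlog)
  }

  # Planted effects act on the standardized feature; concentration-like
  # (strictly positive, skewed) features are standardized on the log
  # scale, the scale on which dose effects are conventionally linear.
  std <- function(v) {
    if (all(v > 0)) v <- log(v)
    s <- stats::sd(v)
    if (isTRUE(s > 0)) (v - mean(v)) / s else rep(0, length(v))
  }

  desc_vals <- list()
  offset <- length(config$analyte_names)
  dnames <- names(config$descriptor_specs)
  for (j in seq_along(dnames)) {
    dn <- dnames[j]
    pes <- Filter(function(pe) pe$descriptor == dn, config$planted_effects)
    eff <- vapply(pes, function(pe) pe$effect * (pe$direction %||% 1), numeric(1))
    latent <- numeric(n)
    for (i in seq_along(pes)) {
      fn <- pes[[i]]$feature
      fv <- if (fn %in% names(analytes)) analytes[[fn]]
            else if (fn %in% names(desc_vals)) desc_vals[[fn]]
            else stop_config("planted feature '%s' not yet generated (order descriptors so drivers come first)", fn)
      latent <- latent + eff[i] * std(fv)
    }
    set.seed(child_seed(config$seed, offset + j))
    latent <- latent + stats::rnorm(n, 0, config$noise_sd)
    lv <- config$descriptor_specs[[dn]]
    ps <- Filter(function(s) s$descriptor == dn, config$planted_splits)
    if (length(ps)) {
      # two-subgroup structure: the latent decides the subgroup at the
      # boundary's quantile cut; within a subgroup the level is uniform
      b <- ps[[1]]$boundary
      k <- match(b, lv)
      sd_tot <- sqrt(sum(eff^2) + config$noise_sd^2)
      cut <- stats::qnorm(k / length(lv), 0, if (sd_tot > 0) sd_tot else 1)
      g <- latent > cut
      lo <- lv[seq_len(k)]; hi <- lv[-seq_len(k)]
      vals <- integer(n)
      vals[!g] <- lo[1L + (sample.int(n, sum(!g), replace = TRUE) %% length(lo))]
      vals[g] <- hi[1L + (sample.int(n, sum(g), replace = TRUE) %% length(hi))]
      desc_vals[[dn]] <- vals
    } else {
      cuts <- latent_cuts(length(lv), eff, config$noise_sd)
      desc_vals[[dn]] <- lv[1L + findInterval(latent, cuts)]
    }
  }

  for (dn in dnames) dat[[dn]] <- desc_vals[[dn]]
  sf_mask <- seq_len(n) <= config$n_sf_subset
  for (an in config$analyte_names) {
    v <- analytes[[an]]
    v[!sf_mask] <- NA_real_
    dat[[an]] <- v
  }

  kinds <- c(stats::setNames(rep("clinical", length(dnames)), dnames),
             stats::setNames(rep("analyte", length(config$analyte_names)),
                             config$analyte_names))
  cohort_table(dat, kinds, levels = config$descriptor_specs)
}

#' Generate a wide external validation table (OAI-like)
#'
#' Emulates a large observational cohort: blocks of correlated continuous
#' features, six WOMAC-style ordinal target columns (pain 0-20, function
#' 0-68, rigidity 0-8, left and right) driven by one informative feature
#' block each, a binary knee-surgery history flag, and per-cell
#' missingness on the feature columns.
#'
#' @param n_rows number of subjects.
#' @param n_features number of continuous feature columns.
#' @param missing_rate per-cell missingness probability on features,
#'   in [0, 1).
#' @param n_surgery number of rows flagged with surgery history.
#' @param seed integer seed.
#' @param block_size features per correlated block.
#' @param block_rho within-block correlation (0 <= rho < 1).
#' @param effect_size latent effect (SD units) of each target's driver
#'   feature.
#' @param target_noise_sd latent noise SD for the targets.
#' @return a \code{\link{cohort_table}}; targets are kind
#'   \code{clinical}, features \code{analyte}, the flag \code{admin}.
#' @export
generate_external_table <- function(n_rows, n_features = 100,
                                    missing_rate = 0, n_surgery = 0,
                                    seed = 1, block_size = 5,
                                    block_rho = 0.6, effect_size = 1.5,
                                    target_noise_sd = 1) {
  if (n_surgery > n_rows) stop_config("n_surgery exceeds n_rows")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must be in [0, 1)")
  if (block_rho < 0 || block_rho >= 1) stop_config("block_rho must be in [0, 1)")
  n_blocks <- ceiling(n_features / block_size)
  if (n_blocks < 6) stop_config("need at least 6 feature blocks for the 6 targets")

  set.seed(child_seed(seed, 0))
  factors <- matrix(stats::rnorm(n_rows * n_blocks), n_rows, n_blocks)
  X <- matrix(NA_real_, n_rows, n_features)
  for (j in seq_len(n_features)) {
    b <- ((j - 1L) %/% block_size) + 1L
    set.seed(child_seed(seed, j))
    X[, j] <- sqrt(block_rho) * factors[, b] +
      sqrt(1 - block_rho) * stats::rnorm(n_rows)
  }
  colnames(X) <- sprintf("V%03d", seq_len(n_features))

  target_levels <- list(
    womac_pain_left = 0:20,  womac_pain_right = 0:20,
    womac_func_left = 0:68,  womac_func_right = 0:68,
    womac_rigidity_left = 0:8, womac_rigidity_right = 0:8
  )
  dat <- data.frame(subject_id = sprintf("E%05d", seq_len(n_rows)),
                    stringsAsFactors = FALSE)
  tnames <- names(target_levels)
  for (t in seq_along(tnames)) {
    driver <- X[, (t - 1L) * block_size + 1L]   # first column of block t
    set.seed(child_seed(seed, n_features + t))
    latent <- effect_size * as.numeric(scale(driver)) +
      stats::rnorm(n_rows, 0, target_noise_sd)
    lv <- target_levels[[t]]
    cuts <- latent_cuts(length(lv), effect_size, target_noise_sd)
    dat[[tnames[t]]] <- lv[1L + findInterval(latent, cuts)]
  }

  set.seed(child_seed(seed, n_features + 10L))
  flag <- integer(n_rows)
  flag[sample.int(n_rows, n_surgery)] <- 1L
  dat$surgery_history <- flag

  if (missing_rate > 0) {
    set.seed(child_seed(seed, n_features + 11L))
    miss <- matrix(stats::runif(length(X)) < missing_rate, nrow(X), ncol(X))
    X[miss] <- NA_real_
  }
  for (j in seq_len(ncol(X))) dat[[colnames(X)[j]]] <- X[, j]

  kinds <- c(stats::setNames(rep("clinical", length(tnames)), tnames),
             surgery_history = "admin",
             stats::setNames(rep("analyte", ncol(X)), colnames(X)))
  cohort_table(dat, kinds, levels = target_levels)
}

#' Write / read a cohort table as CSV plus a sidecar YAML
#'
#' The CSV is RFC-4180 with a one-line header and empty cells for missing
#' values; the sidecar (same path with extension \code{.yaml}) records the
#' column kinds and ordinal level ranges.
#'
#' @param ct a \code{cohort_table}.
#' @param path CSV path.
#' @return \code{write_cohort}: the path, invisibly. \code{read_cohort}:
#'   the \code{cohort_table}.
#' @export
write_cohort <- function(ct, path) {
  utils::write.csv(ct$data, path, row.names = FALSE, na = "")
  meta <- list(kinds = as.list(ct$kinds),
               levels = lapply(ct$levels, function(lv) c(min(lv), max(lv))))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[A-Za-z0-9]+$", ".yaml", path)

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(sidecar_path(path))
  kinds <- unlist(meta$kinds)
  levels <- lapply(meta$levels, function(r) seq(r[[1]], r[[2]]))
  cohort_table(dat, kinds, levels)
}
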