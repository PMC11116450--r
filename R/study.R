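# The canonical synthetic study: the conditions under which the whole
# analysis (and its tests) run. A cohort of 51 women, 25 with synovial
# fluid, each descriptor carrying a planted two-subgroup split at its
# mid-scale boundary, with functionality (FU) acting as the hub of a
# chain of graded associations and three analytes feeding selected
# descriptors. These are the package's fixed study conditions, not
# tuning knobs.

#' Configuration of the canonical synthetic study
#'
#' Returns the \code{\link{cohort_config}} used by the analysis scripts:
#' 51 subjects, 25 with the synovial fluid panel, the seven descriptors
#' on their conventional scales, each with a planted split at its
#' mid-scale boundary, and a hub-and-spoke association structure
#' (FU drives JP, RI, DE and CA; JP drives SE; RI and leptin drive SY;
#' IL-6 and TNF-alpha contribute to JP and RI). Effect sizes 2-2.5 SD
#' for descriptor-descriptor links and 1-1.5 SD for analyte links.
#'
#' @param seed integer seed for the generator.
#' @return a \code{\link{cohort_config}}.
#' @export
synthetic_study_config <- function(seed = 1) {
  specs <- default_descriptor_specs()
  specs <- specs[c("FU", "JP", "RI", "SE", "DE", "CA", "SY")]  # drivers first
  mid_boundary <- function(lv) lv[ceiling(length(lv) / 2)]
  splits <- lapply(names(specs), function(d)
    list(descriptor = d, boundary = mid_boundary(specs[[d]])))
  cohort_config(
    n_subjects = 51, n_sf_subset = 25,
    descriptor_specs = specs,
    planted_effects = list(
      list(feature = "FU",     descriptor = "JP", effect = 2.5),
      list(feature = "IL6",    descriptor = "JP", effect = 1.0),
      list(feature = "FU",     descriptor = "RI", effect = 2.0),
      list(feature = "TNFa",   descriptor = "RI", effect = 1.0),
      list(feature = "JP",     descriptor = "SE", effect = 2.0),
      list(feature = "FU",     descriptor = "DE", effect = 2.0),
      list(feature = "FU",     descriptor = "CA", effect = 2.5),
      list(feature = "SE",     descriptor = "CA", effect = 1.0),
      list(feature = "RI",     descriptor = "SY", effect = 2.0),
      list(feature = "leptin", descriptor = "SY", effect = 1.5)),
    planted_splits = splits,
    noise_sd = 1,
    seed = seed)
}
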