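## S4 classes for the slide/cohort simulation, cell maps, density summaries
## and fitted association models.

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Configuration of the synthetic slide generator
#'
#' Holds all point-process intensities, nuclear morphology parameters,
#' rendering parameters and the random seed. Intensities are in cells per
#' square millimetre; lengths in microns. Coordinates are continuous microns
#' with the origin at the top-left corner and y increasing downward (raster
#' convention).
#'
#' @slot field_width_um,field_height_um field dimensions in microns.
#' @slot lymphocyte_intensity,cancer_intensity,stromal_intensity expected
#'   number of nuclei per mm^2 for each class.
#' @slot cluster_mode `"poisson"` (homogeneous Poisson for every class) or
#'   `"thomas"` (Thomas cluster process for lymphocytes: Poisson parents,
#'   Gaussian-scattered offspring; other classes stay Poisson).
#' @slot thomas_parent_intensity parents per mm^2 (Thomas mode).
#' @slot thomas_mean_offspring mean offspring per parent (Thomas mode).
#' @slot thomas_sigma_um offspring scatter s.d. in microns (Thomas mode).
#' @slot nucleus_radius_um named list mapping class to `c(mean, sd)` of the
#'   nuclear radius in microns.
#' @slot render_pixel_size_um raster pixel size in microns.
#' @slot render_noise_sd s.d. of additive Gaussian pixel noise (intensity
#'   units on \[0, 1\]).
#' @slot seed integer random seed; identical config + seed gives identical
#'   output.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    field_width_um = "numeric",
    field_height_um = "numeric",
    lymphocyte_intensity = "numeric",
    cancer_intensity = "numeric",
    stromal_intensity = "numeric",
    cluster_mode = "character",
    thomas_parent_intensity = "numeric",
    thomas_mean_offspring = "numeric",
    thomas_sigma_um = "numeric",
    nucleus_radius_um = "list",
    render_pixel_size_um = "numeric",
    render_noise_sd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  inten <- c(object@lymphocyte_intensity, object@cancer_intensity,
             object@stromal_intensity)
  if (any(!is.finite(inten)) || any(inten < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (object@field_width_um <= 0 || object@field_height_um <= 0)
    msg <- c(msg, "field dimensions must be > 0")
  if (!object@cluster_mode %in% c("poisson", "thomas"))
    msg <- c(msg, "cluster_mode must be 'poisson' or 'thomas'")
  if (object@cluster_mode == "thomas" &&
      (!is.finite(object@thomas_sigma_um) || object@thomas_sigma_um <= 0))
    msg <- c(msg, "thomas_sigma_um must be > 0 in thomas mode")
  if (!all(cellClassLevels() %in% names(object@nucleus_radius_um)))
    msg <- c(msg, "nucleus_radius_um must name all three classes")
  if (object@render_pixel_size_um <= 0)
    msg <- c(msg, "render_pixel_size_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth synthetic slide
#'
#' A simulated slide: cells as a marked point pattern (with per-cell true
#' class and nuclear radius) and, after [renderSlide()], an RGB raster.
#'
#' @slot cells `data.frame` with columns `cell_id`, `x_um`, `y_um`, `class`,
#'   `radius_um`.
#' @slot image RGB array (height x width x 3, values in \[0, 1\]) or `NULL`
#'   before rendering.
#' @slot config the [SyntheticConfig-class] that produced the slide.
#' @exportClass GroundTruthSlide
setClass("GroundTruthSlide",
  representation(cells = "data.frame", image = "arrayOrNULL",
                 config = "SyntheticConfig")
)

setValidity("GroundTruthSlide", function(object) {
  msg <- character()
  cl <- object@cells
  need <- c("cell_id", "x_um", "y_um", "class", "radius_um")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "cells must have cell_id, x_um, y_um, class, radius_um")
  else if (nrow(cl)) {
    if (any(cl$x_um < 0 | cl$x_um > object@config@field_width_um |
            cl$y_um < 0 | cl$y_um > object@config@field_height_um))
      msg <- c(msg, "all cell centres must lie inside the field")
    if (any(cl$radius_um <= 0))
      msg <- c(msg, "radii must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Detected cells of one slide as a marked point pattern
#'
#' The pivot between imaging and spatial statistics: cell centroids in
#' microns with class labels, plus the field geometry.
#'
#' @slot slide_id slide identifier.
#' @slot points `data.frame` with columns `x_um`, `y_um`, `class`
#'   (`"cancer"`, `"stromal"` or `"lymphocyte"`).
#' @slot field_width_um,field_height_um field dimensions in microns.
#' @exportClass CellMap
setClass("CellMap",
  representation(slide_id = "character", points = "data.frame",
                 field_width_um = "numeric", field_height_um = "numeric")
)

setValidity("CellMap", function(object) {
  msg <- character()
  p <- object@points
  if (!all(c("x_um", "y_um", "class") %in% names(p)))
    msg <- c(msg, "points must have x_um, y_um, class")
  else if (nrow(p)) {
    if (!all(p$class %in% cellClassLevels()))
      msg <- c(msg, "class must be cancer, stromal or lymphocyte")
    if (any(p$x_um < 0 | p$x_um > object@field_width_um |
            p$y_um < 0 | p$y_um > object@field_height_um))
      msg <- c(msg, "coordinates must lie within the field")
  }
  if (object@field_width_um <= 0 || object@field_height_um <= 0)
    msg <- c(msg, "field dimensions must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-slide lymphocyte density summary
#'
#' Median of the per-lymphocyte K-nearest-neighbour densities
#' \eqn{k/(\pi R^2)} in cells per square micron (reported downstream as
#' arbitrary units, a.u.). With fewer than 2 lymphocytes the summary is
#' missing; with \eqn{2 \le n \le k} the neighbour count is truncated to
#' \eqn{n - 1}.
#'
#' @slot slide_id slide identifier.
#' @slot patient_id patient identifier (may be `NA`).
#' @slot n_lymphocytes number of detected lymphocytes.
#' @slot k_used neighbours used: `min(n_target, n - 1)`; `NA` when `n < 2`.
#' @slot median_density median per-lymphocyte density (`NA` when `n < 2`).
#' @slot per_lymphocyte_densities optional vector of per-lymphocyte
#'   densities (`NULL` unless requested).
#' @exportClass SlideDensitySummary
setClass("SlideDensitySummary",
  representation(slide_id = "character", patient_id = "character",
                 n_lymphocytes = "integer", k_used = "integer",
                 median_density = "numeric",
                 per_lymphocyte_densities = "numericOrNULL")
)

setValidity("SlideDensitySummary", function(object) {
  msg <- character()
  if (!is.na(object@median_density) && object@median_density < 0)
    msg <- c(msg, "median_density must be >= 0")
  if (object@n_lymphocytes >= 2L) {
    if (is.na(object@k_used) || object@k_used > object@n_lymphocytes - 1L)
      msg <- c(msg, "k_used must be <= n_lymphocytes - 1")
  } else if (!is.na(object@median_density)) {
    msg <- c(msg, "median_density must be missing when n_lymphocytes < 2")
  }
  if (length(msg)) msg else TRUE
})

#' Pre- to post-treatment density change for one patient
#'
#' @slot patient_id patient identifier.
#' @slot pre,post the two [SlideDensitySummary-class] objects.
#' @slot delta post minus pre median density (`NA` if either is missing).
#' @slot log_ratio `log(post/pre)` when both are strictly positive.
#' @exportClass DensityChange
setClass("DensityChange",
  representation(patient_id = "character", pre = "SlideDensitySummary",
                 post = "SlideDensitySummary", delta = "numeric",
                 log_ratio = "numeric")
)

#' Trained three-class nucleus classifier
#'
#' A radial-basis-kernel support-vector machine over standardized
#' morphology/intensity features, separating cancer, stromal and lymphocyte
#' nuclei.
#'
#' @slot model fitted `e1071::svm` object.
#' @slot feature_names feature column names, in training order.
#' @slot center,scale per-feature standardization constants.
#' @slot classes the three class labels.
#' @slot metadata list with per-class training counts and the seed.
#' @exportClass TrainedCellClassifier
setClass("TrainedCellClassifier",
  representation(model = "ANY", feature_names = "character",
                 center = "numeric", scale = "numeric",
                 classes = "character", metadata = "list")
)

setValidity("TrainedCellClassifier", function(object) {
  msg <- character()
  if (length(object@classes) != 3L)
    msg <- c(msg, "exactly 3 classes required")
  if (any(!is.finite(object@center)) || any(!is.finite(object@scale)) ||
      any(object@scale <= 0))
    msg <- c(msg, "standardization constants must be finite with sd > 0")
  if (length(msg)) msg else TRUE
})

#' Fitted logistic regression for pCR
#'
#' @slot table per-term `data.frame`: `term`, `estimate` (log-odds), `se`,
#'   `or`, `ci_lo`, `ci_hi`, `p` (Wald).
#' @slot n complete-case observations used.
#' @slot converged `FALSE` when the fit did not converge or the data were
#'   degenerate (e.g. perfect separation, constant outcome); no odds ratios
#'   are reported then.
#' @slot outcome outcome column name.
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(table = "data.frame", n = "integer", converged = "logical",
                 outcome = "character")
)

setValidity("LogisticFit", function(object) {
  if (object@converged && nrow(object@table)) {
    bad <- with(object@table, any(ci_lo > ci_hi, na.rm = TRUE) ||
                  any(abs(or - exp(estimate)) > 1e-8 * (1 + or),
                      na.rm = TRUE))
    if (bad) return("OR must equal exp(coefficient) and CI bounds be ordered")
  }
  TRUE
})

#' Fitted Cox proportional-hazards model
#'
#' @slot table per-term `data.frame`: `term`, `estimate` (log-hazard), `se`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`.
#' @slot n,n_events observations and events in the fitted subset.
#' @slot stratum ER stratum label (`"Positive"`, `"Negative"` or `"all"`).
#' @slot endpoint `"OS"` or `"DFS"`.
#' @exportClass SurvivalFit
setClass("SurvivalFit",
  representation(table = "data.frame", n = "integer", n_events = "integer",
                 stratum = "character", endpoint = "character")
)

setValidity("SurvivalFit", function(object) {
  if (object@n_events > object@n) return("events must be <= n")
  TRUE
})

#' Cohort flow through the analytic stages
#'
#' Patient counts at each analysis stage (primary analysis, baseline density
#' analysis, matched pre/post analysis) with pCR counts and exclusion
#' reasons, as summarized by a trial flowchart.
#'
#' @slot n_primary_analysis,n_baseline_included,n_matched_pre_post stage
#'   counts (each a subset of the previous).
#' @slot n_pcr_baseline,n_pcr_matched pCR counts within the baseline and
#'   matched stages.
#' @slot exclusion_reasons named integer vector; sums must equal the
#'   stage-to-stage differences.
#' @exportClass CohortFlow
setClass("CohortFlow",
  representation(n_primary_analysis = "integer",
                 n_baseline_included = "integer",
                 n_matched_pre_post = "integer",
                 n_pcr_baseline = "integer", n_pcr_matched = "integer",
                 exclusion_reasons = "integer")
)

setValidity("CohortFlow", function(object) {
  msg <- character()
  if (object@n_baseline_included > object@n_primary_analysis ||
      object@n_matched_pre_post > object@n_baseline_included)
    msg <- c(msg, "stage counts must be nested (matched <= baseline <= primary)")
  if (object@n_pcr_baseline > object@n_baseline_included ||
      object@n_pcr_matched > object@n_matched_pre_post)
    msg <- c(msg, "pCR counts cannot exceed their denominators")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic trial cohort generator
#'
#' Defines the covariate distributions, the logistic outcome model for pCR,
#' the survival/censoring model and the pre-to-post density-change model.
#'
#' @slot n_patients cohort size.
#' @slot intercept logistic intercept (log-odds).
#' @slot beta_density log-odds of pCR per unit pre-treatment density (a.u.).
#' @slot beta_covariates named numeric: log-odds per unit (continuous) or
#'   for the non-reference level (binary) of each covariate.
#' @slot covariate_distributions named list of distribution specs, see
#'   [cohortConfig()].
#' @slot delta_density_model list linking residual disease to the
#'   pre-to-post density change (two-component shift scheme).
#' @slot survival_baseline_rate,relapse_baseline_rate,censoring_rate
#'   exponential rates (events per year).
#' @slot log_hazards named numeric log-hazard effects for survival.
#' @slot seed integer random seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    n_patients = "integer", intercept = "numeric", beta_density = "numeric",
    beta_covariates = "numeric", covariate_distributions = "list",
    delta_density_model = "list", survival_baseline_rate = "numeric",
    relapse_baseline_rate = "numeric", censoring_rate = "numeric",
    log_hazards = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@n_patients < 1L) msg <- c(msg, "n_patients must be >= 1")
  if (!is.finite(object@intercept) || !is.finite(object@beta_density))
    msg <- c(msg, "intercept and beta_density must be finite")
  for (nm in names(object@covariate_distributions)) {
    sp <- object@covariate_distributions[[nm]]
    if (!is.list(sp) || is.null(sp$dist))
      msg <- c(msg, sprintf("distribution spec for '%s' must name a dist", nm))
    else if (identical(sp$dist, "categorical") &&
             (abs(sum(sp$probs) - 1) > 1e-8 || any(sp$probs < 0)))
      msg <- c(msg, sprintf("'%s' probabilities must be a proper simplex", nm))
    else if (identical(sp$dist, "bernoulli") &&
             (sp$p < 0 || sp$p > 1))
      msg <- c(msg, sprintf("'%s' bernoulli p must be in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})
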