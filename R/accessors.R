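## Constructors, generics, accessors and show methods.

#' Create a synthetic slide configuration
#'
#' Defaults describe a 1 x 1 mm field with moderately infiltrated tissue:
#' lymphocytes are small, dark and round; cancer nuclei large and mildly
#' irregular; stromal nuclei elongated and pale.
#'
#' @param field_width_um,field_height_um field size in microns.
#' @param lymphocyte_intensity,cancer_intensity,stromal_intensity expected
#'   nuclei per mm^2.
#' @param cluster_mode `"poisson"` or `"thomas"` (clustered lymphocytes).
#' @param thomas_parent_intensity parents per mm^2 (thomas mode).
#' @param thomas_mean_offspring mean offspring per parent.
#' @param thomas_sigma_um offspring scatter s.d., microns.
#' @param nucleus_radius_um named list of `c(mean, sd)` nuclear radii in
#'   microns for `cancer`, `stromal`, `lymphocyte`.
#' @param render_pixel_size_um raster pixel size, microns.
#' @param render_noise_sd additive pixel noise s.d. on \[0, 1\].
#' @param seed random seed.
#' @return A [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(lymphocyte_intensity = 300, seed = 7)
#' slide <- simulatePointPattern(cfg)
#' @export
syntheticConfig <- function(field_width_um = 1000, field_height_um = 1000,
                            lymphocyte_intensity = 400,
                            cancer_intensity = 300,
                            stromal_intensity = 300,
                            cluster_mode = c("poisson", "thomas"),
                            thomas_parent_intensity = 20,
                            thomas_mean_offspring = 20,
                            thomas_sigma_um = 30,
                            nucleus_radius_um = list(
                              cancer = c(6, 0.8),
                              stromal = c(4, 0.5),
                              lymphocyte = c(2.8, 0.3)),
                            render_pixel_size_um = 0.5,
                            render_noise_sd = 0.02,
                            seed = 1L) {
  new("SyntheticConfig",
      field_width_um = field_width_um, field_height_um = field_height_um,
      lymphocyte_intensity = lymphocyte_intensity,
      cancer_intensity = cancer_intensity,
      stromal_intensity = stromal_intensity,
      cluster_mode = match.arg(cluster_mode),
      thomas_parent_intensity = thomas_parent_intensity,
      thomas_mean_offspring = thomas_mean_offspring,
      thomas_sigma_um = thomas_sigma_um,
      nucleus_radius_um = nucleus_radius_um,
      render_pixel_size_um = render_pixel_size_um,
      render_noise_sd = render_noise_sd,
      seed = as.integer(seed))
}

#' Create a cell map
#'
#' @param slide_id slide identifier.
#' @param points `data.frame` with `x_um`, `y_um`, `class`.
#' @param field_width_um,field_height_um field size in microns.
#' @return A [CellMap-class] object.
#' @export
cellMap <- function(slide_id, points, field_width_um, field_height_um) {
  points$class <- as.character(points$class)
  new("CellMap", slide_id = as.character(slide_id),
      points = as.data.frame(points),
      field_width_um = field_width_um, field_height_um = field_height_um)
}

#' @describeIn cellMap the point table of a cell map (or the cells of a
#'   ground-truth slide).
#' @param x a `CellMap` or `GroundTruthSlide`.
#' @export
setGeneric("cellPoints", function(x) standardGeneric("cellPoints"))

#' @rdname cellMap
#' @export
setMethod("cellPoints", "CellMap", function(x) x@points)

#' @rdname cellMap
#' @export
setMethod("cellPoints", "GroundTruthSlide", function(x) x@cells)

#' @describeIn cellMap coordinates of one class as a two-column matrix.
#' @param class cell class to extract.
#' @export
classCoordinates <- function(x, class = "lymphocyte") {
  p <- cellPoints(x)
  p <- p[p$class == class, , drop = FALSE]
  cbind(x_um = p$x_um, y_um = p$y_um)
}

#' Accessors for density summaries
#'
#' @param object a [SlideDensitySummary-class].
#' @return `medianDensity`: the median per-lymphocyte density (a.u.,
#'   `NA` when fewer than 2 lymphocytes); `nLymphocytes`: lymphocyte count;
#'   `kUsed`: neighbours used.
#' @aliases medianDensity nLymphocytes kUsed
#' @export
setGeneric("medianDensity", function(object) standardGeneric("medianDensity"))

#' @rdname medianDensity
#' @export
setMethod("medianDensity", "SlideDensitySummary",
          function(object) object@median_density)

#' @rdname medianDensity
#' @export
setGeneric("nLymphocytes", function(object) standardGeneric("nLymphocytes"))

#' @rdname medianDensity
#' @export
setMethod("nLymphocytes", "SlideDensitySummary",
          function(object) object@n_lymphocytes)

#' @rdname medianDensity
#' @export
setGeneric("kUsed", function(object) standardGeneric("kUsed"))

#' @rdname medianDensity
#' @export
setMethod("kUsed", "SlideDensitySummary", function(object) object@k_used)

#' Coefficient table of a fitted model
#'
#' @param object a [LogisticFit-class] or [SurvivalFit-class].
#' @return `data.frame` of terms with effect estimates, Wald standard
#'   errors, OR/HR with 95% CI and p-values.
#' @export
setGeneric("fitTable", function(object) standardGeneric("fitTable"))

#' @rdname fitTable
#' @export
setMethod("fitTable", "LogisticFit", function(object) object@table)

#' @rdname fitTable
#' @export
setMethod("fitTable", "SurvivalFit", function(object) object@table)

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:",
      sprintf("%g x %g um field, %s mode", object@field_width_um,
              object@field_height_um, object@cluster_mode), "\n")
  cat(sprintf("  intensities (per mm^2): lymphocyte %g, cancer %g, stromal %g\n",
              object@lymphocyte_intensity, object@cancer_intensity,
              object@stromal_intensity))
  cat(sprintf("  pixel size %g um, seed %d\n", object@render_pixel_size_um,
              object@seed))
})

setMethod("show", "GroundTruthSlide", function(object) {
  tab <- table(factor(object@cells$class, levels = cellClassLevels()))
  cat(sprintf("GroundTruthSlide: %d cells (%s)%s\n", nrow(object@cells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if (is.null(object@image)) "" else ", rendered"))
})

setMethod("show", "CellMap", function(object) {
  tab <- table(factor(object@points$class, levels = cellClassLevels()))
  cat(sprintf("CellMap '%s': %d cells in %g x %g um (%s)\n",
              object@slide_id, nrow(object@points), object@field_width_um,
              object@field_height_um,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SlideDensitySummary", function(object) {
  cat(sprintf(
    "SlideDensitySummary '%s': n_lymphocytes = %d, k = %s, median density = %s a.u.\n",
    object@slide_id, object@n_lymphocytes,
    ifelse(is.na(object@k_used), "NA", object@k_used),
    ifelse(is.na(object@median_density), "NA",
           format(object@median_density, digits = 4))))
})

setMethod("show", "DensityChange", function(object) {
  cat(sprintf("DensityChange '%s': delta = %s, log-ratio = %s\n",
              object@patient_id,
              ifelse(is.na(object@delta), "NA",
                     format(object@delta, digits = 4)),
              ifelse(is.na(object@log_ratio), "NA",
                     format(object@log_ratio, digits = 4))))
})

setMethod("show", "TrainedCellClassifier", function(object) {
  n <- object@metadata$n_per_class
  cat(sprintf("TrainedCellClassifier: RBF SVM, %d features, classes %s\n",
              length(object@feature_names),
              paste(object@classes, collapse = "/")))
  if (!is.null(n))
    cat("  training n per class:",
        paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit (outcome %s, n = %d, %s)\n", object@outcome,
              object@n,
              if (object@converged) "converged" else "NOT converged"))
  if (object@converged) print(object@table, digits = 3, row.names = FALSE)
})

setMethod("show", "SurvivalFit", function(object) {
  cat(sprintf("SurvivalFit (%s, ER %s, n = %d, events = %d)\n",
              object@endpoint, object@stratum, object@n, object@n_events))
  print(object@table, digits = 3, row.names = FALSE)
})

setMethod("show", "CohortFlow", function(object) {
  cat(sprintf(
    "CohortFlow: primary %d -> baseline %d -> matched %d; pCR %d / %d\n",
    object@n_primary_analysis, object@n_baseline_included,
    object@n_matched_pre_post, object@n_pcr_baseline, object@n_pcr_matched))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d patients, beta_density = %.3f (OR %.2f), seed %d\n",
    object@n_patients, object@beta_density, exp(object@beta_density),
    object@seed))
})
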