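#' Cell class labels
#'
#' The closed set of cell classes used throughout the pipeline, in canonical
#' order.
#'
#' @return `c("cancer", "stromal", "lymphocyte")`
#' @export
cellClassLevels <- function() c("cancer", "stromal", "lymphocyte")

## canonical factor level orders for the clinical covariates; the first
## level is the reference category of every model
.covariateLevels <- list(
  er_status = c("Negative", "Positive"),
  node_status = c("Negative", "Positive"),
  tumour_size_cat = c("<=50 mm", ">50 mm"),
  arm = c("BEV+D FEC", "D FEC")
)

#' Round half away from zero
#'
#' Integer rounding with halves going away from zero, the convention used
#' for the cohort-flow percentages (e.g. 78.4 -> 78, 48.5 -> 49).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

.assertScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.integer(x)
}

.assertFiniteMatrixXY <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x_um", "y_um") %in% names(points)) ||
                all(c("x", "y") %in% names(points)))
    if (all(c("x_um", "y_um") %in% names(points)))
      points <- cbind(points$x_um, points$y_um)
    else points <- cbind(points$x, points$y)
  }
  points <- as.matrix(points)
  if (ncol(points) < 2L) stop("points must have two coordinate columns")
  points <- points[, 1:2, drop = FALSE]
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("coordinates must be finite")
  points
}
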