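## The K-nearest-neighbour lymphocyte density statistic: for every
## lymphocyte the mean distance R to its k nearest lymphocytes, the
## per-lymphocyte density k/(pi R^2), and the per-slide median summary.

#' Mean distance to the k nearest neighbours of one point
#'
#' Euclidean metric in micron coordinates; the point itself is excluded.
#' Exact ties are resolved by the distance multiset (the k smallest
#' distance values are averaged), so tied points are interchangeable.
#'
#' @param points two-column matrix or `data.frame` of coordinates (`x_um`,
#'   `y_um` or plain columns).
#' @param index 1-based index of the query point.
#' @param k number of neighbours, `1 <= k <= n - 1`.
#' @return mean of the k smallest distances from point `index` to the
#'   others, in the coordinate units.
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
#' knnMeanDistance(pts, index = 1, k = 3)  # (1 + 1 + sqrt(2)) / 3
#' @export
knnMeanDistance <- function(points, index, k) {
  pts <- .assertFiniteMatrixXY(points)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points")
  if (index < 1L || index > n) stop("index out of range")
  if (k < 1L || k > n - 1L) stop("k must be in [1, n - 1]")
  d <- sqrt((pts[, 1] - pts[index, 1])^2 + (pts[, 2] - pts[index, 2])^2)
  d <- d[-index]
  mean(sort(d, partial = k)[seq_len(k)])
}

#' Per-lymphocyte KNN densities and the per-slide median summary
#'
#' For each lymphocyte the mean distance \eqn{R_i} to its `k_used` nearest
#' lymphocytes is computed (grid-accelerated exact search) and converted to
#' a density \eqn{k_{used}/(\pi R_i^2)}; the slide summary is the median
#' over lymphocytes. `k_used = min(n_target, n - 1)`: slides with
#' `2 <= n <= n_target` lymphocytes use the truncated neighbour count, and
#' slides with fewer than 2 lymphocytes get a missing summary. Lymphocytes
#' at exactly duplicated coordinates (\eqn{R_i = 0}) get a missing density
#' and are excluded from the median, with a warning.
#'
#' No edge correction is applied; densities near the field border are
#' biased low.
#'
#' @param x a [CellMap-class] (its lymphocyte points are used), a
#'   [GroundTruthSlide-class], or a two-column coordinate matrix of
#'   lymphocyte positions in microns.
#' @param n_target target neighbour count N (default 50).
#' @param slide_id,patient_id identifiers carried into the summary (taken
#'   from a `CellMap` when available).
#' @param keep_densities keep the per-lymphocyte density vector in the
#'   result.
#' @return A [SlideDensitySummary-class]; densities in cells per square
#'   micron (reported downstream as arbitrary units).
#' @examples
#' pts <- cbind(runif(200, 0, 500), runif(200, 0, 500))
#' medianDensity(lymphocyteDensity(pts, n_target = 50))
#' @export
lymphocyteDensity <- function(x, n_target = 50, slide_id = "slide",
                              patient_id = NA_character_,
                              keep_densities = FALSE) {
  n_target <- .assertScalarCount(n_target, "n_target")
  if (n_target < 1L) stop("n_target must be >= 1")
  if (is(x, "CellMap")) {
    slide_id <- x@slide_id
    pts <- classCoordinates(x, "lymphocyte")
  } else if (is(x, "GroundTruthSlide")) {
    cl <- x@cells
    cl <- cl[cl$class == "lymphocyte", , drop = FALSE]
    pts <- cbind(cl$x_um, cl$y_um)
  } else {
    pts <- .assertFiniteMatrixXY(x)
  }
  n <- nrow(pts)
  if (n < 2L)
    return(new("SlideDensitySummary", slide_id = as.character(slide_id),
               patient_id = as.character(patient_id),
               n_lymphocytes = as.integer(n), k_used = NA_integer_,
               median_density = NA_real_,
               per_lymphocyte_densities = NULL))
  k <- min(n_target, n - 1L)
  R <- .knnMeanDistAll(pts[, 1], pts[, 2], as.integer(k))
  dens <- k / (pi * R^2)
  zero <- R == 0
  if (any(zero)) {
    warning(sprintf(
      "%d lymphocyte(s) at duplicated coordinates excluded from the median",
      sum(zero)))
    dens[zero] <- NA_real_
  }
  med <- median(dens, na.rm = TRUE)
  if (!is.finite(med)) med <- NA_real_
  new("SlideDensitySummary", slide_id = as.character(slide_id),
      patient_id = as.character(patient_id), n_lymphocytes = as.integer(n),
      k_used = as.integer(k), median_density = med,
      per_lymphocyte_densities = if (keep_densities) dens else NULL)
}

#' Pre- to post-treatment density change
#'
#' `delta = post - pre` median density; the log-ratio `log(post/pre)` is
#' added when both are strictly positive. A missing summary on either side
#' propagates (the record is retained with missing change values).
#'
#' @param pre,post [SlideDensitySummary-class] objects for the same
#'   patient; non-missing, non-matching patient ids are a contract
#'   violation.
#' @param patient_id identifier; defaults to the (shared) id of the
#'   summaries.
#' @return A [DensityChange-class].
#' @examples
#' s1 <- lymphocyteDensity(cbind(runif(100, 0, 300), runif(100, 0, 300)))
#' s2 <- lymphocyteDensity(cbind(runif(400, 0, 300), runif(400, 0, 300)))
#' densityChange(s1, s2)
#' @export
densityChange <- function(pre, post, patient_id = NULL) {
  stopifnot(is(pre, "SlideDensitySummary"), is(post, "SlideDensitySummary"))
  ids <- c(pre@patient_id, post@patient_id)
  known <- ids[!is.na(ids)]
  if (length(unique(known)) > 1L)
    stop("pre and post summaries belong to different patients")
  if (is.null(patient_id))
    patient_id <- if (length(known)) known[1] else NA_character_
  a <- pre@median_density; b <- post@median_density
  delta <- if (is.na(a) || is.na(b)) NA_real_ else b - a
  lr <- if (!is.na(delta) && a > 0 && b > 0) log(b / a) else NA_real_
  new("DensityChange", patient_id = as.character(patient_id), pre = pre,
      post = post, delta = delta, log_ratio = lr)
}

#' Rescale values to the unit interval
#'
#' `(x - min) / (max - min)` over the non-missing values; an all-equal
#' input maps to all zeros (documented convention). Missing values stay
#' missing.
#'
#' @param values numeric vector with at least one non-missing value.
#' @return vector on \[0, 1\], same length and order.
#' @examples
#' rescaleUnitInterval(c(2, 4, 6))
#' @export
rescaleUnitInterval <- function(values) {
  if (!length(values) || all(is.na(values)))
    stop("need at least one non-missing value")
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (hi == lo) return(ifelse(is.na(values), NA_real_, 0))
  (values - lo) / (hi - lo)
}
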