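## Morphology and intensity features of segmented nuclei, used by the
## three-class cell classifier.

#' Feature names of the nucleus feature vector
#'
#' Seven morphology/intensity features: area (um^2), moment-based
#' eccentricity, solidity (area / convex hull area), equivalent diameter
#' (um), mean and s.d. of the haematoxylin optical density under the mask,
#' and circularity (moment-based roundness `A / (pi * a^2)` with `a` the
#' semi-major axis `2 * sqrt(lambda1)`; 1 for a disc, `b/a` for an
#' ellipse).
#'
#' @return character vector of feature column names.
#' @export
nucleusFeatureNames <- function() {
  c("area_um2", "eccentricity", "solidity", "equivalent_diameter_um",
    "mean_haematoxylin_od", "sd_haematoxylin_od", "circularity")
}

.polygonArea <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Extract the feature vector of one nucleus
#'
#' Morphology comes from the pixel mask (in micron units), intensity
#' statistics from the haematoxylin channel under the mask. Deterministic.
#' Solidity uses the convex hull of the pixel squares (centres offset by
#' half a pixel in the four diagonal directions), so it is <= 1 up to
#' discretization and clamped to \[0, 1\].
#'
#' @param rows,cols pixel coordinates of the mask (1-based, rows = y).
#' @param haematoxylin haematoxylin channel matrix.
#' @param microns_per_pixel raster calibration.
#' @return named numeric vector, see [nucleusFeatureNames()].
#' @export
extractFeatures <- function(rows, cols, haematoxylin, microns_per_pixel) {
  npx <- length(rows)
  if (!npx) stop("empty mask")
  mpp <- microns_per_pixel
  x <- (cols - 0.5) * mpp
  y <- (rows - 0.5) * mpp
  area <- npx * mpp^2

  mx <- mean(x); my <- mean(y)
  ## central second moments plus the pixel's own spread (1/12 px^2)
  mu20 <- mean((x - mx)^2) + mpp^2 / 12
  mu02 <- mean((y - my)^2) + mpp^2 / 12
  mu11 <- mean((x - mx) * (y - my))
  tr <- (mu20 + mu02) / 2
  det <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr + det
  l2 <- max(tr - det, 0)
  eccentricity <- sqrt(max(0, 1 - l2 / l1))
  semi_major <- 2 * sqrt(l1)
  circularity <- min(1, area / (pi * semi_major^2))

  hx <- c(x + mpp / 2, x + mpp / 2, x - mpp / 2, x - mpp / 2)
  hy <- c(y + mpp / 2, y - mpp / 2, y + mpp / 2, y - mpp / 2)
  hull <- chull(hx, hy)
  hull_area <- .polygonArea(hx[hull], hy[hull])
  solidity <- min(1, area / hull_area)

  vals <- haematoxylin[cbind(rows, cols)]
  c(area_um2 = area,
    eccentricity = eccentricity,
    solidity = solidity,
    equivalent_diameter_um = 2 * sqrt(area / pi),
    mean_haematoxylin_od = mean(vals),
    sd_haematoxylin_od = if (npx > 1) sd(vals) else 0,
    circularity = circularity)
}

#' Extract features for every nucleus of a segmented image
#'
#' @param nuclei a [NucleusSet-class] (or any integer label matrix).
#' @param haematoxylin haematoxylin channel matrix, same size as the label
#'   matrix.
#' @return `data.frame` with `nucleus_id` and the seven feature columns,
#'   one row per nucleus, in `nucleusTable()` order.
#' @export
extractAllFeatures <- function(nuclei, haematoxylin) {
  lab <- if (is(nuclei, "NucleusSet")) nuclei@labels else nuclei
  mpp <- if (is(nuclei, "NucleusSet")) nuclei@microns_per_pixel else 1
  stopifnot(identical(dim(lab), dim(haematoxylin)))
  ids <- sort(unique(lab[lab > 0L]))
  idx <- which(lab > 0L)
  labv <- lab[idx]
  H <- nrow(lab)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  feat <- t(vapply(ids, function(id) {
    sel <- labv == id
    extractFeatures(rows[sel], cols[sel], haematoxylin, mpp)
  }, numeric(length(nucleusFeatureNames()))))
  out <- data.frame(nucleus_id = ids, feat)
  names(out)[-1] <- nucleusFeatureNames()
  out
}
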