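## Nucleus segmentation: colour deconvolution into haematoxylin/eosin
## optical-density channels, then smoothing -> Otsu threshold -> hole fill
## -> distance-transform watershed -> area filter.

#' Detected nuclei of one image
#'
#' @slot objects `data.frame` with `nucleus_id`, `x_um`, `y_um`,
#'   `area_um2`, one row per nucleus, sorted row-major by centroid.
#' @slot labels integer label matrix (rows = y, cols = x; 0 = background);
#'   masks are disjoint by construction.
#' @slot microns_per_pixel raster calibration.
#' @exportClass NucleusSet
setClass("NucleusSet",
  representation(objects = "data.frame", labels = "matrix",
                 microns_per_pixel = "numeric")
)

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d nuclei in a %d x %d px image (%g um/px)\n",
              nrow(object@objects), nrow(object@labels),
              ncol(object@labels), object@microns_per_pixel))
})

#' @rdname detectNuclei
#' @param x a `NucleusSet`.
#' @return `nucleusTable`: the per-nucleus `data.frame`.
#' @export
nucleusTable <- function(x) x@objects

## Ruifrok-Johnston H&E optical-density stain vectors (rows, unit length)
.heStainMatrix <- function() {
  m <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             d = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

.asRGBArray <- function(image) {
  if (is(image, "Image")) {
    d <- dim(image)
    if (length(d) != 3L || d[3] != 3L)
      stop("input must be an RGB image")
    image <- aperm(EBImage::imageData(image), c(2, 1, 3))
  }
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("input must be an RGB image (height x width x 3 array)")
  if (max(image) > 1) image <- image / 255
  image
}

#' Separate haematoxylin and eosin stains by colour deconvolution
#'
#' Converts RGB transmittance to optical density and projects onto fixed
#' H&E stain vectors (Ruifrok-Johnston matrix). The haematoxylin channel is
#' high over nuclei, the eosin channel over cytoplasm/stroma. Channels are
#' clamped at zero.
#'
#' @param image RGB array (height x width x 3, values on \[0, 1\] or
#'   \[0, 255\]) or an `EBImage::Image` in colour mode.
#' @return list with matrices `haematoxylin` and `eosin` (optical density
#'   units, rows = y).
#' @examples
#' slide <- renderSlide(simulatePointPattern(syntheticConfig(
#'   field_width_um = 100, field_height_um = 100, seed = 1)))
#' st <- separateStains(slideImage(slide))
#' range(st$haematoxylin)
#' @export
separateStains <- function(image) {
  image <- .asRGBArray(image)
  d <- dim(image)
  od <- -log10(pmax(image, 1 / 255))
  odm <- matrix(od, ncol = 3L)
  conc <- odm %*% solve(.heStainMatrix())
  conc[conc < 0] <- 0
  list(haematoxylin = matrix(conc[, 1], d[1], d[2]),
       eosin = matrix(conc[, 2], d[1], d[2]))
}

#' Segmentation parameters
#'
#' `microns_per_pixel` has no default: the calibration must be explicit.
#' Areas are in square microns; the default bounds (8-250 um^2) are
#' generous around the generator's nuclear radii.
#'
#' @param microns_per_pixel raster calibration (um per pixel).
#' @param smooth_sigma_um Gaussian smoothing scale before thresholding.
#' @param threshold `"otsu"` or a numeric absolute threshold on the
#'   (smoothed, min-max normalized) haematoxylin channel.
#' @param min_area_um2,max_area_um2 object area filter.
#' @param watershed_tolerance_px minimum distance-map peak depth (pixels)
#'   for splitting touching nuclei.
#' @param min_contrast_od minimum dynamic range (optical density) of the
#'   smoothed channel; images below it are treated as foreground-free
#'   (guards against Otsu segmenting pure pixel noise).
#' @return list of validated parameters.
#' @export
segmentationParams <- function(microns_per_pixel,
                               smooth_sigma_um = 1,
                               threshold = "otsu",
                               min_area_um2 = 8,
                               max_area_um2 = 250,
                               watershed_tolerance_px = 2,
                               min_contrast_od = 0.1) {
  if (missing(microns_per_pixel) || !is.finite(microns_per_pixel) ||
      microns_per_pixel <= 0)
    stop("microns_per_pixel must be given and > 0")
  if (min_area_um2 >= max_area_um2)
    stop("min_area_um2 must be < max_area_um2")
  list(microns_per_pixel = microns_per_pixel,
       smooth_sigma_um = smooth_sigma_um, threshold = threshold,
       min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
       watershed_tolerance_px = watershed_tolerance_px,
       min_contrast_od = min_contrast_od)
}

#' Detect and segment nuclei in a haematoxylin channel
#'
#' Pipeline: Gaussian smoothing, global threshold (Otsu by default on the
#' min-max normalized channel), hole filling, distance-transform watershed
#' to split touching nuclei, then an area filter. Deterministic: the same
#' channel and parameters give the identical object list, sorted row-major
#' by centroid.
#'
#' @param haematoxylin single-channel matrix (rows = y), e.g. from
#'   [separateStains()].
#' @param params list from [segmentationParams()].
#' @return A [NucleusSet-class]. An image with no detectable foreground
#'   yields an empty set (not an error).
#' @export
detectNuclei <- function(haematoxylin, params) {
  if (!is.matrix(haematoxylin) || !is.numeric(haematoxylin))
    stop("haematoxylin must be a single-channel numeric matrix")
  mpp <- params$microns_per_pixel
  H <- nrow(haematoxylin); W <- ncol(haematoxylin)
  empty <- function() new("NucleusSet",
    objects = data.frame(nucleus_id = integer(), x_um = numeric(),
                         y_um = numeric(), area_um2 = numeric()),
    labels = matrix(0L, H, W), microns_per_pixel = mpp)
  if (!length(haematoxylin)) return(empty())

  ch <- EBImage::Image(t(haematoxylin))
  if (params$smooth_sigma_um > 0) {
    sigma_px <- params$smooth_sigma_um / mpp
    ch <- EBImage::gblur(ch, sigma = sigma_px)
  }
  v <- EBImage::imageData(ch)
  rng <- range(v)
  mc <- if (is.null(params$min_contrast_od)) 0.1 else params$min_contrast_od
  if (diff(rng) < mc) return(empty())  # flat / noise-only image
  v01 <- (v - rng[1]) / diff(rng)
  thr <- if (identical(params$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(v01), range = c(0, 1))
  else as.numeric(params$threshold)
  mask <- v01 > thr
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance_px,
                           ext = 1)
  lab <- t(EBImage::imageData(ws))  # back to rows = y
  storage.mode(lab) <- "integer"

  npx <- tabulate(lab)
  if (!length(npx)) return(empty())
  area_um2 <- npx * mpp^2
  keep <- which(area_um2 >= params$min_area_um2 &
                  area_um2 <= params$max_area_um2)
  if (!length(keep)) return(empty())

  idx <- which(lab > 0L)
  labv <- lab[idx]
  sel <- labv %in% keep
  idx <- idx[sel]; labv <- labv[sel]
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  cx <- tapply((cols - 0.5) * mpp, labv, mean)
  cy <- tapply((rows - 0.5) * mpp, labv, mean)
  ids_old <- as.integer(names(cx))
  ord <- order(cy, cx)

  relabel <- integer(max(labv))
  relabel[ids_old[ord]] <- seq_along(ord)
  newlab <- matrix(0L, H, W)
  newlab[idx] <- relabel[labv]
  objects <- data.frame(nucleus_id = seq_along(ord),
                        x_um = as.numeric(cx[ord]),
                        y_um = as.numeric(cy[ord]),
                        area_um2 = as.numeric(area_um2[ids_old[ord]]))
  new("NucleusSet", objects = objects, labels = newlab,
      microns_per_pixel = mpp)
}

#' Match detected nuclei to ground-truth cells
#'
#' Greedy one-to-one nearest matching: a detection matches the closest
#' unmatched ground-truth cell whose centre lies within `tol_radii` times
#' that cell's radius.
#'
#' @param detections `data.frame` with `x_um`, `y_um`.
#' @param truth ground-truth cells `data.frame` with `x_um`, `y_um`,
#'   `radius_um` (e.g. `cellPoints()` of a [GroundTruthSlide-class]).
#' @param tol_radii match tolerance in units of the true nuclear radius.
#' @return integer vector, for each detection the matched truth row index
#'   or `NA`.
#' @export
matchNuclei <- function(detections, truth, tol_radii = 1) {
  nd <- nrow(detections)
  out <- rep(NA_integer_, nd)
  if (!nd || !nrow(truth)) return(out)
  taken <- rep(FALSE, nrow(truth))
  for (i in seq_len(nd)) {
    d2 <- (truth$x_um - detections$x_um[i])^2 +
      (truth$y_um - detections$y_um[i])^2
    ok <- which(!taken & d2 <= (tol_radii * truth$radius_um)^2)
    if (length(ok)) {
      j <- ok[which.min(d2[ok])]
      out[i] <- j
      taken[j] <- TRUE
    }
  }
  out
}
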