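## Synthetic ground-truth slides: marked point patterns of cancer / stromal /
## lymphocyte nuclei and their rendering as H&E-like RGB rasters.

## class-conditional appearance, defined in stain-concentration space:
## the rendered colour is the Beer-Lambert transmittance
## 10^-(ch * H + ce * E) for the fixed H&E stain vectors, so colour
## deconvolution recovers the configured haematoxylin level. Lymphocytes
## are small/dark/round (high haematoxylin), cancer nuclei large and
## mildly irregular, stromal nuclei elongated and paler.
.classAppearance <- list(
  cancer     = list(ch = 0.45, ce = 0.18, ratio = c(1.2, 1.7)),
  stromal    = list(ch = 0.35, ce = 0.35, ratio = c(2.5, 4.0)),
  lymphocyte = list(ch = 1.00, ce = 0.10, ratio = c(1.0, 1.15))
)
.backgroundStain <- c(ch = 0.015, ce = 0.10)

## transmittance colour of a stain mixture (Beer-Lambert, base 10)
.stainColour <- function(ch, ce) {
  m <- .heStainMatrix()
  10^-(ch * m["h", ] + ce * m["e", ])
}

.truncNorm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Simulate a marked point pattern of cell nuclei
#'
#' Draws each cell class as a homogeneous Poisson process at its configured
#' intensity; in `"thomas"` mode the lymphocytes instead follow a Thomas
#' cluster process (Poisson parents at `thomas_parent_intensity`, a
#' Poisson(`thomas_mean_offspring`) number of offspring per parent scattered
#' with isotropic Gaussian s.d. `thomas_sigma_um`, clipped to the field).
#' Nuclear radii are truncated-normal per class; each nucleus also receives
#' an ellipse axis ratio and orientation used by [renderSlide()].
#'
#' The draw is fully determined by the config (including its `seed`).
#'
#' @param config a [SyntheticConfig-class].
#' @return A [GroundTruthSlide-class] (cells only; no image yet).
#' @examples
#' slide <- simulatePointPattern(syntheticConfig(seed = 42))
#' head(cellPoints(slide))
#' @export
simulatePointPattern <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed)
  W <- config@field_width_um
  H <- config@field_height_um
  area_mm2 <- (W / 1000) * (H / 1000)

  one_class <- function(class, intensity) {
    if (class == "lymphocyte" && config@cluster_mode == "thomas") {
      n_par <- rpois(1, config@thomas_parent_intensity * area_mm2)
      if (n_par == 0L) return(NULL)
      px <- runif(n_par, 0, W)
      py <- runif(n_par, 0, H)
      n_off <- rpois(n_par, config@thomas_mean_offspring)
      x <- rep(px, n_off) + rnorm(sum(n_off), 0, config@thomas_sigma_um)
      y <- rep(py, n_off) + rnorm(sum(n_off), 0, config@thomas_sigma_um)
      keep <- x >= 0 & x <= W & y >= 0 & y <= H
      x <- x[keep]; y <- y[keep]
    } else {
      n <- rpois(1, intensity * area_mm2)
      if (n == 0L) return(NULL)
      x <- runif(n, 0, W)
      y <- runif(n, 0, H)
    }
    n <- length(x)
    if (n == 0L) return(NULL)
    rmv <- config@nucleus_radius_um[[class]]
    app <- .classAppearance[[class]]
    data.frame(x_um = x, y_um = y, class = class,
               radius_um = .truncNorm(n, rmv[1], rmv[2], lower = 0.5),
               axis_ratio = runif(n, app$ratio[1], app$ratio[2]),
               theta = runif(n, 0, pi))
  }

  parts <- list(one_class("cancer", config@cancer_intensity),
                one_class("stromal", config@stromal_intensity),
                one_class("lymphocyte", config@lymphocyte_intensity))
  cells <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(cells))
    cells <- data.frame(x_um = numeric(), y_um = numeric(),
                        class = character(), radius_um = numeric(),
                        axis_ratio = numeric(), theta = numeric())
  cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL
  new("GroundTruthSlide", cells = cells, image = NULL, config = config)
}

## ellipse half-axes preserving area pi * r^2: a = r*sqrt(ratio), b = r/sqrt(ratio)
.ellipseAxes <- function(radius, ratio) {
  s <- sqrt(ratio)
  cbind(a = radius * s, b = radius / s)
}

#' Rasterize ground-truth cells into a label mask
#'
#' Paints each nucleus ellipse with its `cell_id` (later cells overwrite
#' earlier ones where nuclei overlap). Useful as a segmentation oracle and
#' for feature extraction from known masks.
#'
#' @param slide a [GroundTruthSlide-class].
#' @param config the rendering config; defaults to the slide's own.
#' @return Integer matrix (rows = y, cols = x); 0 is background.
#' @export
rasterizeGroundTruth <- function(slide, config = slide@config) {
  mpp <- config@render_pixel_size_um
  if (mpp <= 0) stop("render_pixel_size_um must be > 0")
  W <- max(1L, round(config@field_width_um / mpp))
  H <- max(1L, round(config@field_height_um / mpp))
  lab <- matrix(0L, nrow = H, ncol = W)
  cl <- slide@cells
  if (!nrow(cl)) return(lab)
  ax <- .ellipseAxes(cl$radius_um, cl$axis_ratio)
  for (i in seq_len(nrow(cl))) {
    px <- .ellipsePixels(cl$x_um[i], cl$y_um[i], ax[i, 1], ax[i, 2],
                         cl$theta[i], mpp, H, W)
    if (length(px)) lab[px] <- cl$cell_id[i]
  }
  lab
}

## linear indices of pixels whose centres fall inside the rotated ellipse
.ellipsePixels <- function(cx, cy, a, b, theta, mpp, H, W) {
  r_max <- max(a, b)
  c0 <- max(1L, floor((cx - r_max) / mpp))
  c1 <- min(W, ceiling((cx + r_max) / mpp) + 1L)
  r0 <- max(1L, floor((cy - r_max) / mpp))
  r1 <- min(H, ceiling((cy + r_max) / mpp) + 1L)
  if (c1 < c0 || r1 < r0) return(integer())
  cols <- c0:c1
  rows <- r0:r1
  xs <- (cols - 0.5) * mpp - cx
  ys <- (rows - 0.5) * mpp - cy
  dx <- matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(ys, nrow = length(rows), ncol = length(cols))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- which(u * u + v * v <= 1)
  if (!length(inside)) return(integer())
  rr <- rows[(inside - 1L) %% length(rows) + 1L]
  cc <- cols[(inside - 1L) %/% length(rows) + 1L]
  (cc - 1L) * H + rr
}

#' Render a ground-truth slide as an RGB raster
#'
#' Each nucleus is drawn as a filled ellipse with its class colour (small
#' per-nucleus brightness jitter) on a pale pink background, then additive
#' Gaussian pixel noise is applied. The render is deterministic for a given
#' config (noise is seeded from `config@seed`).
#'
#' @param slide a [GroundTruthSlide-class].
#' @param config rendering config; defaults to the slide's own.
#' @return The slide with its `image` slot set to a height x width x 3
#'   array on \[0, 1\].
#' @seealso [slideImage()], [rasterizeGroundTruth()]
#' @export
renderSlide <- function(slide, config = slide@config) {
  stopifnot(is(slide, "GroundTruthSlide"))
  mpp <- config@render_pixel_size_um
  if (mpp <= 0) stop("render_pixel_size_um must be > 0")
  set.seed(config@seed + 1L)
  W <- max(1L, round(config@field_width_um / mpp))
  H <- max(1L, round(config@field_height_um / mpp))
  bg <- .stainColour(.backgroundStain["ch"], .backgroundStain["ce"])
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  cl <- slide@cells
  if (nrow(cl)) {
    ax <- .ellipseAxes(cl$radius_um, cl$axis_ratio)
    jitter <- rnorm(nrow(cl), 0, 0.05)
    for (i in seq_len(nrow(cl))) {
      px <- .ellipsePixels(cl$x_um[i], cl$y_um[i], ax[i, 1], ax[i, 2],
                           cl$theta[i], mpp, H, W)
      if (!length(px)) next
      app <- .classAppearance[[cl$class[i]]]
      col <- .stainColour(app$ch * (1 + jitter[i]), app$ce)
      img[px] <- col[1]
      img[px + H * W] <- col[2]
      img[px + 2L * H * W] <- col[3]
    }
  }
  if (config@render_noise_sd > 0) {
    img <- img + rnorm(length(img), 0, config@render_noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  initialize(slide, image = img)
}

#' @rdname renderSlide
#' @param x a rendered [GroundTruthSlide-class].
#' @return `slideImage`: the RGB array, or `NULL` if not rendered.
#' @export
slideImage <- function(x) x@image

#' Convert a ground-truth slide to a cell map
#'
#' Drops morphology, keeping centroids and true class labels; useful to run
#' the spatial statistics directly on ground truth (coordinate mode).
#'
#' @param slide a [GroundTruthSlide-class].
#' @param slide_id identifier for the resulting map.
#' @return A [CellMap-class].
#' @export
asCellMap <- function(slide, slide_id = "slide1") {
  cellMap(slide_id,
          slide@cells[, c("x_um", "y_um", "class"), drop = FALSE],
          slide@config@field_width_um, slide@config@field_height_um)
}
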