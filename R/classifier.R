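## Three-class nucleus classification: RBF-kernel SVM on standardized
## morphology/intensity features (one-vs-one for the three classes).

#' Train the three-class nucleus classifier
#'
#' Features are standardized (per-feature mean/sd from the training set)
#' and a radial-basis-kernel support-vector machine is fitted with
#' one-vs-one decomposition over the classes cancer / stromal /
#' lymphocyte. Training uses equal per-class counts by design upstream, so
#' no class reweighting is applied. Deterministic given the data (the seed
#' is recorded in the metadata for provenance of any stochastic upstream
#' sampling).
#'
#' @param features `data.frame` or matrix of feature columns (see
#'   [nucleusFeatureNames()]); extra columns such as `nucleus_id` are
#'   ignored.
#' @param labels vector of class labels, one per row.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses the libsvm
#'   default 1/n_features).
#' @param seed recorded training seed.
#' @return A [TrainedCellClassifier-class].
#' @examples
#' ts <- makeTrainingSet(n_per_class = 50, seed = 1)
#' clf <- trainCellClassifier(ts$features, ts$labels)
#' @export
trainCellClassifier <- function(features, labels, cost = 1, gamma = NULL,
                                seed = 1L) {
  X <- .featureMatrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("one label per feature row required")
  missing_cl <- setdiff(cellClassLevels(), labels)
  if (length(missing_cl))
    stop("class(es) absent from training data: ",
         paste(missing_cl, collapse = ", "))
  tab <- table(labels)
  if (any(tab < 2L)) stop("need >= 2 examples per class")

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  y <- factor(labels, levels = cellClassLevels())
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  model <- e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
  new("TrainedCellClassifier", model = model,
      feature_names = colnames(X), center = ctr, scale = scl,
      classes = cellClassLevels(),
      metadata = list(n_per_class = as.list(tab), seed = as.integer(seed),
                      cost = cost, gamma = gamma))
}

.featureMatrix <- function(features) {
  features <- as.data.frame(features)
  keep <- intersect(nucleusFeatureNames(), names(features))
  if (length(keep) == 0) {
    X <- as.matrix(features)
  } else {
    X <- as.matrix(features[, keep, drop = FALSE])
  }
  if (any(!is.finite(X))) stop("features must be finite")
  X
}

#' Classify segmented nuclei
#'
#' Applies the stored standardization and the fitted SVM; returns one label
#' per input row, in order. Deterministic.
#'
#' @param clf a [TrainedCellClassifier-class].
#' @param features feature `data.frame`/matrix with the training feature
#'   columns.
#' @return character vector of class labels (empty input gives an empty
#'   vector).
#' @export
classifyCells <- function(clf, features) {
  stopifnot(is(clf, "TrainedCellClassifier"))
  if (NROW(features) == 0L) return(character())
  X <- .featureMatrix(features)
  if (!identical(colnames(X), clf@feature_names)) {
    if (!all(clf@feature_names %in% colnames(X)))
      stop("feature columns do not match the trained classifier")
    X <- X[, clf@feature_names, drop = FALSE]
  }
  Xs <- scale(X, center = clf@center, scale = clf@scale)
  as.character(predict(clf@model, Xs))
}

#' Serialize a trained classifier to a single versioned file
#'
#' The file embeds the fitted SVM, the feature standardization constants
#' and the training metadata, with a format version for forward
#' compatibility.
#'
#' @param clf a [TrainedCellClassifier-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClassifier <- function(clf, path) {
  stopifnot(is(clf, "TrainedCellClassifier"))
  saveRDS(list(format = "TILDensity-classifier", version = 1L,
               classifier = clf), path)
  invisible(path)
}

#' @rdname writeClassifier
#' @return `readClassifier`: the restored
#'   [TrainedCellClassifier-class].
#' @export
readClassifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "TILDensity-classifier"))
    stop("not a serialized TILDensity classifier")
  validObject(obj$classifier)
  obj$classifier
}

#' Build a labelled training set from the synthetic generator
#'
#' Renders each requested nucleus alone on a small noisy tile, segments
#' the tile with the production segmentation chain ([detectNuclei()]) and
#' extracts the features of the detected object, labelling it with the
#' true class. Training examples therefore come from the same measurement
#' process as the objects classified later. Equal per-class counts; rare
#' tiles where segmentation fails are redrawn.
#'
#' @param n_per_class objects per class.
#' @param config a [SyntheticConfig-class] providing morphology, pixel
#'   size and noise level (intensities are ignored).
#' @param seed random seed for the nucleus draws.
#' @return list with `features` (`data.frame`) and `labels` (character).
#' @export
makeTrainingSet <- function(n_per_class = 1000, config = syntheticConfig(),
                            seed = 1L) {
  set.seed(seed)
  tile_um <- 30
  mpp <- config@render_pixel_size_um
  sparams <- segmentationParams(mpp)
  classes <- cellClassLevels()
  total <- n_per_class * length(classes)
  feats <- matrix(NA_real_, total, length(nucleusFeatureNames()))
  labels <- character(total)
  row <- 0L
  tile <- 0L
  for (cl in classes) {
    rmv <- config@nucleus_radius_um[[cl]]
    app <- .classAppearance[[cl]]
    got <- 0L
    while (got < n_per_class) {
      tile <- tile + 1L
      radius <- .truncNorm(1, rmv[1], rmv[2], lower = 0.5)
      ratio <- runif(1, app$ratio[1], app$ratio[2])
      theta <- runif(1, 0, pi)
      cells <- data.frame(cell_id = 1L, x_um = tile_um / 2,
                          y_um = tile_um / 2, class = cl,
                          radius_um = radius, axis_ratio = ratio,
                          theta = theta)
      cfg <- initialize(config, field_width_um = tile_um,
                        field_height_um = tile_um,
                        seed = as.integer(seed + tile))
      slide <- new("GroundTruthSlide", cells = cells, image = NULL,
                   config = cfg)
      slide <- renderSlide(slide, cfg)
      st <- separateStains(slideImage(slide))
      nuc <- detectNuclei(st$haematoxylin, sparams)
      obj <- nucleusTable(nuc)
      if (!nrow(obj)) next  # failed tile: redraw
      ## the object closest to the tile centre
      id <- obj$nucleus_id[which.min((obj$x_um - tile_um / 2)^2 +
                                       (obj$y_um - tile_um / 2)^2)]
      idx <- which(nuc@labels == id)
      H <- nrow(nuc@labels)
      row <- row + 1L
      got <- got + 1L
      feats[row, ] <- extractFeatures((idx - 1L) %% H + 1L,
                                      (idx - 1L) %/% H + 1L,
                                      st$haematoxylin, mpp)
      labels[row] <- cl
    }
  }
  features <- as.data.frame(feats)
  names(features) <- nucleusFeatureNames()
  list(features = features, labels = labels)
}
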