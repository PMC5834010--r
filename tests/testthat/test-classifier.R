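# brute-force one-vs-one RBF decision function, written against the libsvm
# model layout (support vectors, dual coefficients, rho, per-class counts)
bruteForceSvmPredict <- function(clf, X) {
  model <- clf@model
  Xs <- scale(X, center = clf@center, scale = clf@scale)
  SV <- model$SV
  coefs <- model$coefs
  rho <- model$rho
  nSV <- model$nSV
  labs <- model$labels
  gamma <- model$gamma
  nclass <- length(labs)
  start <- c(0, cumsum(nSV))
  kern <- function(x, s) exp(-gamma * sum((x - s)^2))
  apply(Xs, 1, function(x) {
    K <- apply(SV, 1, kern, x = x)
    votes <- integer(nclass)
    p <- 0
    for (i in seq_len(nclass - 1)) {
      for (j in (i + 1):nclass) {
        p <- p + 1
        si <- start[i] + seq_len(nSV[i])
        sj <- start[j] + seq_len(nSV[j])
        dec <- sum(coefs[si, j - 1] * K[si]) +
          sum(coefs[sj, i] * K[sj]) - rho[p]
        if (dec > 0) votes[i] <- votes[i] + 1 else votes[j] <- votes[j] + 1
      }
    }
    model$levels[labs[which.max(votes)]]
  })
}

toyFeatures <- function() {
  # three well-separated feature prototypes, replicated per class
  proto <- rbind(cancer = c(115, 0.7, 0.95, 12, 0.45, 0.03, 0.7),
                 stromal = c(52, 0.95, 0.90, 8, 0.35, 0.03, 0.31),
                 lymphocyte = c(25, 0.3, 0.93, 5.6, 1.0, 0.08, 0.92))
  X <- proto[rep(1:3, each = 5), ]
  colnames(X) <- nucleusFeatureNames()
  list(features = as.data.frame(X),
       labels = rep(rownames(proto), each = 5))
}

test_that("a separable toy set is fitted perfectly; contracts enforced", {
  toy <- toyFeatures()
  clf <- trainCellClassifier(toy$features, toy$labels)
  expect_identical(classifyCells(clf, toy$features), toy$labels)

  expect_error(trainCellClassifier(toy$features,
                                   rep(c("cancer", "stromal"),
                                       length.out = 15)),
               "absent")
  expect_error(trainCellClassifier(toy$features, toy$labels[1:3]),
               "one label per")
  expect_identical(classifyCells(clf, toy$features[0, ]), character())
  expect_error(classifyCells(clf, toy$features[, 1:3]), "feature columns")
})

test_that("predictions match a brute-force one-vs-one decision function", {
  ts <- sharedTrainingSet()
  clf <- sharedClassifier()
  idx <- seq(1, nrow(ts$features), by = 7)
  X <- as.matrix(ts$features[idx, nucleusFeatureNames()])
  expect_identical(classifyCells(clf, ts$features[idx, ]),
                   unname(bruteForceSvmPredict(clf, X)))
})

test_that("held-out synthetic nuclei are classified accurately", {
  clf <- sharedClassifier()
  hold <- makeTrainingSet(n_per_class = 100, seed = 1234)
  acc <- mean(classifyCells(clf, hold$features) == hold$labels)
  expect_gte(acc, 0.95)
})

test_that("training order permutation leaves predictions unchanged", {
  toy <- makeTrainingSet(n_per_class = 60, seed = 6)
  hold <- makeTrainingSet(n_per_class = 40, seed = 7)
  clf1 <- trainCellClassifier(toy$features, toy$labels)
  set.seed(99)
  perm <- sample(nrow(toy$features))
  clf2 <- trainCellClassifier(toy$features[perm, ], toy$labels[perm])
  expect_identical(classifyCells(clf1, hold$features),
                   classifyCells(clf2, hold$features))
})

test_that("feature scaling before standardization does not change predictions", {
  toy <- makeTrainingSet(n_per_class = 60, seed = 6)
  hold <- makeTrainingSet(n_per_class = 40, seed = 7)
  clf1 <- trainCellClassifier(toy$features, toy$labels)
  scaled <- toy$features
  scaled$area_um2 <- scaled$area_um2 * 1000
  holds <- hold$features
  holds$area_um2 <- holds$area_um2 * 1000
  clf2 <- trainCellClassifier(scaled, toy$labels)
  expect_identical(classifyCells(clf1, hold$features),
                   classifyCells(clf2, holds))
})

test_that("classifiers round-trip through the versioned model file", {
  toy <- toyFeatures()
  clf <- trainCellClassifier(toy$features, toy$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  writeClassifier(clf, path)
  clf2 <- readClassifier(path)
  expect_identical(classifyCells(clf2, toy$features),
                   classifyCells(clf, toy$features))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(readClassifier(bad), "not a serialized")
})

test_that("whole-slide classification is diagonal-dominant on isolated nuclei", {
  clf <- sharedClassifier()
  cfg <- syntheticConfig(field_width_um = 400, field_height_um = 400,
                         seed = 11)
  slide <- renderSlide(simulatePointPattern(cfg))
  st <- separateStains(slideImage(slide))
  nuc <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  pred <- classifyCells(clf, extractAllFeatures(nuc, st$haematoxylin))
  truth <- cellPoints(slide)
  iso <- isolatedNuclei(truth)
  m <- matchNuclei(nucleusTable(nuc), truth, tol_radii = 1)
  use <- !is.na(m) & iso[replace(m, is.na(m), 1L)]
  cm <- table(truth = truth$class[m[use]],
              pred = factor(pred[use], levels = cellClassLevels()))
  recall <- diag(cm[cellClassLevels(), cellClassLevels()]) /
    rowSums(cm[cellClassLevels(), ])
  expect_true(all(recall >= 0.9))
})
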