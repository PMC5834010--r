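test_that("stain separation behaves at the boundaries", {
  white <- array(1, dim = c(8, 8, 3))
  st <- separateStains(white)
  expect_lt(max(st$haematoxylin), 1e-8)
  expect_lt(max(st$eosin), 1e-8)

  black <- array(0, dim = c(8, 8, 3))
  stb <- separateStains(black)
  expect_true(all(is.finite(stb$haematoxylin)))
  expect_true(all(is.finite(stb$eosin)))

  expect_error(separateStains(matrix(1, 8, 8)), "RGB")
  expect_error(separateStains(array(1, dim = c(8, 8, 4))), "RGB")
})

test_that("nucleus pixels dominate background in the haematoxylin channel", {
  slide <- nonOverlappingSlide(seed = 5, field_um = 300)
  slide <- renderSlide(slide)
  st <- separateStains(slideImage(slide))
  lab <- rasterizeGroundTruth(slide)
  bg_q99 <- quantile(st$haematoxylin[lab == 0], 0.99)
  cl <- cellPoints(slide)
  above <- vapply(cl$cell_id, function(id) {
    median(st$haematoxylin[lab == id]) > bg_q99
  }, logical(1))
  expect_gte(mean(above), 0.99)
})

test_that("a blank image yields zero nuclei, not an error", {
  cfg <- syntheticConfig(field_width_um = 100, field_height_um = 100,
                         lymphocyte_intensity = 0, cancer_intensity = 0,
                         stromal_intensity = 0, seed = 3)
  slide <- renderSlide(simulatePointPattern(cfg))
  st <- separateStains(slideImage(slide))
  nuc <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  expect_identical(nrow(nucleusTable(nuc)), 0L)
})

test_that("segmentation parameters are validated", {
  expect_error(segmentationParams(), "microns_per_pixel")
  expect_error(segmentationParams(0), "microns_per_pixel")
  expect_error(segmentationParams(0.5, min_area_um2 = 250,
                                  max_area_um2 = 8), "min_area_um2")
})

test_that("non-overlapping nuclei are recovered with sub-radius centroid error", {
  slide <- nonOverlappingSlide(seed = 21)
  slide <- renderSlide(slide)
  st <- separateStains(slideImage(slide))
  nuc <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  det <- nucleusTable(nuc)
  truth <- cellPoints(slide)
  m <- matchNuclei(det, truth, tol_radii = 1)
  recall <- sum(!is.na(m)) / nrow(truth)
  precision <- sum(!is.na(m)) / nrow(det)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  err <- sqrt((det$x_um - truth$x_um[m])^2 + (det$y_um - truth$y_um[m])^2)
  expect_true(all(err < truth$radius_um[m], na.rm = TRUE))
})

test_that("watershed splits two modestly overlapping nuclei", {
  r <- 4
  cells <- data.frame(cell_id = 1:2, x_um = c(20, 20 + 1.75 * r),
                      y_um = c(20, 20), class = "cancer",
                      radius_um = r, axis_ratio = 1, theta = 0)
  cfg <- syntheticConfig(field_width_um = 50, field_height_um = 40, seed = 2)
  sl <- new("GroundTruthSlide", cells = cells, image = NULL, config = cfg)
  sl <- renderSlide(sl, cfg)
  st <- separateStains(slideImage(sl))
  nuc <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  expect_identical(nrow(nucleusTable(nuc)), 2L)
})

test_that("segmentation is deterministic with disjoint, conserved masks", {
  slide <- renderSlide(nonOverlappingSlide(seed = 13, field_um = 250))
  st <- separateStains(slideImage(slide))
  n1 <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  n2 <- detectNuclei(st$haematoxylin, segmentationParams(0.5))
  expect_identical(nucleusTable(n1), nucleusTable(n2))
  expect_identical(n1@labels, n2@labels)
  # one label per pixel by construction; total mask area <= image area
  expect_lte(sum(n1@labels > 0), length(n1@labels))
  # every reported area equals its mask's pixel count
  npx <- table(n1@labels[n1@labels > 0])
  expect_equal(nucleusTable(n1)$area_um2,
               as.numeric(npx[as.character(nucleusTable(n1)$nucleus_id)]) *
                 0.25, tolerance = 1e-12)
})

test_that("raising the minimum-area filter never increases the count", {
  slide <- renderSlide(nonOverlappingSlide(seed = 17, field_um = 250))
  st <- separateStains(slideImage(slide))
  counts <- vapply(c(5, 10, 20, 40, 80, 120), function(amin) {
    nrow(nucleusTable(detectNuclei(st$haematoxylin,
                                   segmentationParams(0.5,
                                                      min_area_um2 = amin))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
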