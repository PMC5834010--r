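test_that("knnMeanDistance reproduces closed-form cases and contracts", {
  expect_equal(knnMeanDistance(rbind(c(0, 0), c(3, 0)), 1, 1), 3)
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(knnMeanDistance(sq, 1, 3), (1 + 1 + sqrt(2)) / 3,
               tolerance = 1e-12)
  expect_error(knnMeanDistance(sq, 1, 4), "k must be")
  expect_error(knnMeanDistance(sq, 5, 2), "index")
  expect_error(knnMeanDistance(rbind(c(0, 0)), 1, 1), "at least 2")
})

test_that("grid-accelerated KNN equals the all-pairs brute force", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(52:500, 1)
    k <- sample(c(1, 5, 50, n - 1), 1)
    pts <- cbind(runif(n, 0, 2000), runif(n, 0, 1500))
    impl <- vapply(seq_len(n),
                   function(i) knnMeanDistance(pts, i, k), numeric(1))
    s <- lymphocyteDensity(pts, n_target = k, keep_densities = TRUE)
    oracle <- bruteForceKnnMean(pts, k)
    expect_equal(impl, oracle, tolerance = 1e-9)
    expect_equal(s@per_lymphocyte_densities, k / (pi * oracle^2),
                 tolerance = 1e-9)
  }
})

test_that("density summary implements N/(pi R^2) with the median rule", {
  # two points 1 um apart: k_used = 1, each density 1/pi
  s <- lymphocyteDensity(rbind(c(0, 0), c(1, 0)))
  expect_identical(kUsed(s), 1L)
  expect_equal(medianDensity(s), 1 / pi, tolerance = 1e-12)

  # single lymphocyte: summary missing, count retained
  s1 <- lymphocyteDensity(rbind(c(5, 5)))
  expect_identical(nLymphocytes(s1), 1L)
  expect_true(is.na(medianDensity(s1)))
  expect_true(is.na(kUsed(s1)))

  # sparse slide: k truncated to n - 1
  set.seed(2)
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  s20 <- lymphocyteDensity(pts, n_target = 50)
  expect_identical(kUsed(s20), 19L)

  # even count: median is the mean of the two central order statistics
  pts4 <- rbind(c(0, 0), c(1, 0), c(10, 0), c(14, 0))
  s4 <- lymphocyteDensity(pts4, n_target = 1, keep_densities = TRUE)
  d <- s4@per_lymphocyte_densities
  expect_equal(medianDensity(s4), mean(sort(d)[2:3]), tolerance = 1e-12)
})

test_that("duplicate coordinates are excluded from the median with a warning", {
  pts <- rbind(c(0, 0), c(0, 0), c(3, 0), c(4, 0))
  expect_warning(s <- lymphocyteDensity(pts, n_target = 1,
                                        keep_densities = TRUE),
                 "duplicated")
  expect_identical(sum(is.na(s@per_lymphocyte_densities)), 2L)
  expect_equal(medianDensity(s), 1 / pi, tolerance = 1e-12)
})

test_that("density change tracks delta and log-ratio with missing propagation", {
  mk <- function(med, n = 100L, pid = "P1") new("SlideDensitySummary",
    slide_id = "s", patient_id = pid, n_lymphocytes = n,
    k_used = min(50L, n - 1L), median_density = med,
    per_lymphocyte_densities = NULL)
  dc <- densityChange(mk(0.2), mk(0.2))
  expect_equal(dc@delta, 0)
  dc2 <- densityChange(mk(0.1), mk(0.4))
  expect_equal(dc2@delta, 0.3, tolerance = 1e-12)
  expect_equal(dc2@log_ratio, log(4), tolerance = 1e-12)
  dc3 <- densityChange(mk(NA_real_, n = 1L), mk(0.4))
  expect_true(is.na(dc3@delta) && is.na(dc3@log_ratio))
  expect_error(densityChange(mk(0.1, pid = "P1"), mk(0.2, pid = "P2")),
               "different patients")
})

test_that("unit-interval rescaling follows the documented conventions", {
  expect_equal(rescaleUnitInterval(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(rescaleUnitInterval(c(5, 5, 5)), c(0, 0, 0))
  expect_error(rescaleUnitInterval(numeric()), "non-missing")
  expect_error(rescaleUnitInterval(c(NA_real_, NA_real_)), "non-missing")
  set.seed(3)
  x <- rnorm(50)
  r <- rescaleUnitInterval(x)
  expect_equal(range(r), c(0, 1))
  expect_identical(order(r), order(x))
  x[7] <- NA
  expect_true(is.na(rescaleUnitInterval(x)[7]))
})

test_that("densities are rigid-motion invariant and scale as 1/c^2", {
  set.seed(4)
  pts <- cbind(runif(300, 0, 800), runif(300, 0, 800))
  base <- lymphocyteDensity(pts, keep_densities = TRUE)

  th <- 0.62
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(pts %*% t(R), 2, c(250, -90), "+")
  rot <- lymphocyteDensity(moved, keep_densities = TRUE)
  expect_equal(rot@per_lymphocyte_densities,
               base@per_lymphocyte_densities, tolerance = 1e-9)
  expect_equal(medianDensity(rot), medianDensity(base), tolerance = 1e-9)

  for (c_scale in c(0.5, 3)) {
    sc <- lymphocyteDensity(pts * c_scale, keep_densities = TRUE)
    expect_equal(sc@per_lymphocyte_densities,
                 base@per_lymphocyte_densities / c_scale^2,
                 tolerance = 1e-9)
  }
})

test_that("the Poisson calibration constant holds: median summary ~ 2.07 lambda", {
  # regression pin: for lambda = 400 / mm^2 on a 1.5 x 1.5 mm field with
  # N = 50, the mean median-summary over replicates is ~2.07 * lambda
  # (edge effects keep it below the unbounded-plane constant ~2.21)
  set.seed(11)
  lam <- 400
  med <- replicate(20, {
    n <- rpois(1, lam * 2.25)
    medianDensity(lymphocyteDensity(cbind(runif(n, 0, 1500),
                                          runif(n, 0, 1500))))
  })
  expect_equal(mean(med) / (lam / 1e6), 2.07, tolerance = 0.08)
})

test_that("cell maps route their lymphocytes into the summary", {
  pts <- data.frame(x_um = c(1, 2, 3, 50), y_um = c(1, 2, 3, 50),
                    class = c("lymphocyte", "lymphocyte", "cancer",
                              "lymphocyte"))
  cm <- cellMap("s9", pts, 100, 100)
  s <- lymphocyteDensity(cm, n_target = 2)
  expect_identical(nLymphocytes(s), 3L)
  expect_identical(s@slide_id, "s9")
})
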