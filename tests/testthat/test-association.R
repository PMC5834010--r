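table2x2Cohort <- function(a, b, c, d) {
  # exposed: a events / b non-events; unexposed: c events / d non-events
  data.frame(pcr = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
             exposed = c(rep("yes", a + b), rep("no", c + d)))
}

test_that("a single binary covariate recovers the cross-product odds ratio", {
  co <- table2x2Cohort(10, 20, 5, 40)
  co$exposed <- factor(co$exposed, levels = c("no", "yes"))
  fit <- fitLogistic(co, "exposed")
  tab <- fitTable(fit)
  expect_equal(tab$or[tab$term == "exposedyes"], 4.0, tolerance = 1e-6)
  expect_identical(fit@n, 75L)
})

test_that("degenerate outcomes and separation are flagged, not reported", {
  co <- table2x2Cohort(0, 30, 0, 45)   # no events at all
  fit <- fitLogistic(co, "exposed")
  expect_false(fit@converged)
  expect_identical(nrow(fitTable(fit)), 0L)

  sep <- data.frame(pcr = c(rep(0, 30), rep(1, 30)),
                    x = c(rnorm(30, -4), rnorm(30, 4)))
  fit2 <- fitLogistic(sep, "x")
  expect_false(fit2@converged)
  expect_error(formatFitTable(fit2), "non-converged")
})

test_that("report rows render ratios and CIs to two decimals", {
  mk <- function(est, lo, hi) {
    se <- (hi - lo) / (2 * 1.96)
    new("LogisticFit",
        table = data.frame(term = "density", estimate = est, se = se,
                           or = exp(est), ci_lo = exp(lo), ci_hi = exp(hi),
                           p = 2 * pnorm(-abs(est / se))),
        n = 609L, converged = TRUE, outcome = "pcr")
  }
  r1 <- formatFitTable(mk(log(2.93), log(1.77), log(4.85)))
  expect_identical(r1$estimate, "2.93")
  expect_identical(r1$ci_95, "1.77–4.85")
  r2 <- formatFitTable(mk(0, -0.5, 0.5))
  expect_identical(r2$estimate, "1.00")
  r3 <- formatFitTable(mk(log(0.10), log(0.033), log(0.31)))
  expect_identical(r3$estimate, "0.10")
  expect_identical(r3$ci_95, "0.03–0.31")
})

test_that("complete-case deletion reports per-model n", {
  co <- simulateCohort(cohortConfig(n_patients = 1000, seed = 14))
  co$grade[1:100] <- NA
  f_uni <- fitLogistic(co, "pre_density")
  f_grade <- fitLogistic(co, c("pre_density", "grade"))
  expect_identical(f_uni@n, 1000L)
  expect_identical(f_grade@n, 900L)
})

test_that("binary recoding inverts the odds ratio exactly", {
  co <- table2x2Cohort(12, 18, 7, 33)
  co$exposed <- factor(co$exposed, levels = c("no", "yes"))
  or1 <- fitTable(fitLogistic(co, "exposed"))
  co$exposed <- factor(as.character(co$exposed), levels = c("yes", "no"))
  or2 <- fitTable(fitLogistic(co, "exposed"))
  expect_equal(or1$or[or1$term == "exposedyes"],
               1 / or2$or[or2$term == "exposedno"], tolerance = 1e-8)
})

test_that("rescaling density rescales its coefficient by 1/c", {
  co <- simulateCohort(cohortConfig(n_patients = 5000, seed = 15))
  b1 <- fitTable(fitLogistic(co, "pre_density"))
  co$pre_density_x10 <- co$pre_density * 10
  b2 <- fitTable(fitLogistic(co, "pre_density_x10"))
  expect_equal(b1$estimate[2], 10 * b2$estimate[2], tolerance = 1e-6)
})

test_that("Kruskal-Wallis reproduces the hand-ranked example and contracts", {
  kw <- kruskalWallis(1:9, rep(1:3, each = 3))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_identical(kw$df, 2L)

  expect_equal(kruskalWallis(rep(4.2, 12), rep(1:3, each = 4))$H, 0)
  expect_error(kruskalWallis(1:5, rep(1, 5)), "two non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank sum", {
  set.seed(8)
  x <- c(rnorm(12), rnorm(15, 0.8))
  g <- rep(1:2, c(12, 15))
  kw <- kruskalWallis(x, g)
  # Wilcoxon rank-sum z without continuity correction
  r <- rank(x)
  n1 <- 12; n2 <- 15; n <- n1 + n2
  W <- sum(r[g == 1])
  z <- (W - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rlnorm(60)
  g <- rep(1:3, each = 20)
  expect_equal(kruskalWallis(x, g)$H, kruskalWallis(exp(x), g)$H,
               tolerance = 1e-12)
  expect_equal(kruskalWallis(x, g)$H, kruskalWallis(rank(x), g)$H,
               tolerance = 1e-12)
})

test_that("Cox fits are null-calibrated and recover a known hazard ratio", {
  set.seed(16)
  n <- 2000
  arm <- factor(sample(c("BEV+D FEC", "D FEC"), n, TRUE),
                levels = c("BEV+D FEC", "D FEC"))
  tt <- rexp(n, 0.2)           # identical hazards in both arms
  cc <- rexp(n, 0.1)
  df <- data.frame(os_time = pmin(tt, cc), os_event = as.integer(tt <= cc),
                   arm = arm)
  tab <- fitTable(fitCox(df, "OS", terms = "arm"))
  expect_lt(abs(tab$estimate[1]), 3 * tab$se[1])

  set.seed(17)
  x <- rbinom(5000, 1, 0.5)
  tt <- rexp(5000, 0.2 * exp(log(2) * x))
  cc <- rexp(5000, 0.13)
  df2 <- data.frame(os_time = pmin(tt, cc),
                    os_event = as.integer(tt <= cc),
                    node_status = factor(ifelse(x == 1, "Positive",
                                                "Negative"),
                                         levels = c("Negative", "Positive")))
  tab2 <- fitTable(fitCox(df2, "OS", terms = "node_status"))
  expect_lte(tab2$ci_lo[1], 2)
  expect_gte(tab2$ci_hi[1], 2)
})

test_that("Cox estimates are invariant to a common time rescaling", {
  co <- simulateCohort(cohortConfig(n_patients = 3000, seed = 18))
  t1 <- fitTable(fitCox(co, "OS", stratum = "Negative",
                        terms = "node_status"))
  co$os_time <- co$os_time * 365.25
  t2 <- fitTable(fitCox(co, "OS", stratum = "Negative",
                        terms = "node_status"))
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-8)
})

test_that("Cox contracts: strata, events and time positivity", {
  co <- simulateCohort(cohortConfig(n_patients = 400, seed = 19))
  expect_error(fitCox(co[1, ], "OS", terms = "node_status"), "too small")
  co0 <- co
  co0$os_event <- 0L
  expect_error(fitCox(co0, "OS", terms = "node_status"), "no events")
  cot <- co
  cot$os_time[3] <- 0
  expect_error(fitCox(cot, "OS", terms = "node_status"), "positive")
  fit <- fitCox(co, "DFS", stratum = "Positive", terms = "node_status")
  expect_identical(fit@stratum, "Positive")
  expect_identical(fit@endpoint, "DFS")
  expect_identical(fit@n_events,
                   sum(co$dfs_event[co$er_status == "Positive"]))
})
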