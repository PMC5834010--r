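## Synthetic trial cohorts: covariates, a logistic pCR outcome model,
## exponential survival with independent censoring, and a two-component
## pre-to-post density-change model tied to residual disease.

#' Create a cohort generator configuration
#'
#' Default effect sizes place pCR under a logistic model in pre-treatment
#' lymphocyte density (odds ratio `exp(beta_density)` per a.u.) with the
#' usual clinical covariates as confounders (age and grade continuous; ER
#' status, nodal status, tumour-size category and treatment arm binary,
#' first level = reference). Survival is exponential from surgery with
#' independent exponential censoring capped at ~6 years of follow-up.
#' Post-treatment density change follows a two-component scheme in which
#' patients with residual disease have a configurable probability of a
#' positive density shift.
#'
#' @param n_patients cohort size.
#' @param intercept logistic intercept (log-odds).
#' @param beta_density log-odds of pCR per unit (a.u.) pre-treatment
#'   density.
#' @param beta_covariates named log-odds: continuous terms per unit, binary
#'   terms for the non-reference level.
#' @param covariate_distributions named list of specs; supported `dist`
#'   values: `"normal"` (mean, sd, optional min/max truncation),
#'   `"lognormal"` (meanlog, sdlog), `"categorical"` (levels, probs),
#'   `"bernoulli"` (p, levels = c(reference, other)).
#' @param delta_density_model list: `matched_fraction` (share of patients
#'   with a post-treatment slide), `p_increase_rd` / `p_increase_pcr`
#'   (probability of the positive-shift component given residual disease /
#'   pCR), `increase_mean`, `increase_sd`, `base_mean`, `base_sd` (a.u.).
#' @param survival_baseline_rate,relapse_baseline_rate,censoring_rate
#'   exponential rates, events per year.
#' @param log_hazards named log-hazard effects applied to both death and
#'   relapse rates.
#' @param seed random seed.
#' @return A [CohortConfig-class].
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_patients = 500, seed = 3))
#' mean(cohort$pcr)
#' @export
cohortConfig <- function(n_patients = 609,
                         intercept = -2.2,
                         beta_density = log(2.13),
                         beta_covariates = c(
                           age = log(0.98),
                           grade = log(2.80),
                           er_status = log(0.29),
                           node_status = log(0.65),
                           tumour_size_cat = log(1.05),
                           arm = log(0.60)),
                         covariate_distributions = list(
                           age = list(dist = "normal", mean = 50, sd = 10,
                                      min = 25, max = 80),
                           grade = list(dist = "categorical",
                                        levels = c(1, 2, 3),
                                        probs = c(0.10, 0.45, 0.45)),
                           er_status = list(dist = "bernoulli", p = 0.60,
                                            levels = c("Negative", "Positive")),
                           node_status = list(dist = "bernoulli", p = 0.45,
                                              levels = c("Negative", "Positive")),
                           tumour_size_cat = list(dist = "bernoulli", p = 0.15,
                                                  levels = c("<=50 mm", ">50 mm")),
                           arm = list(dist = "bernoulli", p = 0.50,
                                      levels = c("BEV+D FEC", "D FEC")),
                           pre_density = list(dist = "lognormal",
                                              meanlog = -0.7, sdlog = 0.6)),
                         delta_density_model = list(
                           matched_fraction = 0.63,
                           p_increase_rd = 0.40, p_increase_pcr = 0.05,
                           increase_mean = 0.30, increase_sd = 0.10,
                           base_mean = -0.08, base_sd = 0.10),
                         survival_baseline_rate = 0.05,
                         relapse_baseline_rate = 0.08,
                         censoring_rate = 0.15,
                         log_hazards = c(er_status = log(0.7),
                                         node_status = log(1.6)),
                         seed = 1L) {
  new("CohortConfig",
      n_patients = as.integer(n_patients), intercept = intercept,
      beta_density = beta_density, beta_covariates = beta_covariates,
      covariate_distributions = covariate_distributions,
      delta_density_model = delta_density_model,
      survival_baseline_rate = survival_baseline_rate,
      relapse_baseline_rate = relapse_baseline_rate,
      censoring_rate = censoring_rate, log_hazards = log_hazards,
      seed = as.integer(seed))
}

.drawCovariate <- function(spec, n) {
  switch(spec$dist,
    normal = {
      x <- rnorm(n, spec$mean, spec$sd)
      if (!is.null(spec$min)) x <- pmax(x, spec$min)
      if (!is.null(spec$max)) x <- pmin(x, spec$max)
      x
    },
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    bernoulli = {
      lev <- if (is.null(spec$levels)) c("0", "1") else spec$levels
      factor(lev[1L + rbinom(n, 1, spec$p)], levels = lev)
    },
    stop(sprintf("unknown distribution '%s'", spec$dist))
  )
}

## numeric coding used in the linear predictor: binary factors -> 0/1
## indicator of the non-reference level; everything else as numeric
.numericCoding <- function(x) {
  if (is.factor(x)) as.numeric(x) - 1 else as.numeric(x)
}

#' Simulate a trial cohort
#'
#' Covariates are drawn from the configured distributions; pCR follows
#' `Bernoulli(plogis(intercept + beta_density * pre_density + sum(beta_j *
#' x_j)))`; death and relapse times are exponential with rates scaled by
#' `exp(log-hazards)`, censoring is independent exponential (administrative
#' cap at 6.3 years); post-treatment density is drawn for the matched
#' subset so that residual-disease patients have elevated probability of a
#' density increase. The draw is fully determined by the config seed.
#'
#' @param config a [CohortConfig-class].
#' @return `data.frame`, one patient per row, with columns `patient_id`,
#'   the covariates, `pre_density`, `pcr`, `has_baseline`, `has_post`,
#'   `post_density`, `delta_density`, `os_time`, `os_event`, `dfs_time`,
#'   `dfs_event`.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@n_patients
  cov <- lapply(config@covariate_distributions, .drawCovariate, n = n)
  cohort <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
  for (nm in names(cov)) cohort[[nm]] <- cov[[nm]]
  if (is.null(cohort$pre_density))
    stop("covariate_distributions must include pre_density")

  lp <- rep(config@intercept, n) +
    config@beta_density * cohort$pre_density
  for (nm in names(config@beta_covariates)) {
    if (is.null(cohort[[nm]]))
      stop(sprintf("beta_covariates names '%s' but it has no distribution", nm))
    lp <- lp + config@beta_covariates[[nm]] * .numericCoding(cohort[[nm]])
  }
  cohort$pcr <- rbinom(n, 1, plogis(lp))

  ## survival from surgery: exponential death/relapse, independent censoring
  lh <- rep(0, n)
  for (nm in names(config@log_hazards)) {
    if (!is.null(cohort[[nm]]))
      lh <- lh + config@log_hazards[[nm]] * .numericCoding(cohort[[nm]])
  }
  t_death <- rexp(n, config@survival_baseline_rate * exp(lh))
  t_relapse <- rexp(n, config@relapse_baseline_rate * exp(lh))
  t_cens <- pmin(rexp(n, config@censoring_rate), 6.3)
  cohort$os_time <- pmin(t_death, t_cens)
  cohort$os_event <- as.integer(t_death <= t_cens)
  t_dfs <- pmin(t_relapse, t_death)
  cohort$dfs_time <- pmin(t_dfs, t_cens)
  cohort$dfs_event <- as.integer(t_dfs <= t_cens)

  ## matched pre/post subset and the density-change model
  dm <- config@delta_density_model
  cohort$has_baseline <- TRUE
  cohort$has_post <- runif(n) < dm$matched_fraction
  p_inc <- ifelse(cohort$pcr == 1, dm$p_increase_pcr, dm$p_increase_rd)
  inc <- runif(n) < p_inc
  delta <- ifelse(inc,
                  abs(rnorm(n, dm$increase_mean, dm$increase_sd)),
                  rnorm(n, dm$base_mean, dm$base_sd))
  delta[!cohort$has_post] <- NA_real_
  cohort$post_density <- pmax(cohort$pre_density + delta, 0.01)
  cohort$delta_density <- cohort$post_density - cohort$pre_density
  cohort
}
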