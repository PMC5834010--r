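## Association analyses: logistic regression of pCR on lymphocyte density
## and clinical covariates, Kruskal-Wallis covariate tests, and
## ER-stratified Cox proportional-hazards models for OS/DFS.

## coerce the clinical covariates to factors with the canonical reference
## (first) levels; unknown character columns get first-appearance order
.codeCovariates <- function(df, terms) {
  for (nm in terms) {
    v <- df[[nm]]
    if (is.null(v)) stop(sprintf("cohort has no column '%s'", nm))
    if (nm %in% names(.covariateLevels)) {
      lev <- .covariateLevels[[nm]]
      bad <- setdiff(unique(as.character(v)), c(lev, NA))
      if (length(bad))
        stop(sprintf("column '%s' has unknown level(s): %s", nm,
                     paste(bad, collapse = ", ")))
      df[[nm]] <- factor(as.character(v), levels = lev)
    } else if (is.character(v) || is.logical(v)) {
      df[[nm]] <- factor(v, levels = unique(v[!is.na(v)]))
    }
  }
  df
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a patient-record table: follow-up
#' times non-negative, grade within \[1, 3\], categorical covariates within
#' their closed level sets, pCR and event indicators in \{0, 1\}.
#'
#' @param cohort `data.frame`, one patient per row.
#' @return the cohort, invisibly; errors describe the violations.
#' @export
validateCohort <- function(cohort) {
  msg <- character()
  chk01 <- function(col) {
    v <- cohort[[col]]
    if (!is.null(v) && !all(v %in% c(0, 1, NA)))
      msg <<- c(msg, sprintf("'%s' must be 0/1", col))
  }
  for (col in c("pcr", "os_event", "dfs_event")) chk01(col)
  for (col in c("os_time", "dfs_time")) {
    v <- cohort[[col]]
    if (!is.null(v) && any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("'%s' must be >= 0", col))
  }
  if (!is.null(cohort$grade) &&
      any(cohort$grade < 1 | cohort$grade > 3, na.rm = TRUE))
    msg <- c(msg, "'grade' must lie in [1, 3]")
  for (nm in names(.covariateLevels)) {
    v <- cohort[[nm]]
    if (!is.null(v)) {
      bad <- setdiff(unique(as.character(v)),
                     c(.covariateLevels[[nm]], NA))
      if (length(bad))
        msg <- c(msg, sprintf("'%s' has invalid level(s): %s", nm,
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  invisible(cohort)
}

#' Logistic regression of pCR on density and clinical covariates
#'
#' Maximum-likelihood fit (IRLS, convergence when the deviance change is
#' below 1e-8) on the complete cases of the requested terms; the per-model
#' n is reported. Categorical covariates are coded with the canonical first
#' level as reference (Negative for ER and nodes, `BEV+D FEC` for arm,
#' `<=50 mm` for size). Wald 95% CIs `exp(beta +/- 1.96 se)`. A constant
#' outcome or (quasi-)perfect separation is flagged: the fit is returned
#' with `converged = FALSE` and no odds ratios.
#'
#' @param cohort patient table (see [simulateCohort()]).
#' @param terms character vector of model terms (column names).
#' @param outcome binary outcome column, default `"pcr"`.
#' @return A [LogisticFit-class].
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_patients = 2000, seed = 1))
#' fitLogistic(cohort, "pre_density")
#' @export
fitLogistic <- function(cohort, terms, outcome = "pcr") {
  if (!length(terms)) stop("at least one term required")
  if (is.null(cohort[[outcome]])) stop("outcome column not found")
  df <- .codeCovariates(as.data.frame(cohort), terms)
  df <- df[complete.cases(df[, c(outcome, terms), drop = FALSE]), ,
           drop = FALSE]
  n <- nrow(df)
  if (n == 0L) stop("no complete cases")
  if (n < length(terms) + 1L) stop("fewer complete cases than terms + 1")

  bad_fit <- function() new("LogisticFit",
    table = data.frame(term = character(), estimate = numeric(),
                       se = numeric(), or = numeric(), ci_lo = numeric(),
                       ci_hi = numeric(), p = numeric()),
    n = as.integer(n), converged = FALSE, outcome = outcome)

  if (length(unique(df[[outcome]])) < 2L) return(bad_fit())
  fml <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df,
                              control = list(epsilon = 1e-8, maxit = 100)))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ## quasi-separation: monstrous per-SD effects or exploding Wald errors
  mm <- stats::model.matrix(fit)
  sds <- apply(mm, 2, sd)
  sds["(Intercept)"] <- 0
  if (!fit$converged || any(!is.finite(se)) ||
      any(abs(est * sds) > 15, na.rm = TRUE) ||
      any(se * sds > 100, na.rm = TRUE)) return(bad_fit())
  z <- est / se
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), or = unname(exp(est)),
                    ci_lo = unname(exp(est - 1.96 * se)),
                    ci_hi = unname(exp(est + 1.96 * se)),
                    p = unname(2 * pnorm(-abs(z))))
  new("LogisticFit", table = tab, n = as.integer(n), converged = TRUE,
      outcome = outcome)
}

.fmtP <- function(p) {
  ifelse(p < 1e-5, "<0.00001", formatC(signif(p, 2), format = "fg"))
}

#' Render a fitted model as report rows
#'
#' One row per non-intercept term: odds/hazard ratio to 2 decimal places,
#' the 95% CI as `low-high` (2 dp, en dash), the Wald p-value and the
#' per-model n. Requires a converged fit.
#'
#' @param fit a [LogisticFit-class] or [SurvivalFit-class].
#' @return `data.frame` with character columns `variable`, `estimate`,
#'   `ci_95`, `p`, `n`.
#' @export
formatFitTable <- function(fit) {
  if (is(fit, "LogisticFit") && !fit@converged)
    stop("cannot format a non-converged fit")
  tab <- fitTable(fit)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  ratio <- if ("or" %in% names(tab)) tab$or else tab$hr
  data.frame(variable = tab$term,
             estimate = sprintf("%.2f", ratio),
             ci_95 = sprintf("%.2f–%.2f", tab$ci_lo, tab$ci_hi),
             p = .fmtP(tab$p),
             n = fit@n,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and a chi-square p-value on
#' `groups - 1` degrees of freedom, via [stats::kruskal.test()].
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length, at least two
#'   non-empty groups.
#' @return list with `H`, `p_value` and `df`.
#' @examples
#' kruskalWallis(1:9, rep(1:3, each = 3))  # H = 7.2
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L)  # fully tied: H degenerates to 0
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1L))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' ER-stratified Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling; follow-up runs from
#' surgery. OS is all-cause mortality; DFS is time to first relapse or to
#' death without relapse, censored otherwise. Analyses are run within one
#' ER stratum (`"Positive"` / `"Negative"`) or on the full table
#' (`stratum = "all"`).
#'
#' @param cohort patient table with `os_time`/`os_event` and
#'   `dfs_time`/`dfs_event` columns.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param stratum ER stratum level, or `"all"`.
#' @param terms model terms (column names).
#' @return A [SurvivalFit-class] with hazard ratios and Wald 95% CIs.
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_patients = 1000, seed = 2))
#' fitCox(cohort, "OS", stratum = "Negative", terms = "node_status")
#' @export
fitCox <- function(cohort, endpoint = c("OS", "DFS"), stratum = "all",
                   terms) {
  endpoint <- match.arg(endpoint)
  if (!length(terms)) stop("at least one term required")
  df <- as.data.frame(cohort)
  if (!identical(stratum, "all")) {
    if (is.null(df$er_status)) stop("er_status column required for strata")
    df <- df[!is.na(df$er_status) & df$er_status == stratum, , drop = FALSE]
  }
  tcol <- if (endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "dfs_event"
  df <- .codeCovariates(df, terms)
  df <- df[complete.cases(df[, c(tcol, ecol, terms), drop = FALSE]), ,
           drop = FALSE]
  if (nrow(df) < 2L) stop("stratum subset too small to fit")
  if (any(df[[tcol]] <= 0)) stop("follow-up times must be positive")
  nev <- sum(df[[ecol]])
  if (nev < 1L) stop("no events in the stratum subset")

  fml <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", tcol, ecol,
                            paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), hr = unname(exp(est)),
                    ci_lo = unname(exp(est - 1.96 * se)),
                    ci_hi = unname(exp(est + 1.96 * se)),
                    p = unname(2 * pnorm(-abs(z))))
  new("SurvivalFit", table = tab, n = as.integer(nrow(df)),
      n_events = as.integer(nev), stratum = as.character(stratum),
      endpoint = endpoint)
}
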