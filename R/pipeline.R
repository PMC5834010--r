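## End-to-end orchestration: simulate -> (render/segment/classify) ->
## density -> association, plus cohort accounting and provenance.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], optionally
#' overridden by a YAML file and/or named arguments. `mode
#' = "coordinates"` runs the spatial statistics on ground-truth cell
#' coordinates; `mode = "image"` renders every slide and runs
#' segmentation + classification first. Per-slide lymphocyte intensity is
#' `density_to_intensity` times the patient's density (a.u.), linking the
#' cohort model to the slides.
#'
#' @param path optional YAML file with overrides.
#' @param ... named overrides applied last.
#' @return named list of pipeline parameters. Notable entries:
#'   `density_to_intensity` links a patient's density (a.u.) to the
#'   slide's lymphocyte intensity (per mm^2); `au_scale` converts the
#'   measured summaries (cells/um^2) to reporting units (default 1000,
#'   i.e. 1 a.u. = 1e-3 um^-2) before the association models.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    mode = "coordinates",
    n_patients = 40L,
    field_width_um = 600, field_height_um = 600,
    density_to_intensity = 800,
    cancer_intensity = 250, stromal_intensity = 250,
    n_target = 50L,
    au_scale = 1000,
    n_train_per_class = 150L,
    render_pixel_size_um = 0.5,
    multivariable_terms = c("age", "grade", "er_status", "node_status",
                            "tumour_size_cat", "arm"),
    cohort = list()
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg
}

.log <- function(logfile, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

.slideConfig <- function(cfg, density_au, seed) {
  syntheticConfig(
    field_width_um = cfg$field_width_um,
    field_height_um = cfg$field_height_um,
    lymphocyte_intensity = cfg$density_to_intensity * density_au,
    cancer_intensity = cfg$cancer_intensity,
    stromal_intensity = cfg$stromal_intensity,
    render_pixel_size_um = cfg$render_pixel_size_um,
    seed = seed)
}

## one slide -> CellMap, through ground truth or the full imaging path
.slideCellMap <- function(cfg, density_au, seed, slide_id, clf) {
  scfg <- .slideConfig(cfg, density_au, seed)
  slide <- simulatePointPattern(scfg)
  if (identical(cfg$mode, "coordinates"))
    return(asCellMap(slide, slide_id))
  slide <- renderSlide(slide)
  st <- separateStains(slideImage(slide))
  nuc <- detectNuclei(st$haematoxylin,
                      segmentationParams(cfg$render_pixel_size_um))
  if (!nrow(nucleusTable(nuc)))
    return(cellMap(slide_id,
                   data.frame(x_um = numeric(), y_um = numeric(),
                              class = character()),
                   cfg$field_width_um, cfg$field_height_um))
  feats <- extractAllFeatures(nuc, st$haematoxylin)
  labels <- classifyCells(clf, feats)
  pts <- nucleusTable(nuc)
  cellMap(slide_id,
          data.frame(x_um = pts$x_um, y_um = pts$y_um, class = labels),
          cfg$field_width_um, cfg$field_height_um)
}

#' Run the full pipeline
#'
#' Executes the stages in order -- cohort simulation, per-patient slide
#' simulation (with rendering, segmentation and classification in image
#' mode), per-slide density summaries, density-change computation for the
#' matched subset, association models, and cohort accounting -- writing
#' per-stage CSV outputs and a JSON manifest (config echo, seed, package
#' version, output checksums) into `outdir`. A rerun with the same config
#' is bit-identical for the deterministic stages. When no patient has a
#' post-treatment slide the change-analysis stage is skipped with a logged
#' reason.
#'
#' @param config a list from [pipelineConfig()] or a YAML file path.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the cohort table (including measured
#'   densities), the fitted models, the [CohortFlow-class] and the output
#'   paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir) {
  if (is.character(config)) config <- pipelineConfig(path = config)
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  paths <- list()

  .log(logfile, "stage 1/5: simulating cohort (n = %d, seed = %d)",
       config$n_patients, config$seed)
  ccfg_args <- c(list(n_patients = config$n_patients, seed = config$seed),
                 config$cohort)
  ccfg <- do.call(cohortConfig, ccfg_args)
  cohort <- simulateCohort(ccfg)
  validateCohort(cohort)
  paths$cohort <- file.path(outdir, "cohort.csv")
  write.csv(cohort, paths$cohort, row.names = FALSE)

  clf <- NULL
  if (identical(config$mode, "image")) {
    .log(logfile, "training nucleus classifier (%d per class)",
         config$n_train_per_class)
    ts <- makeTrainingSet(config$n_train_per_class,
                          config = syntheticConfig(
                            render_pixel_size_um = config$render_pixel_size_um),
                          seed = config$seed + 99L)
    clf <- trainCellClassifier(ts$features, ts$labels,
                               seed = config$seed + 99L)
  }

  .log(logfile, "stage 2/5: slides and density summaries (mode = %s)",
       config$mode)
  summaries <- vector("list", 2L * nrow(cohort))
  si <- 0L
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    map <- .slideCellMap(config, cohort$pre_density[i],
                         config$seed + 1000L + i,
                         paste0(pid, "_pre"), clf)
    si <- si + 1L
    summaries[[si]] <- lymphocyteDensity(map, config$n_target,
                                         patient_id = pid)
    if (isTRUE(cohort$has_post[i])) {
      map <- .slideCellMap(config, cohort$post_density[i],
                           config$seed + 200000L + i,
                           paste0(pid, "_post"), clf)
      si <- si + 1L
      summaries[[si]] <- lymphocyteDensity(map, config$n_target,
                                           patient_id = pid)
    }
  }
  summaries <- summaries[seq_len(si)]
  dtab <- densitySummaryTable(summaries)
  paths$density <- file.path(outdir, "density_summaries.csv")
  write.csv(dtab, paths$density, row.names = FALSE)

  pre_tab <- dtab[grepl("_pre$", dtab$slide_id), ]
  post_tab <- dtab[grepl("_post$", dtab$slide_id), ]
  ## measured summaries are in cells/um^2; report in a.u. (default
  ## 1 a.u. = 1e-3 um^-2) so per-unit odds ratios are readable
  cohort$measured_pre_density <- config$au_scale *
    pre_tab$median_density_au[match(cohort$patient_id, pre_tab$patient_id)]
  cohort$measured_post_density <- config$au_scale *
    post_tab$median_density_au[match(cohort$patient_id, post_tab$patient_id)]

  .log(logfile, "stage 3/5: density change for the matched subset")
  any_post <- nrow(post_tab) > 0L
  if (any_post) {
    cohort$measured_delta_density <-
      cohort$measured_post_density - cohort$measured_pre_density
  } else {
    .log(logfile,
         "no post-treatment slides: change-analysis stage skipped")
    cohort$measured_delta_density <- NA_real_
  }
  paths$cohort_measured <- file.path(outdir, "cohort_measured.csv")
  write.csv(cohort, paths$cohort_measured, row.names = FALSE)

  .log(logfile, "stage 4/5: association models")
  try_fit <- function(label, terms) {
    tryCatch(fitLogistic(cohort, terms),
             error = function(e) {
               .log(logfile, "model '%s' skipped: %s", label,
                    conditionMessage(e))
               NULL
             })
  }
  fits <- list()
  fits$uni_pre <- try_fit("uni_pre", "measured_pre_density")
  fits$multi_pre <- try_fit(
    "multi_pre", c("measured_pre_density", config$multivariable_terms))
  if (any_post)
    fits$multi_delta <- try_fit(
      "multi_delta",
      c("measured_delta_density", config$multivariable_terms))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ftabs <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (f@converged) cbind(model = nm, formatFitTable(f)) else NULL
  })
  report <- do.call(rbind, ftabs[!vapply(ftabs, is.null, logical(1))])
  if (is.null(report))
    report <- data.frame(model = character(), variable = character(),
                         estimate = character(), ci_95 = character(),
                         p = character(), n = integer())
  paths$associations <- file.path(outdir, "association_models.csv")
  write.csv(report, paths$associations, row.names = FALSE)

  .log(logfile, "stage 5/5: cohort accounting")
  flow <- cohortAccounting(cohort)
  pct <- flowPercentages(flow)
  paths$accounting <- file.path(outdir, "cohort_flow.csv")
  write.csv(data.frame(quantity = names(pct), value = unname(pct)),
            paths$accounting, row.names = FALSE)

  paths$config_echo <- file.path(outdir, "cohort_config_echo.txt")
  .writeConfigEcho(ccfg, paths$config_echo)
  manifest <- list(
    package = "TILDensity",
    version = as.character(packageVersion("TILDensity")),
    seed = config$seed,
    config = config[setdiff(names(config), "cohort")],
    md5 = as.list(tools::md5sum(unlist(paths))))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  .log(logfile, "done: %d output files in %s", length(paths), outdir)
  invisible(list(cohort = cohort, fits = fits, flow = flow,
                 percentages = pct, paths = paths))
}

#' Construct a cohort flow object
#'
#' Direct constructor with validity checks (stage counts must be nested,
#' pCR counts bounded by their denominators, exclusions summing to the
#' stage differences).
#'
#' @param n_primary_analysis,n_baseline_included,n_matched_pre_post stage
#'   counts.
#' @param n_pcr_baseline,n_pcr_matched pCR counts in the baseline/matched
#'   stages.
#' @param exclusion_reasons named integer vector of baseline exclusions.
#' @return A [CohortFlow-class].
#' @export
cohortFlow <- function(n_primary_analysis, n_baseline_included,
                       n_matched_pre_post, n_pcr_baseline, n_pcr_matched,
                       exclusion_reasons = integer()) {
  flow <- new("CohortFlow",
              n_primary_analysis = as.integer(n_primary_analysis),
              n_baseline_included = as.integer(n_baseline_included),
              n_matched_pre_post = as.integer(n_matched_pre_post),
              n_pcr_baseline = as.integer(n_pcr_baseline),
              n_pcr_matched = as.integer(n_pcr_matched),
              exclusion_reasons = setNames(as.integer(exclusion_reasons),
                                           names(exclusion_reasons)))
  if (length(flow@exclusion_reasons) &&
      sum(flow@exclusion_reasons) !=
        flow@n_primary_analysis - flow@n_baseline_included)
    stop("exclusion reasons must sum to the stage-to-stage difference")
  flow
}

#' Cohort accounting across the analytic stages
#'
#' Counts patients through the stages -- primary analysis, baseline
#' density analysis (`has_baseline`), matched pre/post analysis
#' (`has_post`) -- with pCR counts per stage. Availability flags can come
#' from the records themselves or be derived from a slide inventory
#' (`patient_id`, `timepoint` in `"pre"`/`"post"`). Patients lacking
#' baseline data may carry an `exclusion_reason` column.
#'
#' @param records patient table with `patient_id` and `pcr`.
#' @param slide_inventory optional slide table used to derive the flags.
#' @return A [CohortFlow-class]; see [flowPercentages()] for the derived
#'   percentages.
#' @export
cohortAccounting <- function(records, slide_inventory = NULL) {
  records <- as.data.frame(records)
  if (!is.null(slide_inventory)) {
    records$has_baseline <- records$patient_id %in%
      slide_inventory$patient_id[slide_inventory$timepoint == "pre"]
    records$has_post <- records$patient_id %in%
      slide_inventory$patient_id[slide_inventory$timepoint == "post"]
  }
  if (is.null(records$has_baseline) || is.null(records$has_post))
    stop("records need has_baseline/has_post flags or a slide inventory")
  base <- records$has_baseline
  matched <- records$has_baseline & records$has_post
  excl <- if (!is.null(records$exclusion_reason)) {
    tab <- table(records$exclusion_reason[!base])
    setNames(as.integer(tab), names(tab))
  } else if (any(!base)) {
    c(`slide unavailable` = sum(!base))
  } else integer()
  cohortFlow(nrow(records), sum(base), sum(matched),
             sum(records$pcr == 1 & base),
             sum(records$pcr == 1 & matched), excl)
}

#' Percentages derived from a cohort flow
#'
#' Inclusion rates use the primary-analysis count as denominator; pCR
#' rates use their own stage count. Rounded to the nearest integer
#' percent, halves away from zero.
#'
#' @param flow a [CohortFlow-class].
#' @return named numeric vector: `baseline_pct`, `matched_pct`,
#'   `pcr_baseline_pct`, `pcr_matched_pct`.
#' @export
flowPercentages <- function(flow) {
  stopifnot(is(flow, "CohortFlow"))
  c(baseline_pct = roundHalfUp(
      100 * flow@n_baseline_included / flow@n_primary_analysis),
    matched_pct = roundHalfUp(
      100 * flow@n_matched_pre_post / flow@n_primary_analysis),
    pcr_baseline_pct = roundHalfUp(
      100 * flow@n_pcr_baseline / max(1L, flow@n_baseline_included)),
    pcr_matched_pct = roundHalfUp(
      100 * flow@n_pcr_matched / max(1L, flow@n_matched_pre_post)))
}
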