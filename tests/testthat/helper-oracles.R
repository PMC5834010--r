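# Independent oracles and shared fixtures, built in code at test time.

# all-pairs brute-force mean distance to the k nearest neighbours
bruteForceKnnMean <- function(pts, k) {
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  vapply(seq_len(nrow(pts)), function(i) mean(sort(D[i, ])[seq_len(k)]),
         numeric(1))
}

# a slide whose nuclei are pairwise non-overlapping and away from the
# border, by greedy thinning of a Poisson draw
nonOverlappingSlide <- function(seed, field_um = 400, margin_um = 15,
                                gap_um = 2) {
  cfg <- syntheticConfig(field_width_um = field_um,
                         field_height_um = field_um,
                         lymphocyte_intensity = 600,
                         cancer_intensity = 450,
                         stromal_intensity = 450, seed = seed)
  slide <- simulatePointPattern(cfg)
  cl <- cellPoints(slide)
  rmax <- cl$radius_um * sqrt(cl$axis_ratio)
  keep <- rep(TRUE, nrow(cl))
  for (i in seq_len(nrow(cl))) {
    if (!keep[i]) next
    d <- sqrt((cl$x_um - cl$x_um[i])^2 + (cl$y_um - cl$y_um[i])^2)
    clash <- which(d < rmax + rmax[i] + gap_um & seq_len(nrow(cl)) > i)
    keep[clash] <- FALSE
  }
  keep <- keep & cl$x_um > margin_um & cl$x_um < field_um - margin_um &
    cl$y_um > margin_um & cl$y_um < field_um - margin_um
  cl <- cl[keep, , drop = FALSE]
  cl$cell_id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  slide@cells <- cl
  slide
}

# truth indices of nuclei isolated from every other nucleus (their detected
# object has an unambiguous true label)
isolatedNuclei <- function(cells, gap_um = 1) {
  D <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  diag(D) <- Inf
  rmax <- cells$radius_um * sqrt(cells$axis_ratio)
  vapply(seq_len(nrow(cells)),
         function(i) all(D[i, ] > rmax + rmax[i] + gap_um), logical(1))
}

# shared trained classifier (expensive; built once per session)
.fixtures <- new.env(parent = emptyenv())
sharedClassifier <- function() {
  if (is.null(.fixtures$clf)) {
    ts <- makeTrainingSet(n_per_class = 300, seed = 1)
    .fixtures$train <- ts
    .fixtures$clf <- trainCellClassifier(ts$features, ts$labels)
  }
  .fixtures$clf
}
sharedTrainingSet <- function() {
  sharedClassifier()
  .fixtures$train
}

# synthetic patient table reproducing a trial flowchart's stage counts
flowFixtureRecords <- function(n_primary = 781, n_baseline = 609,
                               n_matched = 383, n_pcr_baseline = 109,
                               n_pcr_matched = 17, n_pcr_total = 156) {
  stopifnot(n_matched <= n_baseline, n_baseline <= n_primary,
            n_pcr_matched <= n_pcr_baseline,
            n_pcr_baseline + (n_primary - n_baseline) >= n_pcr_total)
  has_baseline <- c(rep(TRUE, n_baseline), rep(FALSE, n_primary - n_baseline))
  has_post <- c(rep(TRUE, n_matched), rep(FALSE, n_primary - n_matched))
  pcr <- integer(n_primary)
  pcr[seq_len(n_pcr_matched)] <- 1L                      # matched subset
  pcr[n_matched + seq_len(n_pcr_baseline - n_pcr_matched)] <- 1L  # baseline
  extra <- n_pcr_total - n_pcr_baseline                  # outside baseline
  if (extra > 0) pcr[n_baseline + seq_len(extra)] <- 1L
  data.frame(patient_id = sprintf("F%04d", seq_len(n_primary)),
             pcr = pcr, has_baseline = has_baseline, has_post = has_post)
}
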