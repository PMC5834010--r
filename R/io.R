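## Plain-text readers/writers for the pipeline's interchange formats.

#' Write / read ground-truth cells as CSV
#'
#' Columns `cell_id,x_um,y_um,class,radius_um` (shape columns are appended
#' when present so a written slide re-renders identically).
#'
#' @param slide a [GroundTruthSlide-class].
#' @param path output CSV path.
#' @return `writeCellsCSV`: the path, invisibly.
#' @export
writeCellsCSV <- function(slide, path) {
  cols <- intersect(c("cell_id", "x_um", "y_um", "class", "radius_um",
                      "axis_ratio", "theta"), names(slide@cells))
  write.csv(slide@cells[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellsCSV
#' @param slide_id identifier for the resulting map.
#' @param field_width_um,field_height_um field geometry of the map.
#' @return `readCellMapCSV`: a [CellMap-class].
#' @export
readCellMapCSV <- function(path, slide_id, field_width_um,
                           field_height_um) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cellMap(slide_id, df[, c("x_um", "y_um", "class")], field_width_um,
          field_height_um)
}

#' Write a cell map (or classifier predictions) as CSV
#'
#' Columns `cell_id,x_um,y_um,class`.
#'
#' @param map a [CellMap-class].
#' @param path output CSV path.
#' @export
writeCellMapCSV <- function(map, path) {
  p <- map@points
  out <- data.frame(cell_id = seq_len(nrow(p)), x_um = p$x_um,
                    y_um = p$y_um, class = p$class)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Per-slide density summaries as a data.frame row / CSV
#'
#' @param summaries list of [SlideDensitySummary-class] objects.
#' @return `data.frame` with `slide_id`, `patient_id`, `n_lymphocytes`,
#'   `k_used`, `median_density_au`.
#' @export
densitySummaryTable <- function(summaries) {
  if (is(summaries, "SlideDensitySummary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s)
    data.frame(slide_id = s@slide_id, patient_id = s@patient_id,
               n_lymphocytes = s@n_lymphocytes, k_used = s@k_used,
               median_density_au = s@median_density)))
}

## flat key = value provenance echo of a config (TOML-style)
.writeConfigEcho <- function(config, path) {
  slots <- slotNames(class(config))
  lines <- vapply(slots, function(s) {
    v <- slot(config, s)
    if (is.list(v))
      sprintf("%s = {%s}", s, paste(
        vapply(names(v), function(nm) sprintf("%s: %s", nm,
          paste(format(unlist(v[[nm]]), digits = 10), collapse = " ")),
          character(1)), collapse = "; "))
    else
      sprintf("%s = %s", s,
              paste(format(v, digits = 10), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
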