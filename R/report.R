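#' Format an accuracy-scale boundary for display
#'
#' Renders a boundary proportion as a percentage at 0 or 1 decimal
#' places.  Boundaries below zero — stages where even all-failure data
#' could not trigger stopping — are rendered as a dash, and rounding is
#' round-half-even (base R [round()]), matching the convention of the
#' published boundary tables (e.g. 1 - 7/8 = 12.5% displays as `"12%"`).
#'
#' @param boundary Numeric vector of boundary proportions (possibly
#'   negative) or `NA`.
#' @param precision Decimal places, 0 or 1.
#' @return Character vector, e.g. `"52%"`, `"88.5%"`, `"-"`.
#' @examples
#' format_boundary(1 - 14/29)        # "52%"
#' format_boundary(1 - 6/52, 1)      # "88.5%"
#' format_boundary(1 - 9/8)          # "-"
#' @export
format_boundary <- function(boundary, precision = 0) {
  if (!precision %in% c(0, 1))
    stop("`precision` must be 0 or 1", call. = FALSE)
  vapply(boundary, function(b) {
    if (is.na(b) || b < 0) "-"
    else sprintf(paste0("%.", precision, "f%%"), round(100 * b, precision))
  }, character(1))
}

# percent for observed estimates; NA (not evaluable) renders as "-"
.format_percent <- function(x, precision = 0) {
  vapply(x, function(v) {
    if (is.na(v)) "-"
    else sprintf(paste0("%.", precision, "f%%"), round(100 * v, precision))
  }, character(1))
}

#' Render monitoring results as a boundary/decision table
#'
#' Produces the standard presentation of sequential DTA monitoring
#' results: one row per evaluated analysis with the accrual sizes, each
#' endpoint's estimate followed by its boundary in brackets, the
#' per-endpoint decisions and the overall decision.
#'
#' @param results A [monitor_dta()] result (class `"dta_monitor"`).
#' @param precision Decimal places for percentages (0 or 1).
#' @return A character-column data frame with columns `N (N_pos)`,
#'   `Sensitivity (boundary)`, `Specificity (boundary)`,
#'   `Sensitivity decision`, `Specificity decision`, `Decision`.
#'   Zero data rows give a header-only table.
#' @examples
#' des <- dta_design(0.35, "positives", c(15, 25, 50), 70,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' cohort <- simulate_cohort(cohort_scenario(0.35, 0.65, 0.85, 250, 7))
#' report_table(monitor_dta(des, cohort))
#' @export
report_table <- function(results, precision = 0) {
  if (!inherits(results, "dta_monitor"))
    stop("`results` must come from `monitor_dta()`", call. = FALSE)
  data.frame(
    `N (N_pos)` = if (nrow(results))
      sprintf("%d (%d)", results$n, results$n_pos) else character(),
    `Sensitivity (boundary)` =
      sprintf("%s (%s)", .format_percent(results$sens, precision),
              format_boundary(results$sens_boundary, precision)),
    `Specificity (boundary)` =
      sprintf("%s (%s)", .format_percent(results$spec, precision),
              format_boundary(results$spec_boundary, precision)),
    `Sensitivity decision` = results$sens_decision,
    `Specificity decision` = results$spec_decision,
    Decision = results$decision,
    check.names = FALSE)
}

#' Write monitoring results to CSV, losslessly
#'
#' Writes the numeric monitoring results (not the formatted display
#' table) so that re-parsing reproduces every field exactly: floating
#' point columns are serialised with 17 significant digits.
#'
#' @param results A [monitor_dta()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_monitor_csv()]
#' @export
write_monitor_csv <- function(results, path) {
  if (!inherits(results, "dta_monitor"))
    stop("`results` must come from `monitor_dta()`", call. = FALSE)
  out <- as.data.frame(results)
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Re-read monitoring results written by [write_monitor_csv()]
#'
#' @param path CSV path.
#' @return A `"dta_monitor"` data frame equal to the one written.
#' @export
read_monitor_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  int_cols <- c("stage", "n", "n_pos", "n_neg", "sens_failures", "sens_r",
                "spec_failures", "spec_r")
  for (col in intersect(int_cols, names(df)))
    df[[col]] <- as.integer(df[[col]])
  class(df) <- c("dta_monitor", "data.frame")
  df
}

#' Futility-boundary rectangles for plotting
#'
#' For each planned analysis, the continue region in the
#' (sensitivity, specificity) plane is the rectangle strictly above both
#' futility boundaries, with upper edges at 100%; an unattainable
#' (dashed) boundary contributes a lower edge at 0%.  The rectangles
#' shrink (nest) as the sample size grows.  Coordinates are returned in
#' percent for direct use by external plotting code.
#'
#' @param design A [dta_design()].
#' @return A data frame with one row per analysis: `stage`, `n_pos`,
#'   `n_neg`, `sens_low`, `sens_high`, `spec_low`, `spec_high`.
#' @examples
#' des <- dta_design(0.35, "total", c(25, 75, 150), 200,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' boundary_rectangles(des)
#' @export
boundary_rectangles <- function(design) {
  .check_dta_design(design)
  proj <- project_group_sizes(design)
  sens_b <- 1 - futility_boundary_count(proj$positives,
                                        design$sens_endpoint) /
    proj$positives
  spec_b <- 1 - futility_boundary_count(proj$negatives,
                                        design$spec_endpoint) /
    proj$negatives
  data.frame(stage = proj$stage, n_pos = proj$positives,
             n_neg = proj$negatives,
             sens_low = 100 * pmax(sens_b, 0), sens_high = 100,
             spec_low = 100 * pmax(spec_b, 0), spec_high = 100)
}
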