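#' Cross-tabulate index test against reference standard
#'
#' Builds the 2x2 accuracy table (TP, FN, TN, FP) over the first `upto`
#' participant records, in recruitment order.
#'
#' @param records Participant records (see [read_participants()]).
#' @param upto Number of leading records to include; defaults to all.
#' @return An object of class `"accuracy_table"`: a list with integer
#'   counts `TP`, `FN`, `TN`, `FP` and derived `sensitivity` and
#'   `specificity` (`NA` when the corresponding group is empty).
#' @examples
#' rec <- data.frame(order = 1:3, reference = c(1, 1, 0),
#'                   index = c(1, 0, 0))
#' tabulate_accuracy(rec)
#' @export
tabulate_accuracy <- function(records, upto = nrow(records)) {
  records <- .check_records(records)
  if (upto < 0 || upto > nrow(records))
    stop("`upto` must lie between 0 and the number of records",
         call. = FALSE)
  ref <- records$reference[seq_len(upto)]
  idx <- records$index[seq_len(upto)]
  tp <- sum(ref == 1 & idx == 1)
  fn <- sum(ref == 1 & idx == 0)
  tn <- sum(ref == 0 & idx == 0)
  fp <- sum(ref == 0 & idx == 1)
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("2x2 accuracy table\n")
  cat("  TP =", x$TP, " FN =", x$FN, " (sensitivity",
      if (is.na(x$sensitivity)) "not evaluable)"
      else paste0(format(signif(100 * x$sensitivity, 4)), "%)"), "\n")
  cat("  TN =", x$TN, " FP =", x$FP, " (specificity",
      if (is.na(x$specificity)) "not evaluable)"
      else paste0(format(signif(100 * x$specificity, 4)), "%)"), "\n")
  invisible(x)
}

# Decision for one endpoint from its failure count and observed group size.
# Boundaries use the observed size but keep the planned anchor.
.endpoint_decision <- function(failures, n, design, final) {
  if (n == 0L)
    return(list(decision = "Not evaluable", r = NA_integer_,
                boundary = NA_real_, estimate = NA_real_))
  r <- futility_boundary_count(n, design)
  a <- if (!is.null(design$efficacy)) {
    av <- efficacy_boundary_count(n, design)
    if (final) r - 1L else av
  } else -1L
  decision <-
    if (failures >= r) "Stop for futility"
    else if (a >= 0L && failures <= a) "Stop for efficacy"
    else "Continue"
  list(decision = decision, r = r, boundary = 1 - r / n,
       estimate = 1 - failures / n)
}

#' Evaluate accrued 2x2 data at one interim analysis
#'
#' Applies the stagewise stopping rule to an accuracy table: for each
#' endpoint the failure count (FN for sensitivity, FP for specificity)
#' is compared against the futility count at the observed group size —
#' equivalently, the study stops when the accuracy estimate is at or
#' below the accuracy-scale boundary, with equality triggering stopping.
#' Decisions are taken on integer failure counts, never on rounded
#' percentages.  The per-endpoint decisions are combined by the design's
#' futility rule (`"either"` by default) and, when efficacy stopping is
#' enabled, by the both-endpoints efficacy rule.  An endpoint with an
#' empty group is `"Not evaluable"` and never triggers stopping.
#'
#' At the final analysis a crossed futility boundary is still reported
#' as `"Stop for futility"` (the null hypothesis of adequate accuracy is
#' rejected); otherwise the overall decision is `"No termination"`.
#'
#' @param design A [dta_design()].
#' @param table An [tabulate_accuracy()] table of the data accrued at
#'   the analysis.
#' @param final Logical: is this the final analysis?
#' @param stage Stage index used for labelling.
#' @return An object of class `"interim_result"`: a one-row data frame
#'   with group sizes, estimates, failure counts, boundary counts,
#'   accuracy-scale boundaries, per-endpoint decisions and the overall
#'   `decision`.
#' @export
evaluate_interim <- function(design, table, final = FALSE, stage = 1L) {
  .check_dta_design(design)
  if (!inherits(table, "accuracy_table"))
    stop("`table` must be an `accuracy_table`", call. = FALSE)
  n_pos <- table$TP + table$FN
  n_neg <- table$TN + table$FP
  sens <- .endpoint_decision(table$FN, n_pos, design$sens_endpoint, final)
  spec <- .endpoint_decision(table$FP, n_neg, design$spec_endpoint, final)
  decisions <- c(sens$decision, spec$decision)
  futile <- decisions == "Stop for futility"
  stop_futility <- if (design$futility_rule == "either") any(futile)
                   else all(futile)
  stop_efficacy <- design$efficacy_enabled &&
    all(decisions == "Stop for efficacy")
  overall <-
    if (stop_futility) "Stop for futility"
    else if (stop_efficacy) "Stop for efficacy"
    else if (final) "No termination"
    else "Continue"
  out <- data.frame(
    stage = as.integer(stage), n = n_pos + n_neg,
    n_pos = n_pos, n_neg = n_neg,
    sens = sens$estimate, sens_failures = table$FN, sens_r = sens$r,
    sens_boundary = sens$boundary, sens_decision = sens$decision,
    spec = spec$estimate, spec_failures = table$FP, spec_r = spec$r,
    spec_boundary = spec$boundary, spec_decision = spec$decision,
    decision = overall, final = final)
  class(out) <- c("interim_result", "data.frame")
  out
}

#' Sequentially monitor accrued DTA data
#'
#' Walks the scheduled analysis points of a design over ordered
#' participant records, emitting one interim result per reached stage
#' and stopping after the first overall stop (the study is terminated,
#' so later scheduled analyses are not evaluated).  The final analysis
#' is appended when the target is reached without stopping.
#'
#' @param design A [dta_design()].
#' @param records Participant records ordered by recruitment (see
#'   [read_participants()]); an optional `day` column makes analysis
#'   cuts fall on batch (end-of-day) boundaries, reproducing the
#'   overshoot seen when accrual outpaces milestone checks.
#' @return A data frame of class `"dta_monitor"` (one
#'   [evaluate_interim()] row per evaluated analysis).  Zero rows when
#'   accrual never reaches the first scheduled point.
#' @examples
#' des <- dta_design(0.35, "positives", c(15, 25, 50), 70,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' cohort <- simulate_cohort(cohort_scenario(0.35, 0.65, 0.85,
#'                                           n = 250, seed = 7))
#' monitor_dta(des, cohort)
#' @export
monitor_dta <- function(design, records) {
  .check_dta_design(design)
  records <- .check_records(records)
  stages <- realized_stage_sizes(design, records)
  rows <- list()
  for (i in seq_len(nrow(stages))) {
    if (!stages$reached[i]) break
    res <- evaluate_interim(design,
                            tabulate_accuracy(records, stages$cut[i]),
                            final = stages$final[i], stage = stages$stage[i])
    rows[[length(rows) + 1L]] <- res
    if (res$decision %in% c("Stop for futility", "Stop for efficacy"))
      break
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    evaluate_interim(design, tabulate_accuracy(records, 0L))[0, ]
  class(out) <- c("dta_monitor", "data.frame")
  attr(out, "design") <- design
  out
}

#' @export
print.dta_monitor <- function(x, precision = 0, ...) {
  if (nrow(x) == 0) {
    cat("No scheduled analysis point reached.\n")
    return(invisible(x))
  }
  print(report_table(x, precision = precision), row.names = FALSE, ...)
  invisible(x)
}
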