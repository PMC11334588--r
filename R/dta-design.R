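#' Bivariate interim monitoring plan for a DTA study
#'
#' Combines two single-endpoint monitoring plans — one for sensitivity
#' (monitored through its false-negative rate) and one for specificity
#' (through its false-positive rate) — with an accrual schedule and the
#' rules for combining the two endpoints into an overall decision.
#'
#' Interim analyses may be scheduled by the total number of participants
#' recruited (`schedule_by = "total"`) or by the number of
#' disease-positive cases observed (`schedule_by = "positives"`).  The
#' assumed `prevalence` converts schedule points and the overall `target`
#' into planned per-endpoint group sizes: under a by-total schedule a
#' point of `N` participants projects to `round(N * prevalence)`
#' positives and the rest negatives; under a by-positives schedule the
#' negative group is projected as `round(N_pos * (1 - prevalence) /
#' prevalence)`.  Projections are planning quantities only — at analysis
#' time the observed group sizes replace them, while boundaries stay
#' anchored to the planned final group sizes.
#'
#' The default futility rule is `"either"`: the study stops if either
#' sensitivity or specificity crosses its futility boundary, appropriate
#' when the test must meet a minimum level on both measures.  Efficacy
#' stopping (when enabled on the endpoints) always requires both
#' endpoints to cross their acceptance boundaries.
#'
#' @param prevalence Assumed disease prevalence, strictly between 0
#'   and 1.
#' @param schedule_by `"total"` or `"positives"`: whether
#'   `schedule_points` and `target` count all participants or
#'   disease-positive cases.
#' @param schedule_points Strictly increasing positive integers, all
#'   below `target`: the planned interim analysis points.
#' @param target Planned total participants (`"total"`) or planned total
#'   disease-positive cases (`"positives"`) at the final analysis.
#' @param sens_p0,spec_p0 Minimally acceptable sensitivity and
#'   specificity (proportions).
#' @param alpha One-sided per-endpoint type I error rate, applied
#'   separately to each endpoint with no cross-endpoint adjustment.
#' @param futility_rule `"either"` (default) or `"both"`.
#' @param sens_efficacy,spec_efficacy Optional efficacy parameter lists
#'   (`p_a`, `beta`) passed to [endpoint_design()]; efficacy stopping is
#'   only active when both are supplied.
#'
#' @return An object of class `"dta_design"`: a list holding the
#'   schedule, the assumed prevalence, the combination rules and the two
#'   [endpoint_design()] objects (`sens_endpoint`, `spec_endpoint`) whose
#'   planned stage sizes and anchors are the projected group sizes.
#'
#' @examples
#' # The worked simulated-study plan: 200 participants, 35% prevalence,
#' # interims after 15, 25 and 50 disease-positive cases, requiring 75%
#' # sensitivity and 90% specificity.
#' des <- dta_design(prevalence = 0.35, schedule_by = "positives",
#'                   schedule_points = c(15, 25, 50), target = 70,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' project_group_sizes(des)
#' @seealso [monitor_dta()], [project_group_sizes()], [reestimate_target()]
#' @export
dta_design <- function(prevalence, schedule_by = c("total", "positives"),
                       schedule_points, target, sens_p0, spec_p0,
                       alpha = 0.05, futility_rule = c("either", "both"),
                       sens_efficacy = NULL, spec_efficacy = NULL) {
  schedule_by <- match.arg(schedule_by)
  futility_rule <- match.arg(futility_rule)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be a single proportion strictly between 0 and 1",
         call. = FALSE)
  if (length(target) != 1L || is.na(target) || target < 1 ||
      target != floor(target))
    stop("`target` must be a single positive integer", call. = FALSE)
  if (length(schedule_points)) {
    if (any(is.na(schedule_points)) || any(schedule_points < 1) ||
        any(schedule_points != floor(schedule_points)))
      stop("`schedule_points` must be positive integers", call. = FALSE)
    if (any(diff(schedule_points) <= 0))
      stop("`schedule_points` must be strictly increasing", call. = FALSE)
    if (any(schedule_points >= target))
      stop("all `schedule_points` must be strictly below `target`",
           call. = FALSE)
  }
  proj <- .project_sizes(prevalence, schedule_by, schedule_points, target)
  sens_endpoint <- endpoint_design("FNR", p0 = sens_p0, alpha = alpha,
                                   stage_sizes = proj$positives,
                                   anchor_size = proj$final_positives,
                                   efficacy = sens_efficacy)
  spec_endpoint <- endpoint_design("FPR", p0 = spec_p0, alpha = alpha,
                                   stage_sizes = proj$negatives,
                                   anchor_size = proj$final_negatives,
                                   efficacy = spec_efficacy)
  structure(
    list(prevalence = prevalence, schedule_by = schedule_by,
         schedule_points = as.integer(schedule_points),
         target = as.integer(target),
         sens_endpoint = sens_endpoint, spec_endpoint = spec_endpoint,
         futility_rule = futility_rule,
         efficacy_rule = "both",
         efficacy_enabled = !is.null(sens_efficacy) &&
                            !is.null(spec_efficacy)),
    class = "dta_design")
}

# round half away from zero; planning projections only
.round_half_up <- function(x) floor(x + 0.5)

.project_sizes <- function(prevalence, schedule_by, points, target) {
  if (schedule_by == "total") {
    pos <- .round_half_up(points * prevalence)
    list(positives = as.integer(pos),
         negatives = as.integer(points - pos),
         final_positives = as.integer(.round_half_up(target * prevalence)),
         final_negatives = as.integer(target -
                                      .round_half_up(target * prevalence)))
  } else {
    ratio <- (1 - prevalence) / prevalence
    list(positives = as.integer(points),
         negatives = as.integer(.round_half_up(points * ratio)),
         final_positives = as.integer(target),
         final_negatives = as.integer(.round_half_up(target * ratio)))
  }
}

#' @export
print.dta_design <- function(x, ...) {
  cat("DTA interim monitoring design\n")
  cat("  Schedule:   interims at ",
      if (length(x$schedule_points))
        paste(x$schedule_points, collapse = ", ") else "(none)",
      " ", if (x$schedule_by == "total") "participants"
           else "disease-positive cases",
      "; target ", x$target, "\n", sep = "")
  cat("  Prevalence: ", format(100 * x$prevalence), "% (assumed)\n", sep = "")
  cat("  Futility rule: stop if ", x$futility_rule,
      " endpoint(s) cross; efficacy ",
      if (x$efficacy_enabled) "requires both endpoints" else "disabled",
      "\n", sep = "")
  cat("  Sensitivity endpoint: p0 = ", format(100 * x$sens_endpoint$p0),
      "%, group sizes ", paste(x$sens_endpoint$stage_sizes, collapse = ", "),
      " / final ", x$sens_endpoint$anchor_size, "\n", sep = "")
  cat("  Specificity endpoint: p0 = ", format(100 * x$spec_endpoint$p0),
      "%, group sizes ", paste(x$spec_endpoint$stage_sizes, collapse = ", "),
      " / final ", x$spec_endpoint$anchor_size, "\n", sep = "")
  invisible(x)
}

.check_dta_design <- function(design) {
  if (!inherits(design, "dta_design"))
    stop("`design` must be an object created by `dta_design()`",
         call. = FALSE)
  invisible(design)
}

#' Planned per-endpoint group sizes at each analysis
#'
#' Converts the schedule of a [dta_design()] into planned
#' disease-positive and disease-negative group sizes at each interim and
#' at the final analysis, using the assumed prevalence.  These are the
#' planning projections; observed accrual replaces them at analysis time.
#'
#' @param design A [dta_design()].
#' @return A data frame with one row per analysis: `stage`, `point`
#'   (scheduled value on the schedule scale), `positives`, `negatives`,
#'   `total` and `final` (logical, `TRUE` on the last row).
#' @examples
#' des <- dta_design(0.35, "total", c(25, 75, 150), 200,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' project_group_sizes(des)  # final anchors: 70 positives, 130 negatives
#' @export
project_group_sizes <- function(design) {
  .check_dta_design(design)
  proj <- .project_sizes(design$prevalence, design$schedule_by,
                         design$schedule_points, design$target)
  pos <- c(proj$positives, proj$final_positives)
  neg <- c(proj$negatives, proj$final_negatives)
  data.frame(stage = seq_along(pos),
             point = c(design$schedule_points, design$target),
             positives = pos, negatives = neg, total = pos + neg,
             final = seq_along(pos) == length(pos))
}

#' Observed group sizes at each scheduled analysis point
#'
#' Walks ordered accrual data and locates, for every scheduled interim
#' point and for the final target, the first accrual position at or
#' beyond the point: the first participant (or, when the records carry a
#' `day` column, the first end-of-day batch) at which the total count
#' (by-total schedules) or the disease-positive count (by-positives
#' schedules) reaches the scheduled value.  Overshoot past the milestone
#' is retained — with batched accrual the analysis includes all data
#' available when the milestone is crossed.
#'
#' @param design A [dta_design()].
#' @param records Participant records: a data frame with columns
#'   `reference` and `index` (0/1), ordered by recruitment, optionally
#'   with a non-decreasing integer `day` batch column.  See
#'   [read_participants()].
#' @return A data frame with one row per scheduled analysis: `stage`,
#'   `point`, `reached` (logical), and for reached stages the cut
#'   position `cut` (number of leading records included), `n`, `n_pos`,
#'   `n_neg`, plus `final`.
#' @examples
#' rec <- data.frame(order = 1:10,
#'                   reference = c(1, 0, 1, 0, 0, 1, 0, 1, 0, 0),
#'                   index     = c(1, 0, 0, 0, 1, 1, 0, 1, 0, 0))
#' des <- dta_design(0.4, "positives", c(2, 3), 4,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' realized_stage_sizes(des, rec)
#' @export
realized_stage_sizes <- function(design, records) {
  .check_dta_design(design)
  records <- .check_records(records)
  points <- c(design$schedule_points, design$target)
  n_rec <- nrow(records)
  cum_pos <- cumsum(records$reference)
  # eligible cut positions: every record, or end-of-day batch boundaries
  if (!is.null(records$day)) {
    eligible <- which(records$day != c(records$day[-1], NA) |
                        seq_len(n_rec) == n_rec)
  } else {
    eligible <- seq_len(n_rec)
  }
  watched <- if (design$schedule_by == "total") eligible else
    cum_pos[eligible]
  cut <- vapply(points, function(pt) {
    hit <- which(watched >= pt)
    if (length(hit)) eligible[hit[1]] else NA_integer_
  }, integer(1))
  reached <- !is.na(cut)
  n_pos <- ifelse(reached, cum_pos[cut], NA_integer_)
  data.frame(stage = seq_along(points), point = points, reached = reached,
             cut = cut, n = cut, n_pos = as.integer(n_pos),
             n_neg = as.integer(cut - n_pos),
             final = seq_along(points) == length(points))
}

#' Re-estimate the study target from observed prevalence
#'
#' Interim analyses can also check the prevalence assumption: if the
#' observed prevalence differs from the planning value, the
#' total-participant target can be re-estimated so that the originally
#' required number of disease-positive cases is still expected.  For a
#' by-total design the new target is
#' `ceiling(required_positives / observed_prevalence)`; for a
#' by-positives design the positive target is unchanged but the updated
#' prevalence re-projects the negative group (and hence the specificity
#' anchor).  Downstream boundaries re-anchor to the new projections.
#'
#' @param design A [dta_design()].
#' @param observed_prevalence Observed disease prevalence, strictly
#'   between 0 and 1.
#' @return A new `dta_design`.  When the observed prevalence equals the
#'   assumed one the design is returned unchanged.
#' @examples
#' des <- dta_design(0.35, "total", c(25, 75, 150), 200,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' reestimate_target(des, 0.25)$target  # 70 positives now need 280
#' @export
reestimate_target <- function(design, observed_prevalence) {
  .check_dta_design(design)
  if (!is.numeric(observed_prevalence) || length(observed_prevalence) != 1L ||
      is.na(observed_prevalence) || observed_prevalence <= 0 ||
      observed_prevalence >= 1)
    stop("`observed_prevalence` must be a single proportion strictly ",
         "between 0 and 1", call. = FALSE)
  if (observed_prevalence == design$prevalence) return(design)
  new_target <- design$target
  if (design$schedule_by == "total") {
    required_pos <- design$sens_endpoint$anchor_size
    # guard the ratio against floating error before taking the ceiling
    new_target <- as.integer(ceiling(required_pos / observed_prevalence -
                                       1e-8))
  }
  dta_design(prevalence = observed_prevalence,
             schedule_by = design$schedule_by,
             schedule_points = design$schedule_points,
             target = new_target,
             sens_p0 = design$sens_endpoint$p0,
             spec_p0 = design$spec_endpoint$p0,
             alpha = design$sens_endpoint$alpha,
             futility_rule = design$futility_rule,
             sens_efficacy = design$sens_endpoint$efficacy,
             spec_efficacy = design$spec_endpoint$efficacy)
}
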