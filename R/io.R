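#' Read participant-level DTA accrual data
#'
#' Reads a headered CSV with one row per participant in recruitment
#' order: `order` (recruitment sequence, unique and contiguous from 1),
#' `reference` (1 = diseased by the reference standard, 0 = not) and
#' `index` (1 = index test positive, 0 = negative).  An optional `day`
#' column of non-decreasing positive integers marks accrual batches
#' (e.g. data arriving daily); when present, interim cuts fall on batch
#' boundaries.  Invalid values are rejected with row-numbered messages.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of participant records.
#' @export
read_participants <- function(path) {
  if (!file.exists(path))
    stop("participant file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_records(df, where = path)
}

.check_records <- function(records, where = "records") {
  if (!is.data.frame(records))
    stop("participant records must be a data frame", call. = FALSE)
  needed <- c("order", "reference", "index")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop(where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("reference", "index")) {
    bad <- which(!(records[[col]] %in% c(0, 1)))
    if (length(bad))
      stop(where, ": column `", col, "` must be 0/1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(records) && !identical(as.integer(records$order),
                                  seq_len(nrow(records))))
    stop(where, ": `order` must be contiguous integers 1, 2, ... in ",
         "recruitment order", call. = FALSE)
  if (!is.null(records$day)) {
    bad <- which(is.na(records$day) | records$day < 1 |
                   records$day != floor(records$day))
    if (length(bad))
      stop(where, ": column `day` must contain positive integers; ",
           "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    if (nrow(records) > 1 && any(diff(records$day) < 0))
      stop(where, ": column `day` must be non-decreasing", call. = FALSE)
  }
  records
}

#' Read a DTA design from a YAML configuration file
#'
#' The configuration mirrors the arguments of [dta_design()]:
#'
#' ```yaml
#' prevalence: 0.35
#' schedule:
#'   by: positives        # or "total"
#'   points: [15, 25, 50]
#'   target: 70
#' sensitivity: {p0: 0.75}
#' specificity: {p0: 0.90}
#' alpha: 0.05            # optional, default 0.05
#' futility_rule: either  # optional, default "either"
#' ```
#'
#' Optional `efficacy: {p_a: ..., beta: ...}` blocks inside
#' `sensitivity`/`specificity` enable efficacy stopping.  Schema
#' violations raise errors naming the offending field.
#'
#' @param path Path to the YAML (or JSON, which YAML subsumes) file.
#' @return A [dta_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    stop("design file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- function(x, field, parent = NULL) {
    if (is.null(x))
      stop("design config: missing required field `",
           if (is.null(parent)) field else paste0(parent, ".", field),
           "`", call. = FALSE)
    x
  }
  schedule <- need(cfg$schedule, "schedule")
  sens <- need(cfg$sensitivity, "sensitivity")
  spec <- need(cfg$specificity, "specificity")
  eff <- function(block) {
    if (is.null(block$efficacy)) NULL
    else list(p_a = need(block$efficacy$p_a, "p_a", "efficacy"),
              beta = need(block$efficacy$beta, "beta", "efficacy"))
  }
  dta_design(
    prevalence = need(cfg$prevalence, "prevalence"),
    schedule_by = match.arg(need(schedule$by, "by", "schedule"),
                            c("total", "positives")),
    schedule_points = unlist(need(schedule$points, "points", "schedule")),
    target = need(schedule$target, "target", "schedule"),
    sens_p0 = need(sens$p0, "p0", "sensitivity"),
    spec_p0 = need(spec$p0, "p0", "specificity"),
    alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
    futility_rule = if (is.null(cfg$futility_rule)) "either"
                    else match.arg(cfg$futility_rule, c("either", "both")),
    sens_efficacy = eff(sens), spec_efficacy = eff(spec))
}

#' Write a DTA design to a YAML configuration file
#'
#' Inverse of [read_design()]: serialises the design fields in the
#' documented schema.
#'
#' @param design A [dta_design()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  .check_dta_design(design)
  block <- function(ep) {
    b <- list(p0 = ep$p0)
    if (!is.null(ep$efficacy)) b$efficacy <- ep$efficacy
    b
  }
  cfg <- list(
    prevalence = design$prevalence,
    schedule = list(by = design$schedule_by,
                    points = as.list(design$schedule_points),
                    target = design$target),
    sensitivity = block(design$sens_endpoint),
    specificity = block(design$spec_endpoint),
    alpha = design$sens_endpoint$alpha,
    futility_rule = design$futility_rule)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
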