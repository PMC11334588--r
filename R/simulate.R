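#' Scenario for synthetic DTA cohort generation
#'
#' Describes the data-generating process of a single-cohort DTA study:
#' each participant's disease status is Bernoulli(`prevalence`), and the
#' index test result is Bernoulli(`sensitivity`) for diseased
#' participants and Bernoulli(`1 - specificity`) for non-diseased ones.
#' Participants are independent and accrue in recruitment order.
#'
#' @param prevalence,sensitivity,specificity True proportions in
#'   `[0, 1]`.
#' @param n Cohort size (number of participants).
#' @param seed Integer seed making the generated cohort reproducible.
#' @return An object of class `"cohort_scenario"`.
#' @examples
#' cohort_scenario(0.35, 0.65, 0.85, n = 200, seed = 1)
#' @export
cohort_scenario <- function(prevalence, sensitivity, specificity, n,
                            seed = 1L) {
  for (nm in c("prevalence", "sensitivity", "specificity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a single proportion in [0, 1]", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  structure(list(prevalence = prevalence, sensitivity = sensitivity,
                 specificity = specificity, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("DTA cohort scenario: n =", x$n, "\n")
  cat("  prevalence ", format(100 * x$prevalence), "%, sensitivity ",
      format(100 * x$sensitivity), "%, specificity ",
      format(100 * x$specificity), "%  (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Lean replicate-level monitor used by simulate_oc: same counting rule
# as monitor_dta()/evaluate_interim() (futility when failures >= r at the
# observed group size anchored to the plan; efficacy when <= a; "either"/
# "both" combination; empty groups never stop) but computed from cumulative
# sums with precomputed boundary drifts.  Equivalence to monitor_dta() is
# asserted in the test suite.
.monitor_counts <- function(design, ref, idx) {
  n <- length(ref)
  cum_pos <- cumsum(ref)
  pos_at <- which(ref == 1L)
  points <- c(design$schedule_points, design$target)
  G <- length(points)
  se <- design$sens_endpoint
  sp <- design$spec_endpoint
  z_a <- stats::qnorm(1 - se$alpha)
  drift_s <- z_a * sqrt(se$anchor_size * se$p_t * (1 - se$p_t))
  drift_p <- stats::qnorm(1 - sp$alpha) *
    sqrt(sp$anchor_size * sp$p_t * (1 - sp$p_t))
  eff_on <- design$efficacy_enabled
  if (eff_on) {
    ed_s <- se$efficacy; ed_p <- sp$efficacy
    edrift_s <- stats::qnorm(1 - ed_s$beta) *
      sqrt(se$anchor_size * ed_s$p_a * (1 - ed_s$p_a))
    edrift_p <- stats::qnorm(1 - ed_p$beta) *
      sqrt(sp$anchor_size * ed_p$p_a * (1 - ed_p$p_a))
  }
  cum_fn <- cumsum(ref * (1L - idx))
  cum_fp <- cumsum((1L - ref) * idx)
  either <- design$futility_rule == "either"
  for (g in seq_len(G)) {
    cut <- if (design$schedule_by == "total") {
      if (points[g] <= n) points[g] else NA_integer_
    } else {
      if (points[g] <= length(pos_at)) pos_at[points[g]] else NA_integer_
    }
    if (is.na(cut))
      return(list(stage = NA_integer_, stop_type = "none", terminal_n = n))
    n_pos <- cum_pos[cut]; n_neg <- cut - n_pos
    final <- g == G
    r_s <- if (n_pos > 0) floor(n_pos * se$p_t + 0.5 + drift_s) + 1 else NA
    r_p <- if (n_neg > 0) floor(n_neg * sp$p_t + 0.5 + drift_p) + 1 else NA
    fut_s <- !is.na(r_s) && cum_fn[cut] >= r_s
    fut_p <- !is.na(r_p) && cum_fp[cut] >= r_p
    if (if (either) (fut_s || fut_p) else (fut_s && fut_p))
      return(list(stage = g, stop_type = "futility", terminal_n = cut))
    if (eff_on) {
      a_s <- if (is.na(r_s)) NA else if (final) r_s - 1 else
        min(ceiling(n_pos * ed_s$p_a - 0.5 - edrift_s) - 1, r_s - 1)
      a_p <- if (is.na(r_p)) NA else if (final) r_p - 1 else
        min(ceiling(n_neg * ed_p$p_a - 0.5 - edrift_p) - 1, r_p - 1)
      eff_s <- !is.na(a_s) && a_s >= 0 && cum_fn[cut] <= a_s && !fut_s
      eff_p <- !is.na(a_p) && a_p >= 0 && cum_fp[cut] <= a_p && !fut_p
      if (eff_s && eff_p)
        return(list(stage = g, stop_type = "efficacy", terminal_n = cut))
    }
    if (final)
      return(list(stage = g, stop_type = "none", terminal_n = cut))
  }
}

.draw_cohort <- function(prevalence, sensitivity, specificity, n) {
  ref <- stats::rbinom(n, 1L, prevalence)
  idx <- stats::rbinom(n, 1L, ifelse(ref == 1L, sensitivity,
                                     1 - specificity))
  list(reference = ref, index = idx)
}

#' Generate a synthetic DTA cohort
#'
#' Draws one ordered participant cohort from a [cohort_scenario()].
#' The draw is deterministic given the scenario's seed (the function
#' seeds R's RNG).
#'
#' @param scenario A [cohort_scenario()].
#' @return A participant-record data frame with columns `order`,
#'   `reference`, `index`, usable directly with [monitor_dta()] and
#'   writable via [utils::write.csv()] in the format of
#'   [read_participants()].
#' @examples
#' head(simulate_cohort(cohort_scenario(0.35, 0.65, 0.85, 50, seed = 2)))
#' @export
simulate_cohort <- function(scenario) {
  if (!inherits(scenario, "cohort_scenario"))
    stop("`scenario` must be a `cohort_scenario`", call. = FALSE)
  set.seed(scenario$seed)
  d <- .draw_cohort(scenario$prevalence, scenario$sensitivity,
                    scenario$specificity, scenario$n)
  data.frame(order = seq_len(scenario$n), reference = d$reference,
             index = d$index)
}

#' Monte Carlo operating characteristics of a DTA design
#'
#' Runs the sequential monitor over independent synthetic cohorts and
#' aggregates stagewise stopping frequencies, the overall
#' stop-for-futility frequency (including rejection at the final
#' analysis) and the mean terminal sample size, with binomial Monte
#' Carlo standard errors.  The root `seed` spawns one sub-seed per
#' replicate, so results are reproducible and individual replicates can
#' be regenerated in isolation.
#'
#' Cohorts should be large enough to reach the design's final target
#' with near certainty; a replicate whose accrual falls short of a
#' scheduled point simply never evaluates that analysis (counted as not
#' stopping, with its accrued size as the terminal size).
#'
#' @param design A [dta_design()].
#' @param scenario A [cohort_scenario()]; its `seed` component is
#'   ignored in favour of `seed`.
#' @param replicates Number of simulated cohorts (>= 1).
#' @param seed Root seed for the replicate stream.
#' @return An object of class `"oc_summary"`: a list with per-stage
#'   `stop_futility` / `stop_efficacy` frequencies, `no_stop`,
#'   `overall_futility` and its standard error `se_overall_futility`,
#'   `mean_terminal_n`, `replicates` and `seed`.
#' @examples
#' des <- dta_design(0.35, "positives", c(15, 25, 50), 70,
#'                   sens_p0 = 0.75, spec_p0 = 0.90)
#' sc <- cohort_scenario(0.35, 0.65, 0.85, n = 300)
#' simulate_oc(des, sc, replicates = 200, seed = 42)
#' @export
simulate_oc <- function(design, scenario, replicates, seed = 1L) {
  .check_dta_design(design)
  if (!inherits(scenario, "cohort_scenario"))
    stop("`scenario` must be a `cohort_scenario`", call. = FALSE)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1)
    stop("`replicates` must be a positive integer", call. = FALSE)
  replicates <- as.integer(replicates)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, replicates)
  G <- length(design$schedule_points) + 1L
  fut <- integer(G)
  eff <- integer(G)
  terminal_n <- numeric(replicates)
  n <- scenario$n
  for (i in seq_len(replicates)) {
    set.seed(sub_seeds[i])
    d <- .draw_cohort(scenario$prevalence, scenario$sensitivity,
                      scenario$specificity, n)
    res <- .monitor_counts(design, d$reference, d$index)
    if (res$stop_type == "futility") {
      fut[res$stage] <- fut[res$stage] + 1L
    } else if (res$stop_type == "efficacy") {
      eff[res$stage] <- eff[res$stage] + 1L
    }
    terminal_n[i] <- res$terminal_n
  }
  p_fut <- sum(fut) / replicates
  structure(list(
    stages = seq_len(G),
    stop_futility = fut / replicates,
    stop_efficacy = eff / replicates,
    no_stop = 1 - (sum(fut) + sum(eff)) / replicates,
    overall_futility = p_fut,
    se_overall_futility = sqrt(p_fut * (1 - p_fut) / replicates),
    mean_terminal_n = mean(terminal_n),
    replicates = replicates, seed = seed),
    class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat("Monte Carlo operating characteristics (", x$replicates,
      " replicates, seed ", x$seed, ")\n", sep = "")
  print(data.frame(stage = x$stages,
                   `stop futility` = x$stop_futility,
                   `stop efficacy` = x$stop_efficacy,
                   check.names = FALSE), row.names = FALSE)
  cat("Overall stop-for-futility frequency: ",
      format(x$overall_futility), " (MC SE ",
      format(signif(x$se_overall_futility, 3)), ")\n", sep = "")
  cat("No stop: ", format(x$no_stop),
      "; mean terminal sample size: ", format(round(x$mean_terminal_n, 1)),
      "\n", sep = "")
  invisible(x)
}
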