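#' Monitoring plan for a single error-rate endpoint
#'
#' Defines the exact group sequential monitoring plan for one of the two
#' error rates of a diagnostic accuracy study: the false-negative rate
#' (FNR, the complement of sensitivity) or the false-positive rate (FPR,
#' the complement of specificity).  The endpoint is expressed on the error
#' scale so that the monitored proportion stays below 0.5, the regime the
#' exact group sequential construction assumes; the accuracy threshold
#' `p0` (minimally acceptable sensitivity or specificity) maps to the
#' threshold error proportion `p_t = 1 - p0`, and the hypotheses are
#' `H0: p <= p_t` against `H1: p > p_t`, where `p` is the true error rate.
#' Rejecting `H0` at an interim analysis corresponds to stopping the study
#' for futility.
#'
#' Interim analyses are planned at cumulative endpoint-group sizes
#' `stage_sizes` (numbers of disease-positive participants for an FNR
#' endpoint, disease-negative for an FPR endpoint), with the final
#' analysis at `anchor_size`.  All stagewise boundaries are anchored to
#' `anchor_size`: observed interim group sizes may differ from (and even
#' exceed) the planned sizes without changing the anchor.
#'
#' @param label `"FNR"` or `"FPR"`: which error rate the endpoint
#'   monitors.  Affects only labelling; the arithmetic is identical.
#' @param p0 Minimally acceptable accuracy (sensitivity or specificity)
#'   on the success scale, strictly between 0 and 1, e.g. `0.75` for a
#'   75% sensitivity requirement.
#' @param alpha One-sided type I error rate for this endpoint
#'   (probability of wrongly rejecting `H0: p <= p_t`).  Default 0.05.
#' @param stage_sizes Strictly increasing positive integers: planned
#'   cumulative endpoint-group sizes at each interim analysis.  May be
#'   empty for a single-stage (no-interim) design.
#' @param anchor_size Planned endpoint-group size at the final analysis,
#'   to which all boundaries are anchored.
#' @param efficacy Optional list with components `p_a` (error proportion
#'   under the alternative deemed good enough to accept early,
#'   `0 <= p_a < p_t`) and `beta` (one-sided error rate for early
#'   acceptance).  When supplied, acceptance (efficacy) boundaries are
#'   computed alongside the futility boundaries; by default efficacy
#'   stopping is disabled, which is the recommended practice for DTA
#'   studies.
#'
#' @return An object of class `"endpoint_design"`: a list with elements
#'   `label`, `p0`, `p_t`, `alpha`, `stage_sizes`, `anchor_size` and
#'   `efficacy`.
#'
#' @details
#' Two conditions draw a warning rather than an error, since they violate
#' recommendations rather than the arithmetic: a threshold error
#' proportion `p_t >= 0.5` (the construction assumes the monitored
#' proportion is below one half), and more than five analyses in total
#' (interims plus final), which risks inflating the type I error.
#'
#' @examples
#' # Sensitivity endpoint of a 200-participant study at 35% prevalence:
#' # interims after 15, 25 and 50 disease-positive cases, final at 70.
#' ep <- endpoint_design("FNR", p0 = 0.75, alpha = 0.05,
#'                       stage_sizes = c(15, 25, 50), anchor_size = 70)
#' boundary_set(ep)
#' @seealso [boundary_set()], [dta_design()]
#' @export
endpoint_design <- function(label = c("FNR", "FPR"), p0, alpha = 0.05,
                            stage_sizes = integer(), anchor_size,
                            efficacy = NULL) {
  label <- match.arg(label)
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("`p0` must be a single proportion strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single proportion strictly between 0 and 1",
         call. = FALSE)
  p_t <- 1 - p0
  if (p_t >= 0.5)
    warning("threshold error proportion p_t = 1 - p0 = ", format(p_t),
            " is not below 0.5; the exact group sequential construction ",
            "assumes the monitored error proportion is less than 0.5",
            call. = FALSE)
  if (length(stage_sizes)) {
    if (any(is.na(stage_sizes)) || any(stage_sizes < 1) ||
        any(stage_sizes != floor(stage_sizes)))
      stop("`stage_sizes` must be positive integers", call. = FALSE)
    if (any(diff(stage_sizes) <= 0))
      stop("`stage_sizes` must be strictly increasing", call. = FALSE)
  }
  if (length(anchor_size) != 1L || is.na(anchor_size) || anchor_size < 1 ||
      anchor_size != floor(anchor_size))
    stop("`anchor_size` must be a single positive integer", call. = FALSE)
  n_analyses <- length(stage_sizes) + 1L
  if (n_analyses > 5L)
    warning("design has ", n_analyses, " analyses (interims plus final); ",
            "using the exact group sequential method with more than five ",
            "analyses is not recommended", call. = FALSE)
  if (!is.null(efficacy)) {
    if (!is.list(efficacy) || !all(c("p_a", "beta") %in% names(efficacy)))
      stop("`efficacy` must be a list with components `p_a` and `beta`",
           call. = FALSE)
    if (efficacy$p_a < 0 || efficacy$p_a >= p_t)
      stop("`efficacy$p_a` must satisfy 0 <= p_a < p_t", call. = FALSE)
    if (efficacy$beta <= 0 || efficacy$beta >= 1)
      stop("`efficacy$beta` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(label = label, p0 = p0, p_t = p_t, alpha = alpha,
         stage_sizes = as.integer(stage_sizes),
         anchor_size = as.integer(anchor_size),
         efficacy = efficacy),
    class = "endpoint_design")
}

#' @export
print.endpoint_design <- function(x, ...) {
  scale <- if (x$label == "FNR") "sensitivity" else "specificity"
  cat("Exact group sequential endpoint design (", x$label, ")\n", sep = "")
  cat("  Accuracy threshold p0: ", format(100 * x$p0), "% ", scale,
      "  (error threshold p_t = ", format(x$p_t), ")\n", sep = "")
  cat("  One-sided alpha:       ", format(x$alpha), "\n", sep = "")
  cat("  Interim group sizes:   ",
      if (length(x$stage_sizes)) paste(x$stage_sizes, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  Final (anchor) size:   ", x$anchor_size, "\n", sep = "")
  if (!is.null(x$efficacy))
    cat("  Efficacy stopping:     enabled (p_a = ", format(x$efficacy$p_a),
        ", beta = ", format(x$efficacy$beta), ")\n", sep = "")
  invisible(x)
}

.is_endpoint_design <- function(x) inherits(x, "endpoint_design")

.check_endpoint_design <- function(design) {
  if (!.is_endpoint_design(design))
    stop("`design` must be an object created by `endpoint_design()`",
         call. = FALSE)
  invisible(design)
}
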