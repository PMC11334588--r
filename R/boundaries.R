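#' Exact group sequential futility boundary count
#'
#' Computes the stagewise failure-count boundary `r_g` for an error-rate
#' endpoint: the study stops for futility at a stage of cumulative
#' endpoint-group size `n` when the observed number of failures (false
#' negatives for an FNR endpoint, false positives for an FPR endpoint)
#' reaches `r_g` or more.  The boundary uses a final-anchored normal
#' deviate with continuity correction,
#'
#' \deqn{r_g = \lfloor n_g p_t + 0.5 + z_{1-\alpha}
#'       \sqrt{n_G\, p_t (1 - p_t)} \rfloor + 1,}
#'
#' where `n_G` is the planned final (anchor) group size.  Anchoring the
#' deviate term to `n_G` rather than `n_g` makes early stopping demand a
#' stronger level of evidence than the final analysis, which is what
#' controls the overall type I error across the planned analyses.
#'
#' When `r_g > n` the boundary cannot be reached at that stage (observing
#' every participant as a failure would still not trigger stopping); the
#' count is still returned, and on the accuracy scale the corresponding
#' boundary `1 - r_g/n` is negative, conventionally displayed as a dash.
#'
#' @param n Cumulative endpoint-group size(s) at the analysis; vectorised.
#' @param design An [endpoint_design()].
#' @return Integer vector of failure-count boundaries, one per element of
#'   `n`.  Values greater than `n` indicate an unattainable boundary.
#' @examples
#' ep <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
#'                       anchor_size = 70)
#' futility_boundary_count(c(15, 25, 50, 70), ep)
#' @export
futility_boundary_count <- function(n, design) {
  .check_endpoint_design(design)
  if (any(is.na(n)) || any(n < 1) || any(n != floor(n)))
    stop("`n` must contain positive integers", call. = FALSE)
  z <- stats::qnorm(1 - design$alpha)
  drift <- z * sqrt(design$anchor_size * design$p_t * (1 - design$p_t))
  as.integer(floor(n * design$p_t + 0.5 + drift) + 1)
}

#' Exact group sequential efficacy (acceptance) boundary count
#'
#' Mirror image of [futility_boundary_count()]: the study may stop early
#' for efficacy at a stage of size `n` when the observed failure count is
#' at or below `a_g`, computed as
#'
#' \deqn{a_g = \lceil n_g p_a - 0.5 - z_{1-\beta}
#'       \sqrt{n_G\, p_a (1 - p_a)} \rceil - 1,}
#'
#' capped at `r_g - 1` so futility and efficacy regions never overlap.
#' At the final stage the acceptance count is forced to `r_G - 1`, so the
#' final analysis always terminates with one decision or the other.
#' A negative count means efficacy stopping is unattainable at that stage
#' (even zero failures would not suffice), which always holds under
#' `p_a = 0` on finite data.
#'
#' Efficacy stopping is disabled unless the design carries `efficacy`
#' parameters; early termination for apparent adequacy is rarely
#' appropriate in DTA studies, where continuing to the target sample size
#' costs participants nothing and buys precision.
#'
#' @inheritParams futility_boundary_count
#' @return Integer vector of acceptance counts; negative values mark
#'   unattainable efficacy stopping.
#' @export
efficacy_boundary_count <- function(n, design) {
  .check_endpoint_design(design)
  if (is.null(design$efficacy))
    stop("design has no efficacy parameters; supply `efficacy = list(p_a, ",
         "beta)` to `endpoint_design()` to enable efficacy stopping",
         call. = FALSE)
  if (any(is.na(n)) || any(n < 1) || any(n != floor(n)))
    stop("`n` must contain positive integers", call. = FALSE)
  p_a <- design$efficacy$p_a
  z <- stats::qnorm(1 - design$efficacy$beta)
  drift <- z * sqrt(design$anchor_size * p_a * (1 - p_a))
  a <- as.integer(ceiling(n * p_a - 0.5 - drift) - 1)
  r <- futility_boundary_count(n, design)
  a <- pmin(a, r - 1L)
  a[n == design$anchor_size] <- r[n == design$anchor_size] - 1L
  a
}

#' Stagewise boundary set for an endpoint design
#'
#' Applies the futility (and, when enabled, efficacy) boundary
#' construction at every planned stage including the final anchor stage,
#' or at a supplied vector of observed stage sizes.  The accuracy-scale
#' boundary `1 - r_g/n_g` is the sensitivity/specificity value at or
#' below which the observed estimate triggers stopping; negative values
#' (unattainable stages) are displayed as dashes by
#' [format_boundary()] and the print method.
#'
#' @param design An [endpoint_design()].
#' @param stage_sizes Optional strictly increasing cumulative group sizes
#'   at which to evaluate the boundaries (e.g. observed accrual,
#'   which may overshoot the plan).  Defaults to the planned
#'   `c(design$stage_sizes, design$anchor_size)`.  The boundary anchor is
#'   always `design$anchor_size`, regardless of the observed sizes.
#' @return A data frame of class `"boundary_set"` with columns `stage`,
#'   `n`, `futility` (failure-count boundary), `boundary` (accuracy-scale
#'   boundary, possibly negative) and, when efficacy is enabled,
#'   `efficacy` (acceptance count, possibly negative).  The last row is
#'   the final analysis.  The generating design is kept in the
#'   `"design"` attribute.
#' @examples
#' ep <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
#'                       anchor_size = 70)
#' boundary_set(ep)
#' @export
boundary_set <- function(design, stage_sizes = NULL) {
  .check_endpoint_design(design)
  if (is.null(stage_sizes))
    stage_sizes <- c(design$stage_sizes, design$anchor_size)
  if (length(stage_sizes) > 1L && any(diff(stage_sizes) <= 0))
    stop("`stage_sizes` must be strictly increasing", call. = FALSE)
  r <- futility_boundary_count(stage_sizes, design)
  out <- data.frame(stage = seq_along(stage_sizes),
                    n = as.integer(stage_sizes),
                    futility = r,
                    boundary = 1 - r / stage_sizes)
  if (!is.null(design$efficacy)) {
    a <- efficacy_boundary_count(stage_sizes, design)
    a[length(a)] <- r[length(r)] - 1L  # final analysis always terminates
    out$efficacy <- a
  }
  attr(out, "design") <- design
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' @export
print.boundary_set <- function(x, precision = 0, ...) {
  design <- attr(x, "design")
  scale <- if (design$label == "FNR") "sensitivity" else "specificity"
  cat("Futility boundaries (", design$label, " endpoint, p0 = ",
      format(100 * design$p0), "% ", scale, ", one-sided alpha = ",
      format(design$alpha), ", anchor n = ", design$anchor_size, ")\n",
      sep = "")
  disp <- data.frame(stage = x$stage, n = x$n,
                     `stop if failures >=` = x$futility,
                     `accuracy boundary` = format_boundary(x$boundary,
                                                           precision),
                     check.names = FALSE)
  if (!is.null(x$efficacy))
    disp$`stop if failures <=` <- ifelse(x$efficacy < 0, "-",
                                         as.character(x$efficacy))
  print(disp, row.names = FALSE, ...)
  invisible(x)
}
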