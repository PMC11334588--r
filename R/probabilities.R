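#' Exact stagewise stopping probabilities
#'
#' Computes, by exact forward recursion over the cumulative failure-count
#' process, the probability that a sequentially monitored binomial
#' endpoint stops at each stage, for a given true error proportion `p`.
#' The recursion propagates the probability mass of the cumulative
#' failure count: at stage 1 the mass is the binomial distribution on
#' `n_1` trials; at each stage, mass at or beyond the futility count
#' `r_g` (and at or below the acceptance count `a_g`, when efficacy
#' stopping is enabled) is harvested as the stopping probability for that
#' stage, and the surviving mass is convolved with the binomial mass of
#' the incremental sample `n_{g+1} - n_g`.  Mass remaining after the
#' final-stage harvest is the probability of completing the study without
#' rejecting (or accepting early).
#'
#' All masses come from [stats::dbinom()], which is numerically stable;
#' no normal approximation is involved, so the results are exact up to
#' floating-point rounding.
#'
#' @param boundaries A [boundary_set()].
#' @param p True error proportion (FNR or FPR) at which to evaluate,
#'   in `[0, 1]`.
#' @return An object of class `"stagewise_prob"`: a list with elements
#'   `n` (stage sizes), `stop_futility` and `stop_efficacy` (per-stage
#'   stopping probabilities; efficacy entries are zero when disabled),
#'   `no_stop` (probability of reaching the end of the final analysis
#'   without stopping) and `p`.  The entries sum to one.
#' @examples
#' ep <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
#'                       anchor_size = 70)
#' sp <- stagewise_probabilities(boundary_set(ep), p = 0.25)
#' sum(sp$stop_futility)  # exact type I error at p = p_t
#' @seealso [exact_type_I_error()], [expected_sample_size()]
#' @export
stagewise_probabilities <- function(boundaries, p) {
  if (!inherits(boundaries, "boundary_set"))
    stop("`boundaries` must be a `boundary_set`", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single proportion in [0, 1]", call. = FALSE)
  n <- boundaries$n
  if (any(diff(n) <= 0))
    stop("stage sizes must be strictly increasing", call. = FALSE)
  r <- boundaries$futility
  a <- if (is.null(boundaries$efficacy)) rep(-1L, length(n))
       else boundaries$efficacy
  G <- length(n)
  fut <- numeric(G)
  eff <- numeric(G)
  # mass[k + 1] = P(cumulative failures == k, no stop so far)
  mass <- stats::dbinom(0:n[1], n[1], p)
  for (g in seq_len(G)) {
    if (g > 1L) {
      inc <- n[g] - n[g - 1L]
      binc <- stats::dbinom(0:inc, inc, p)
      new_mass <- numeric(n[g] + 1L)
      nz <- which(mass > 0)
      for (j in nz)
        new_mass[j:(j + inc)] <- new_mass[j:(j + inc)] + mass[j] * binc
      mass <- new_mass
    }
    if (r[g] <= n[g]) {
      idx <- (r[g] + 1L):(n[g] + 1L)
      fut[g] <- sum(mass[idx])
      mass[idx] <- 0
    }
    if (a[g] >= 0L) {
      idx <- 1:(min(a[g], n[g]) + 1L)
      eff[g] <- sum(mass[idx])
      mass[idx] <- 0
    }
  }
  structure(list(n = n, stop_futility = fut, stop_efficacy = eff,
                 no_stop = sum(mass), p = p),
            class = "stagewise_prob")
}

#' @export
print.stagewise_prob <- function(x, ...) {
  cat("Exact stagewise stopping probabilities at p =", format(x$p), "\n")
  print(data.frame(stage = seq_along(x$n), n = x$n,
                   `P(stop futility)` = signif(x$stop_futility, 6),
                   `P(stop efficacy)` = signif(x$stop_efficacy, 6),
                   check.names = FALSE), row.names = FALSE)
  cat("P(no stop):", format(signif(x$no_stop, 6)), "\n")
  invisible(x)
}

#' Exact type I error of a boundary set
#'
#' Total probability of rejecting `H0: p <= p_t` (stopping for futility
#' at any analysis, including the final one) when the true error
#' proportion equals the threshold `p_t`.  By monotonicity of the
#' rejection probability in `p`, this is the supremum of the type I
#' error over the null.  The anchored construction is approximate, so
#' this attained level generally differs slightly from the nominal
#' `alpha`; this function exposes the exact value for verification.
#'
#' @param boundaries A [boundary_set()].
#' @param p_t Threshold error proportion; defaults to the one carried by
#'   the generating design.
#' @return The exact rejection probability, a single number.
#' @examples
#' ep <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
#'                       anchor_size = 70)
#' exact_type_I_error(boundary_set(ep))
#' @export
exact_type_I_error <- function(boundaries, p_t = NULL) {
  if (is.null(p_t)) {
    design <- attr(boundaries, "design")
    if (is.null(design))
      stop("`boundaries` carries no design; supply `p_t`", call. = FALSE)
    p_t <- design$p_t
  }
  sum(stagewise_probabilities(boundaries, p_t)$stop_futility)
}

#' Expected endpoint-group sample size under sequential monitoring
#'
#' Expected number of endpoint-group participants observed before the
#' study terminates, under true error proportion `p`: the sum over stages
#' of the stage size times the probability of stopping there, with the
#' final stage also receiving the no-stop mass.  Quantifies the
#' efficiency gain from futility monitoring relative to the fixed design
#' of size `n_G`.
#'
#' @inheritParams stagewise_probabilities
#' @return A single number between `n_1` and `n_G`.
#' @examples
#' ep <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
#'                       anchor_size = 70)
#' bs <- boundary_set(ep)
#' expected_sample_size(bs, p = 0.25)  # at the threshold
#' expected_sample_size(bs, p = 0.45)  # a clearly futile test stops early
#' @export
expected_sample_size <- function(boundaries, p) {
  sp <- stagewise_probabilities(boundaries, p)
  stops <- sp$stop_futility + sp$stop_efficacy
  G <- length(sp$n)
  sum(sp$n * stops) + sp$n[G] * sp$no_stop
}
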