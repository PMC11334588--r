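# Shared designs and fixture loaders.

# simulated-study plan: 200 participants, 35% prevalence,
# p0 = 75% sensitivity / 90% specificity, one-sided alpha 0.05
sim_design_by_total <- function(...)
  dta_design(0.35, "total", c(25, 75, 150), 200,
             sens_p0 = 0.75, spec_p0 = 0.90, ...)

sim_design_by_positives <- function(...)
  dta_design(0.35, "positives", c(15, 25, 50), 70,
             sens_p0 = 0.75, spec_p0 = 0.90, ...)

# point-of-care case study: interims after 50 and 100 positive cases,
# target 150 cases, assumed prevalence 30%; MHRA product profiles
raptor_design <- function(profile = c("desirable", "acceptable")) {
  profile <- match.arg(profile)
  if (profile == "desirable")
    dta_design(0.30, "positives", c(50, 100), 150,
               sens_p0 = 0.97, spec_p0 = 0.99)
  else
    dta_design(0.30, "positives", c(50, 100), 150,
               sens_p0 = 0.80, spec_p0 = 0.95)
}

fixture_cohort <- function(name) {
  read_participants(system.file("extdata", name, package = "dtainterim"))
}

# boundary_set-like container with arbitrary counts, for oracle checks
manual_bset <- function(n, r, a = NULL) {
  out <- data.frame(stage = seq_along(n), n = as.integer(n),
                    futility = as.integer(r), boundary = 1 - r / n)
  if (!is.null(a)) out$efficacy <- as.integer(a)
  class(out) <- c("boundary_set", "data.frame")
  out
}
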