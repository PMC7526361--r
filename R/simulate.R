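#' Draw baseline covariates for one arm
#'
#' Ages come from a normal distribution truncated at the arm's bounds,
#' sampled by inverse-CDF on the truncated interval (so the random stream
#' consumes exactly one uniform per subject and results are reproducible
#' for a given seed). Menopausal status is Bernoulli and tumour grade
#' categorical with the arm's stated proportions; grades are encoded as
#' the two indicators `grade2`, `grade3` with grade 1 as reference.
#'
#' @param spec An [arm_spec()].
#' @param n Number of subjects; defaults to `spec$n`. `n = 0` returns an
#'   empty table.
#' @return A tibble with columns `age`, `postmenopausal`, `grade2`,
#'   `grade3`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_covariates(default_arm_a(), n = 5)
simulate_covariates <- function(spec, n = spec$n) {
  validate_arm_spec(spec)
  if (n == 0) {
    return(tibble(age = numeric(), postmenopausal = integer(),
                  grade2 = integer(), grade3 = integer()))
  }
  age <- rtruncnorm_icdf(n, spec$age_mean, spec$age_sd,
                         spec$age_range[1], spec$age_range[2])
  meno <- as.integer(runif(n) < spec$p_postmenopausal)
  u <- runif(n)
  grade <- 1L + (u >= spec$p_grade[1]) + (u >= spec$p_grade[1] + spec$p_grade[2])
  tibble(
    age = age,
    postmenopausal = meno,
    grade2 = as.integer(grade == 2L),
    grade3 = as.integer(grade == 3L)
  )
}

# inverse-CDF sampler for a truncated normal
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(plo + runif(n) * (phi - plo))
}

#' Linear predictor of the Weibull proportional-hazards outcome model
#'
#' Computes \eqn{x\beta} for each row of a covariate table:
#' `beta_age * age + beta_meno * postmenopausal + beta_grade2 * grade2 +
#' beta_grade3 * grade3 + treated * (beta_treatment +
#' beta_interaction * postmenopausal)`.
#'
#' @param covariates Tibble with columns `age`, `postmenopausal`,
#'   `grade2`, `grade3` (as from [simulate_covariates()]).
#' @param spec The [arm_spec()] supplying the coefficients.
#' @param treated Logical flag: does this arm receive the indexed
#'   treatment (arm B)?
#' @return Numeric vector of log-hazard values, one per row.
#' @export
linear_predictor <- function(covariates, spec, treated = FALSE) {
  xb <- spec$beta_age * covariates$age +
    spec$beta_meno * covariates$postmenopausal +
    spec$beta_grade2 * covariates$grade2 +
    spec$beta_grade3 * covariates$grade3
  if (treated) {
    if (is.na(spec$beta_treatment)) {
      abort("invalid arm specification: field `beta_treatment` is required for a treated arm",
            class = "maicsim_config_error")
    }
    xb <- xb + spec$beta_treatment +
      spec$beta_interaction * covariates$postmenopausal
  }
  xb
}

#' Invert the Weibull proportional-hazards survival function
#'
#' With cumulative hazard \eqn{H(t) = \lambda t^{\gamma} e^{x\beta}} the
#' survival function is \eqn{S(t) = \exp(-\lambda t^{\gamma} e^{x\beta})};
#' setting \eqn{S(T) = u} and solving gives
#' \eqn{T = (-\ln u / (\lambda e^{x\beta}))^{1/\gamma}}. `T` is monotone
#' decreasing in `u` (u = 1 maps to T = 0) and strictly decreasing in
#' `xb` at fixed `u`.
#'
#' @param xb Linear-predictor value(s), recycled against `u`.
#' @param spec The [arm_spec()] supplying `weibull_scale` and
#'   `weibull_shape`.
#' @param u Uniform(0, 1] draw(s). `u = 0` is rejected (infinite time).
#' @return Latent event time(s) in days.
#' @export
#' @examples
#' spec <- default_arm_a()
#' simulate_event_time(0, spec, exp(-1)) # S(T) = exp(-1)
simulate_event_time <- function(xb, spec, u) {
  if (any(u <= 0) || any(u > 1)) {
    abort("invalid uniform draw: `u` must lie in (0, 1]",
          class = "maicsim_domain_error")
  }
  (-log(u) / (spec$weibull_scale * exp(xb)))^(1 / spec$weibull_shape)
}

#' Apply uniform random censoring
#'
#' Censoring times are Uniform(0, `censor_upper`) capped at
#' `max_followup`, independent of covariates and treatment. With the
#' default `censor_upper = max_followup` this is censoring uniform over
#' the whole follow-up window and the horizon is enforced by the upper
#' bound itself; a wider `censor_upper` gives lighter random censoring
#' plus administrative censoring at the horizon.
#'
#' @param latent_time Latent event time(s) in days.
#' @param spec The [arm_spec()] supplying `censor_upper` and
#'   `max_followup`.
#' @param u Optional uniform draws (one per subject) for the censoring
#'   times; drawn from the current RNG stream when omitted.
#' @return A tibble with columns `time` (observed, days) and `event`
#'   (1 = event observed, 0 = censored).
#' @export
apply_censoring <- function(latent_time, spec, u = runif(length(latent_time))) {
  cens <- pmin(u * (spec$censor_upper %||% spec$max_followup),
               spec$max_followup)
  tibble(
    time = pmin(latent_time, cens),
    event = as.integer(latent_time <= cens)
  )
}

#' Simulate one complete trial arm
#'
#' Composes covariate simulation, the linear predictor, Weibull event-time
#' inversion and uniform censoring into a patient-level table. Given the
#' same seed and specification the output is identical on re-run.
#'
#' @param spec An [arm_spec()].
#' @param treated Logical: is this the indexed-treatment (B) arm?
#' @param arm Arm label stored in the output (defaults to `"B"` when
#'   `treated` else `"A"`).
#' @param seed Optional integer seed applied via [set.seed()] before any
#'   draws; leave `NULL` to use the current RNG state.
#' @return A tibble of patient records with columns `arm`, `age`,
#'   `postmenopausal`, `grade2`, `grade3`, `treated`, `latent_time`,
#'   `time`, `event`.
#' @export
#' @examples
#' simulate_arm(default_arm_b(1), treated = TRUE, seed = 42)
simulate_arm <- function(spec, treated = FALSE,
                         arm = if (treated) "B" else "A", seed = NULL) {
  validate_arm_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  cov <- simulate_covariates(spec)
  if (nrow(cov) == 0) {
    return(tibble(arm = character(), age = numeric(),
                  postmenopausal = integer(), grade2 = integer(),
                  grade3 = integer(), treated = integer(),
                  latent_time = numeric(), time = numeric(),
                  event = integer()))
  }
  xb <- linear_predictor(cov, spec, treated = treated)
  latent <- simulate_event_time(xb, spec, u = runif(nrow(cov)))
  obs <- apply_censoring(latent, spec, u = runif(nrow(cov)))
  tibble(
    arm = arm,
    age = cov$age,
    postmenopausal = cov$postmenopausal,
    grade2 = cov$grade2,
    grade3 = cov$grade3,
    treated = as.integer(treated),
    latent_time = latent,
    time = obs$time,
    event = obs$event
  )
}
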