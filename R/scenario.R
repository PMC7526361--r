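#' Specify the generative model for one single-arm trial
#'
#' An arm specification bundles everything needed to simulate one arm of a
#' hypothetical single-arm breast-cancer trial: the baseline covariate
#' distributions (age, menopausal status, tumour grade), the Weibull
#' baseline hazard, the log-hazard-ratio coefficients of the proportional
#' hazards outcome model, and the censoring horizon.
#'
#' The outcome model is a Weibull proportional-hazards model with cumulative
#' hazard \eqn{H(t) = \lambda t^{\gamma} e^{x\beta}}: `weibull_scale` is
#' \eqn{\lambda} (per day^gamma) and `weibull_shape` is \eqn{\gamma}. The
#' linear predictor is
#' \deqn{x\beta = \beta_{age} \cdot age + \beta_{meno} \cdot meno +
#'   \beta_{g2} I(grade=2) + \beta_{g3} I(grade=3) +
#'   treated \cdot (\beta_{trt} + \beta_{trt \times meno} \cdot meno).}
#'
#' @param n Number of subjects.
#' @param age_mean,age_sd Mean and standard deviation (years) of the
#'   underlying (untruncated) normal age distribution.
#' @param age_range Length-2 numeric, lower and upper truncation bounds for
#'   age in years.
#' @param p_postmenopausal Proportion postmenopausal.
#' @param p_grade Length-3 numeric, proportions of tumour grades 1, 2, 3
#'   (must sum to 1; grade 1 is the reference level downstream).
#' @param weibull_scale,weibull_shape Weibull baseline parameters
#'   \eqn{\lambda} and \eqn{\gamma}.
#' @param beta_age,beta_meno,beta_grade2,beta_grade3 Log-hazard-ratio
#'   coefficients of the prognostic factors.
#' @param beta_treatment Log hazard ratio of the treatment indicator
#'   (`NA` for an arm that is never the comparator, i.e. arm A).
#' @param beta_interaction Log-hazard-ratio coefficient of the
#'   treatment-by-menopause interaction (effect modification); 0 when the
#'   covariate is purely prognostic.
#' @param max_followup Follow-up horizon in days; random censoring is
#'   uniform on (0, `censor_upper`) capped at `max_followup`.
#' @param censor_upper Upper bound (days) of the uniform censoring draw
#'   before capping at `max_followup`. The default equals
#'   `max_followup`, giving censoring times uniform on the whole
#'   follow-up window; a larger value yields lighter random censoring
#'   plus administrative censoring at the horizon.
#'
#' @return An object of class `arm_spec` (a named list).
#' @seealso [scenario_spec()] for the two shipped study scenarios.
#' @export
#' @examples
#' arm_spec(
#'   n = 100, age_mean = 53, age_sd = 11, age_range = c(21, 80),
#'   p_postmenopausal = 0.4, p_grade = c(0.2, 0.65, 0.15)
#' )
arm_spec <- function(n,
                     age_mean,
                     age_sd,
                     age_range,
                     p_postmenopausal,
                     p_grade,
                     weibull_scale = 4e-8,
                     weibull_shape = 2.2,
                     beta_age = 0.02,
                     beta_meno = 0.5,
                     beta_grade2 = 0.3,
                     beta_grade3 = 0.6,
                     beta_treatment = NA_real_,
                     beta_interaction = 0,
                     max_followup = 2500,
                     censor_upper = max_followup) {
  spec <- structure(
    list(
      n = n, age_mean = age_mean, age_sd = age_sd,
      age_range = as.numeric(age_range),
      p_postmenopausal = p_postmenopausal,
      p_grade = as.numeric(p_grade),
      weibull_scale = weibull_scale, weibull_shape = weibull_shape,
      beta_age = beta_age, beta_meno = beta_meno,
      beta_grade2 = beta_grade2, beta_grade3 = beta_grade3,
      beta_treatment = beta_treatment,
      beta_interaction = beta_interaction,
      max_followup = max_followup,
      censor_upper = censor_upper
    ),
    class = "arm_spec"
  )
  validate_arm_spec(spec)
}

validate_arm_spec <- function(spec) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid arm specification: field `%s` %s", field, msg),
          class = "maicsim_config_error")
  }
  chk_num <- function(field, len = 1L) {
    x <- spec[[field]]
    if (!is.numeric(x) || length(x) != len || anyNA(x) && field != "beta_treatment") {
      stop_field(field, "must be numeric and non-missing")
    }
    x
  }
  n <- chk_num("n")
  if (n < 0 || n != round(n)) stop_field("n", "must be a non-negative integer")
  if (chk_num("age_sd") <= 0) stop_field("age_sd", "must be > 0")
  chk_num("age_mean")
  rng <- spec$age_range
  if (length(rng) != 2L || anyNA(rng) || rng[1] >= rng[2]) {
    stop_field("age_range", "must be c(lower, upper) with lower < upper")
  }
  p <- chk_num("p_postmenopausal")
  if (p < 0 || p > 1) stop_field("p_postmenopausal", "must be in [0, 1]")
  pg <- spec$p_grade
  if (length(pg) != 3L || anyNA(pg) || any(pg < 0) || any(pg > 1)) {
    stop_field("p_grade", "must be three proportions in [0, 1]")
  }
  if (abs(sum(pg) - 1) > 1e-12) stop_field("p_grade", "must sum to 1")
  if (chk_num("weibull_scale") <= 0) stop_field("weibull_scale", "must be > 0")
  if (chk_num("weibull_shape") <= 0) stop_field("weibull_shape", "must be > 0")
  if (chk_num("max_followup") <= 0) stop_field("max_followup", "must be > 0")
  if (chk_num("censor_upper") <= 0) stop_field("censor_upper", "must be > 0")
  for (f in c("beta_age", "beta_meno", "beta_grade2", "beta_grade3",
              "beta_interaction")) chk_num(f)
  spec
}

#' @export
print.arm_spec <- function(x, ...) {
  cat("<arm_spec>\n")
  cat(sprintf("  n = %d; age ~ TN(%g, %g^2) on [%g, %g]\n",
              x$n, x$age_mean, x$age_sd, x$age_range[1], x$age_range[2]))
  cat(sprintf("  P(postmenopausal) = %g; P(grade 1/2/3) = %g/%g/%g\n",
              x$p_postmenopausal, x$p_grade[1], x$p_grade[2], x$p_grade[3]))
  cat(sprintf("  Weibull: scale %g, shape %g; follow-up %g days\n",
              x$weibull_scale, x$weibull_shape, x$max_followup))
  cat(sprintf("  logHR: age %g, meno %g, grade2 %g, grade3 %g, trt %s, trt:meno %g\n",
              x$beta_age, x$beta_meno, x$beta_grade2, x$beta_grade3,
              ifelse(is.na(x$beta_treatment), "NA", format(x$beta_treatment)),
              x$beta_interaction))
  invisible(x)
}

#' Default arm specifications for the two shipped study scenarios
#'
#' `default_arm_a()` is the trial with accessible individual-patient data
#' (n = 1000, healthier population); `default_arm_b()` is the comparator
#' trial published only as aggregates plus a Kaplan-Meier figure (n = 800,
#' more severe population). In scenario 1 the treatment effect is a pure
#' log hazard ratio of -0.5; in scenario 2 the same total effect is split
#' into a main effect of -0.4 plus a -0.2 interaction with menopausal
#' status (making menopause an effect modifier), so the expected treatment
#' effect is -0.5 in both scenarios.
#'
#' @param scenario_id Integer, 1 (no effect modifier) or 2 (menopausal
#'   status modifies the treatment effect).
#' @return An [arm_spec()].
#' @export
default_arm_a <- function() {
  arm_spec(
    n = 1000, age_mean = 53, age_sd = 11, age_range = c(21, 80),
    p_postmenopausal = 0.40, p_grade = c(0.20, 0.65, 0.15)
  )
}

#' @rdname default_arm_a
#' @export
default_arm_b <- function(scenario_id = 1) {
  arm_spec(
    n = 800, age_mean = 56, age_sd = 12, age_range = c(23, 85),
    p_postmenopausal = 0.50, p_grade = c(0.10, 0.70, 0.20),
    beta_treatment = if (scenario_id == 1) -0.5 else -0.4,
    beta_interaction = if (scenario_id == 1) 0 else -0.2
  )
}

#' Assemble a study scenario
#'
#' A scenario couples the two arm specifications with the true marginal
#' treatment effect targeted by the evaluation module (log hazard ratio
#' -0.5 in both shipped scenarios).
#'
#' @param scenario_id 1 or 2, see [default_arm_a()].
#' @param arm_a,arm_b Optional [arm_spec()] overrides.
#' @param true_log_hr True treatment effect on the log-hazard-ratio scale.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec(2)
scenario_spec <- function(scenario_id,
                          arm_a = default_arm_a(),
                          arm_b = default_arm_b(scenario_id),
                          true_log_hr = -0.5) {
  if (!scenario_id %in% c(1, 2)) {
    abort("invalid scenario: field `scenario_id` must be 1 or 2",
          class = "maicsim_config_error")
  }
  validate_arm_spec(arm_a)
  validate_arm_spec(arm_b)
  if (is.na(arm_b$beta_treatment)) {
    abort("invalid scenario: field `arm_b$beta_treatment` must be set",
          class = "maicsim_config_error")
  }
  structure(
    list(scenario_id = scenario_id, arm_a = arm_a, arm_b = arm_b,
         true_log_hr = true_log_hr),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> scenario %d, true logHR %g\n",
              x$scenario_id, x$true_log_hr))
  cat("-- arm A (IPD) --\n"); print(x$arm_a)
  cat("-- arm B (published) --\n"); print(x$arm_b)
  invisible(x)
}
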