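#' Monte Carlo performance metrics of a log-hazard-ratio estimator
#'
#' Given the per-repetition estimates of one strategy, computes
#' \itemize{
#'   \item bias: \eqn{\frac{1}{N}\sum_j (\log\hat{HR}_j - \theta)};
#'   \item Monte-Carlo variance (MCV, the squared empirical standard
#'     error): \eqn{\frac{1}{N-1}\sum_j (\log\hat{HR}_j -
#'     \overline{\log\hat{HR}})^2};
#'   \item mean squared error: \eqn{\frac{1}{N}\sum_j (\log\hat{HR}_j -
#'     \theta)^2};
#'   \item CI coverage: the percentage of repetitions whose confidence
#'     interval (on the HR scale) contains \eqn{e^{\theta}};
#'   \item mean effective sample size.
#' }
#' These satisfy the identity `mse = bias^2 + (N-1)/N * mcv` exactly.
#'
#' @param log_hr Numeric vector of per-repetition log-HR estimates.
#' @param ci_low,ci_high Per-repetition confidence limits on the HR
#'   scale (optional; coverage is `NA` when omitted).
#' @param ess Per-repetition effective sample sizes (optional).
#' @param truth True log hazard ratio (default -0.5).
#' @return A one-row tibble: `n`, `bias`, `mcv`, `mse`,
#'   `ci_coverage_pct`, `mean_ess`.
#' @export
#' @examples
#' performance_metrics(c(-0.4, -0.6)) # bias 0, mcv 0.02, mse 0.01
performance_metrics <- function(log_hr, ci_low = NULL, ci_high = NULL,
                                ess = NULL, truth = -0.5) {
  keep <- is.finite(log_hr)
  log_hr <- log_hr[keep]
  n <- length(log_hr)
  if (n < 2) {
    abort("at least two converged estimates are required",
          class = "maicsim_domain_error")
  }
  coverage <- if (is.null(ci_low) || is.null(ci_high)) {
    NA_real_
  } else {
    100 * mean(ci_low[keep] <= exp(truth) & exp(truth) <= ci_high[keep])
  }
  tibble(
    n = n,
    bias = mean(log_hr - truth),
    mcv = sum((log_hr - mean(log_hr))^2) / (n - 1),
    mse = sum((log_hr - truth)^2) / n,
    ci_coverage_pct = coverage,
    mean_ess = if (is.null(ess)) NA_real_ else mean(ess[keep])
  )
}

#' Bias factor of an omitted dichotomous confounder
#'
#' VanderWeele's bound on the ratio of the observed to the true hazard
#' ratio when a binary confounder U is omitted:
#' \deqn{BF = \frac{HR_{UD} \times RR_{EU}}{HR_{UD} + RR_{EU} - 1}}
#' where \eqn{HR_{UD}} is the maximal effect of U on the outcome and
#' \eqn{RR_{EU}} the risk ratio of U = 1 between the exposed and
#' unexposed populations. The factor equals 1 when either argument is 1
#' and is monotone increasing in each argument above 1.
#'
#' @param hr_ud Maximal hazard ratio of the confounder on the outcome
#'   (> 0).
#' @param rr_eu Prevalence ratio of the confounder across populations
#'   (> 0); `hr_ud + rr_eu` must exceed 1.
#' @return A single number.
#' @export
#' @examples
#' bias_factor(2, 2) # 4/3
#' bias_factor(exp(0.3), 0.50 / 0.40) # about 1.05
bias_factor <- function(hr_ud, rr_eu) {
  if (hr_ud <= 0 || rr_eu <= 0 || hr_ud + rr_eu <= 1) {
    abort("bias factor requires hr_ud > 0, rr_eu > 0 and hr_ud + rr_eu > 1",
          class = "maicsim_domain_error")
  }
  (hr_ud * rr_eu) / (hr_ud + rr_eu - 1)
}

#' Bias-factor parameters implied by a scenario's generative model
#'
#' Takes menopausal status as the omitted confounder U: `hr_ud` is the
#' exponentiated effect of U on the outcome among treated subjects
#' (main effect plus treatment interaction) and `rr_eu` the ratio of
#' postmenopausal prevalence in the comparator versus the IPD
#' population.
#'
#' @param scenario A [scenario_spec()].
#' @return A list with `hr_ud`, `rr_eu`, `bias_factor`.
#' @export
#' @examples
#' scenario_bias_factor(scenario_spec(2))$bias_factor # about 1.05
scenario_bias_factor <- function(scenario) {
  hr_ud <- exp(scenario$arm_b$beta_meno + scenario$arm_b$beta_interaction)
  rr_eu <- scenario$arm_b$p_postmenopausal / scenario$arm_a$p_postmenopausal
  list(hr_ud = hr_ud, rr_eu = rr_eu,
       bias_factor = bias_factor(hr_ud, rr_eu))
}

#' Divide an estimate and its lower limit by a bias factor
#'
#' Implements the adjustment \eqn{\hat{HR}/BF} and \eqn{LL_{\hat{HR}}/BF}
#' used to gauge the plausible true effect when the weighting model may
#' have omitted a confounder that makes the treatment look worse than it
#' is (BF >= 1 by the direction convention).
#'
#' @param hr Hazard-ratio point estimate(s).
#' @param ci_low Lower 95 percent confidence limit(s) on the HR scale.
#' @param bf Bias factor, must be >= 1.
#' @return A tibble with columns `adjusted_hr`, `adjusted_ll`.
#' @export
#' @examples
#' adjust_estimate(0.63, 0.5, 1.05)
adjust_estimate <- function(hr, ci_low, bf) {
  if (bf < 1) {
    abort("bias factor below 1 violates the adjustment's direction convention",
          class = "maicsim_domain_error")
  }
  tibble(adjusted_hr = hr / bf, adjusted_ll = ci_low / bf)
}
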