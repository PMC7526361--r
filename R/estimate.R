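#' Pooled weighted Cox estimate of the B-versus-A hazard ratio
#'
#' Stacks the (re)weighted IPD arm with the reconstructed comparator arm
#' and fits a Cox model on the treatment indicator alone. IPD subjects
#' carry their balancing weights, reconstructed subjects carry unit
#' weights; the variance is the robust sandwich estimator (weights
#' treated as sampling weights) and the 95 percent confidence interval
#' is Wald on the log-hazard-ratio scale. Ties are handled by the
#' Breslow approximation.
#'
#' @param arm_a Patient-record tibble of the IPD arm (columns `time`,
#'   `event`).
#' @param arm_b Reconstructed (or raw) comparator records with columns
#'   `time`, `event`.
#' @param weights Either a [entropy_balance()] result, a numeric vector
#'   of per-subject weights for `arm_a`, or `NULL` for unit weights.
#' @param arm_b_weights Per-subject weights for the comparator arm,
#'   unit by default. The estimate is invariant to rescaling all
#'   weights (both arms) by a common positive constant; rescaling one
#'   arm alone changes its contribution to the risk sets and is not an
#'   equivalent analysis.
#' @param strategy Label stored in the result.
#' @return A one-row tibble: `strategy`, `log_hr`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `ess`, `converged`.
#' @export
pooled_weighted_cox <- function(arm_a, arm_b, weights = NULL,
                                arm_b_weights = NULL,
                                strategy = NA_character_) {
  if (nrow(arm_a) == 0 || nrow(arm_b) == 0) {
    abort("both arms must be nonempty", class = "maicsim_domain_error")
  }
  ess_val <- NA_real_
  if (inherits(weights, "maic_weights")) {
    ess_val <- weights$ess
    weights <- weights$weights
  }
  if (is.null(weights)) weights <- rep(1, nrow(arm_a))
  if (length(weights) != nrow(arm_a)) {
    abort("one weight per IPD subject is required",
          class = "maicsim_domain_error")
  }
  if (is.null(arm_b_weights)) arm_b_weights <- rep(1, nrow(arm_b))
  flagged <- tibble(strategy = strategy, log_hr = NA_real_, se = NA_real_,
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    ess = ess_val, converged = FALSE)
  if (sum(arm_a$event) == 0 || sum(arm_b$event) == 0) return(flagged)
  pooled <- dplyr::bind_rows(
    tibble(time = arm_a$time, event = arm_a$event, treated = 0L, w = weights),
    tibble(time = arm_b$time, event = arm_b$event, treated = 1L,
           w = arm_b_weights)
  ) |>
    dplyr::filter(.data$time > 0)
  fit <- suppressWarnings(tryCatch(
    survival::coxph(survival::Surv(time, event) ~ treated, data = pooled,
                    weights = w, robust = TRUE, ties = "breslow"),
    error = function(e) NULL
  ))
  if (is.null(fit) || !all(is.finite(fit$coefficients)) ||
      !all(is.finite(fit$var))) {
    return(flagged)
  }
  log_hr <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1]) # robust variance when robust = TRUE
  z <- qnorm(0.975)
  tibble(
    strategy = strategy, log_hr = log_hr, se = se, hr = exp(log_hr),
    ci_low = exp(log_hr - z * se), ci_high = exp(log_hr + z * se),
    ess = ess_val, converged = TRUE
  )
}

#' Run the unanchored-MAIC weighting strategies of one repetition
#'
#' Executes the per-scenario strategy list: an unweighted analysis, the
#' fully weighted analysis (all prognostic factors balanced), and the
#' partially weighted analyses that omit the menopause indicator and/or
#' the tumour-grade indicators from the weighting model. Scenario 1
#' evaluates `unweighted`, `all`, `omit_menopause_grade` (the
#' `omit_menopause` strategy can be added for the bias-factor
#' adjustment); scenario 2 evaluates `unweighted`, `all`,
#' `omit_menopause`, `omit_menopause_grade`.
#'
#' @param arm_a IPD-arm patient records.
#' @param publication The comparator's [publish()] object (source of the
#'   aggregate balance targets).
#' @param recon Reconstructed comparator records from [reconstruct()].
#' @param scenario_id 1 or 2.
#' @param extra_strategies Additional strategy labels to run beyond the
#'   scenario's default list.
#' @return A tibble with one row per strategy, as from
#'   [pooled_weighted_cox()].
#' @export
run_strategies <- function(arm_a, publication, recon, scenario_id,
                           extra_strategies = character(0)) {
  strategies <- if (scenario_id == 1) {
    c("unweighted", "all", "omit_menopause_grade")
  } else {
    c("unweighted", "all", "omit_menopause", "omit_menopause_grade")
  }
  strategies <- unique(c(strategies, extra_strategies))
  purrr::map_dfr(strategies, function(st) {
    if (st == "unweighted") {
      pooled_weighted_cox(arm_a, recon, weights = NULL, strategy = st)
    } else {
      w <- tryCatch(
        entropy_balance(arm_a, balance_target(publication$aggregates, st)),
        error = function(e) NULL
      )
      if (is.null(w)) {
        tibble(strategy = st, log_hr = NA_real_, se = NA_real_,
               hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               ess = NA_real_, converged = FALSE)
      } else {
        pooled_weighted_cox(arm_a, recon, weights = w, strategy = st)
      }
    }
  })
}
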