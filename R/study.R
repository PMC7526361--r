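#' Run the full Monte Carlo evaluation of unanchored MAIC
#'
#' For each repetition: simulate the IPD arm (A) and the comparator arm
#' (B); turn B into its published artefacts (digitized Kaplan-Meier
#' curve, numbers-at-risk table, aggregates); reconstruct pseudo-IPD
#' from the publication; optionally validate the reconstruction against
#' the raw B data; estimate the B-versus-A hazard ratio under every
#' weighting strategy; and apply the bias-factor adjustment to the
#' strategy that omits the menopause indicator. Aggregates the
#' repetitions into per-strategy performance metrics, reconstruction
#' validation summaries and bias-factor summaries.
#'
#' Repetition seeds are derived deterministically from `seed`, so the
#' whole study is reproducible bit-for-bit from the master seed. A
#' repetition whose Cox fit or balancing solver fails is logged and
#' excluded from the aggregates (never imputed); a warning is raised if
#' more than 5 percent of repetitions are excluded.
#'
#' @param scenario A [scenario_spec()].
#' @param n_reps Number of Monte Carlo repetitions (>= 2).
#' @param seed Master seed (integer).
#' @param risk_times Reporting grid of the published numbers-at-risk
#'   table.
#' @param surv_digits,time_digits Digitization fidelity, see
#'   [extract_curve()].
#' @param publish_events Whether the publication includes the total
#'   event count.
#' @param validate Fit the reconstruction-validation Cox model each
#'   repetition? (The time-varying term makes this the most expensive
#'   step; disable when only the MAIC estimates are needed.)
#' @param adjust_strategy Strategy whose estimates receive the
#'   bias-factor adjustment (default `"omit_menopause"`; added to the
#'   scenario-1 strategy list when absent).
#' @param tt_form Time-varying-effect form for the validation model.
#' @param log_file Optional path; when given, one JSON line per
#'   repetition (seed, convergence flags, exclusion reasons) is
#'   appended there.
#' @param progress Print a progress message every 50 repetitions?
#' @return An object of class `maic_study`; see [tidy.maic_study()],
#'   [glance.maic_study()], [report_tables()].
#' @export
#' @examples
#' \donttest{
#' st <- run_study(scenario_spec(1), n_reps = 5, seed = 1, validate = FALSE)
#' tidy(st)
#' }
run_study <- function(scenario, n_reps, seed = 1L,
                      risk_times = seq(0, 2500, by = 500),
                      surv_digits = 4, time_digits = 0,
                      publish_events = TRUE,
                      validate = TRUE,
                      adjust_strategy = "omit_menopause",
                      tt_form = "linear",
                      log_file = NULL,
                      progress = FALSE) {
  if (n_reps < 2) {
    abort("at least two repetitions are required",
          class = "maicsim_config_error")
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  bf <- scenario_bias_factor(scenario)
  extra <- if (scenario$scenario_id == 1 && !is.null(adjust_strategy)) {
    adjust_strategy
  } else {
    character(0)
  }

  estimates <- vector("list", n_reps)
  validations <- vector("list", n_reps)
  exclusions <- list()
  log_con <- if (!is.null(log_file)) file(log_file, open = "a") else NULL
  on.exit(if (!is.null(log_con)) close(log_con), add = TRUE)

  for (j in seq_len(n_reps)) {
    rec <- tryCatch({
      set.seed(rep_seeds[j])
      arm_a <- simulate_arm(scenario$arm_a, treated = FALSE)
      arm_b <- simulate_arm(scenario$arm_b, treated = TRUE)
      pub <- publish(arm_b, risk_times = risk_times,
                     surv_digits = surv_digits, time_digits = time_digits,
                     publish_events = publish_events)
      rcn <- reconstruct(pub)
      val <- if (validate) {
        validate_reconstruction(arm_b, rcn, tt_form = tt_form)
      } else NULL
      est <- run_strategies(arm_a, pub, rcn, scenario$scenario_id,
                            extra_strategies = extra)
      list(est = est, val = val, error = NULL)
    }, error = function(e) list(est = NULL, val = NULL,
                                error = conditionMessage(e)))
    if (is.null(rec$error)) {
      estimates[[j]] <- dplyr::mutate(rec$est, rep = j, .before = 1)
      if (!is.null(rec$val)) {
        validations[[j]] <- dplyr::mutate(rec$val, rep = j, .before = 1)
      }
    } else {
      exclusions[[length(exclusions) + 1]] <-
        list(rep = j, reason = rec$error)
    }
    if (!is.null(log_con)) {
      writeLines(jsonlite::toJSON(
        list(rep = j, seed = rep_seeds[j],
             excluded = !is.null(rec$error),
             reason = rec$error %||% ""),
        auto_unbox = TRUE), log_con)
    }
    if (progress && j %% 50 == 0) {
      message(sprintf("repetition %d/%d", j, n_reps))
    }
  }
  if (length(exclusions) > 0.05 * n_reps) {
    warning(sprintf("%d of %d repetitions excluded from aggregation",
                    length(exclusions), n_reps))
  }

  estimates <- dplyr::bind_rows(estimates)
  validations <- dplyr::bind_rows(validations)

  performance <- estimates |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$strategy) |>
    dplyr::group_modify(~ performance_metrics(
      .x$log_hr, .x$ci_low, .x$ci_high, .x$ess,
      truth = scenario$true_log_hr)) |>
    dplyr::ungroup()

  validation_summary <- if (nrow(validations) > 0) {
    ok <- dplyr::filter(validations, .data$converged)
    tibble(
      n = nrow(ok),
      mean_hr_indicator = mean(ok$hr_indicator),
      coverage_indicator_pct = 100 * mean(ok$covered_indicator),
      mean_hr_timevarying = mean(ok$hr_timevarying),
      coverage_timevarying_pct = 100 * mean(ok$covered_tv)
    )
  } else NULL

  adjusted <- NULL
  adj_rows <- if (is.null(adjust_strategy)) {
    estimates[0, ]
  } else {
    dplyr::filter(estimates, .data$strategy == adjust_strategy,
                  .data$converged)
  }
  if (nrow(adj_rows) >= 2) {
    adj <- adjust_estimate(adj_rows$hr, adj_rows$ci_low, bf$bias_factor)
    truth_hr <- exp(scenario$true_log_hr)
    adjusted <- tibble(
      strategy = adjust_strategy,
      n = nrow(adj_rows),
      hr_ud = bf$hr_ud,
      rr_eu = bf$rr_eu,
      bias_factor = bf$bias_factor,
      mean_adjusted_log_bias = mean(log(adj$adjusted_hr) -
                                      scenario$true_log_hr),
      pct_ll_below_truth = 100 * mean(adj$adjusted_ll <= truth_hr)
    )
  }

  structure(
    list(
      scenario = scenario,
      n_reps = n_reps,
      seed = seed,
      rep_seeds = rep_seeds,
      estimates = estimates,
      validations = validations,
      performance = performance,
      validation_summary = validation_summary,
      bias_adjustment = adjusted,
      exclusions = exclusions
    ),
    class = "maic_study"
  )
}

#' @export
print.maic_study <- function(x, ...) {
  cat(sprintf("<maic_study> scenario %d, %d repetitions (%d excluded), seed %d\n",
              x$scenario$scenario_id, x$n_reps, length(x$exclusions), x$seed))
  print(x$performance)
  invisible(x)
}

#' Tidy per-strategy performance of a Monte Carlo study
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @return One row per strategy: `strategy`, `n`, `bias`, `mcv`, `mse`,
#'   `ci_coverage_pct`, `mean_ess`.
#' @export
tidy.maic_study <- function(x, ...) {
  x$performance
}

#' One-row summary of a Monte Carlo study
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @export
glance.maic_study <- function(x, ...) {
  tibble(
    scenario = x$scenario$scenario_id,
    n_reps = x$n_reps,
    n_excluded = length(x$exclusions),
    n_strategies = nrow(x$performance),
    true_log_hr = x$scenario$true_log_hr
  )
}

#' Render the study's summary tables
#'
#' Formats a [run_study()] result into the three tables a report would
#' show: reconstruction validation (mean HRs of the reconstruction
#' indicator and its time-varying effect with CI-coverage-of-one
#' percentages), per-strategy estimator performance (bias, MCV, MSE, CI
#' coverage, mean ESS), and the bias-factor adjustment summary.
#'
#' @param result A [run_study()] result.
#' @return A named list of tibbles: `validation`, `performance`,
#'   `bias_adjustment`, plus `n_excluded`.
#' @export
report_tables <- function(result) {
  if (nrow(result$performance) == 0) {
    abort("no converged estimates to report", class = "maicsim_domain_error")
  }
  order_levels <- c("unweighted", "all", "omit_menopause",
                    "omit_menopause_grade")
  perf <- result$performance |>
    dplyr::arrange(match(.data$strategy, order_levels))
  list(
    validation = result$validation_summary,
    performance = perf,
    bias_adjustment = result$bias_adjustment,
    n_excluded = length(result$exclusions)
  )
}

#' Distribution of the per-repetition estimates by strategy
#'
#' Boxplots of the per-repetition log-hazard-ratio estimates with the
#' true effect marked.
#'
#' @param object A [run_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maic_study <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object$estimates, .data$converged),
    ggplot2::aes(x = .data$strategy, y = .data$log_hr)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$scenario$true_log_hr,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "log hazard ratio (B vs A)") +
    ggplot2::theme_minimal()
}
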