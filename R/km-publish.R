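#' Kaplan-Meier step-curve corners for one arm
#'
#' Wraps the product-limit estimator ([survival::survfit()]) and returns
#' the step-function corners a journal figure would show: one row per
#' distinct event time with the post-drop survival, preceded by the
#' anchor point (0, 1). Censoring times do not create rows.
#'
#' @param records Patient-record tibble with columns `time`, `event`.
#' @return A tibble with columns `time` (days) and `survival`.
#' @export
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1)))
km_estimate <- function(records) {
  if (nrow(records) == 0) {
    abort("cannot estimate a survival curve from an empty record table",
          class = "maicsim_domain_error")
  }
  if (any(records$time < 0)) {
    abort("cannot estimate a survival curve: negative times present",
          class = "maicsim_domain_error")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.type = "none")
  keep <- fit$n.event > 0
  tibble(
    time = c(0, fit$time[keep]),
    survival = c(1, fit$surv[keep])
  )
}

#' Programmatic stand-in for figure digitization
#'
#' Emulates exporting a published Kaplan-Meier curve from a digitizer:
#' times are rounded to the nearest day and survival probabilities to
#' `surv_digits` decimals. Rounding can collapse adjacent corners onto
#' the same day; ties are collapsed keeping the lower survival so the
#' curve stays a valid non-increasing step function. Set either rounding
#' argument to `NULL` (or `Inf`) for a lossless extraction.
#'
#' An optional uniform jitter on both axes mimics manual-digitization
#' error; it is off by default because the error of hand digitization is
#' unquantified.
#'
#' @param curve A curve tibble from [km_estimate()].
#' @param surv_digits Decimals kept on the survival axis (default 4).
#' @param time_digits Decimals kept on the time axis (default 0 = whole
#'   days).
#' @param jitter_time,jitter_surv Half-widths of optional uniform jitter
#'   added before rounding (days / survival units); 0 disables.
#' @return A curve tibble in the same format.
#' @export
extract_curve <- function(curve, surv_digits = 4, time_digits = 0,
                          jitter_time = 0, jitter_surv = 0) {
  time <- curve$time
  surv <- curve$survival
  if (length(time) > 1) {
    idx <- seq_along(time)[-1]
    if (jitter_time > 0) time[idx] <- time[idx] + runif(length(idx), -jitter_time, jitter_time)
    if (jitter_surv > 0) surv[idx] <- surv[idx] + runif(length(idx), -jitter_surv, jitter_surv)
  }
  if (!is.null(time_digits) && is.finite(time_digits)) time <- round(time, time_digits)
  if (!is.null(surv_digits) && is.finite(surv_digits)) surv <- round(surv, surv_digits)
  surv <- pmin(pmax(surv, 0), 1)
  surv <- cummin(surv)
  time <- cummax(time)
  out <- tibble(time = time, survival = surv) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(survival = min(.data$survival), .groups = "drop") |>
    dplyr::arrange(.data$time)
  # keep (0, 1) as the anchor even if rounding merged early corners
  if (out$time[1] != 0 || out$survival[1] != 1) {
    out <- dplyr::bind_rows(tibble(time = 0, survival = 1),
                            dplyr::filter(out, .data$time > 0))
  }
  out
}

#' Numbers-at-risk table at a reporting grid
#'
#' @param records Patient-record tibble with a `time` column.
#' @param times Reporting times in days (must include 0).
#' @return A tibble with columns `time`, `n_at_risk`, where `n_at_risk`
#'   counts subjects with observed time >= t.
#' @export
risk_table <- function(records, times = seq(0, 2500, by = 500)) {
  if (!0 %in% times) {
    abort("risk-table times must include 0", class = "maicsim_config_error")
  }
  times <- sort(unique(times))
  tibble(
    time = times,
    n_at_risk = vapply(times, function(t) sum(records$time >= t), integer(1))
  )
}

#' Aggregate baseline summary as a publication would report it
#'
#' @param records Patient-record tibble.
#' @return A one-row tibble with `mean_age`, `var_age` (sample variance),
#'   `p_postmenopausal`, `p_grade2`, `p_grade3`, `n_total`.
#' @export
aggregate_summary <- function(records) {
  tibble(
    mean_age = mean(records$age),
    var_age = var(records$age),
    p_postmenopausal = mean(records$postmenopausal),
    p_grade2 = mean(records$grade2),
    p_grade3 = mean(records$grade3),
    n_total = nrow(records)
  )
}

#' Emulate the published artefacts of a single-arm trial
#'
#' Bundles everything a typical journal article exposes about a
#' time-to-event endpoint: the digitized Kaplan-Meier step curve, the
#' numbers-at-risk table under the figure, aggregate baseline
#' characteristics, and (optionally) the total number of events.
#'
#' @inheritParams risk_table
#' @inheritParams extract_curve
#' @param risk_times Reporting grid of the numbers-at-risk table.
#' @param publish_events Should the total event count be included?
#'   Reconstruction can exploit it when the risk table is coarse.
#' @return An object of class `km_publication`: a list with elements
#'   `curve`, `risk_table`, `aggregates`, `total_events`.
#' @export
#' @examples
#' arm_b <- simulate_arm(default_arm_b(1), treated = TRUE, seed = 7)
#' publish(arm_b)
publish <- function(records, risk_times = seq(0, 2500, by = 500),
                    surv_digits = 4, time_digits = 0,
                    jitter_time = 0, jitter_surv = 0,
                    publish_events = TRUE) {
  curve <- km_estimate(records) |>
    extract_curve(surv_digits = surv_digits, time_digits = time_digits,
                  jitter_time = jitter_time, jitter_surv = jitter_surv)
  structure(
    list(
      curve = curve,
      risk_table = risk_table(records, risk_times),
      aggregates = aggregate_summary(records),
      total_events = if (publish_events) sum(records$event) else NA_integer_
    ),
    class = "km_publication"
  )
}

#' @export
print.km_publication <- function(x, ...) {
  cat(sprintf("<km_publication> n = %d, %d curve corners, %d risk times, %s events\n",
              x$aggregates$n_total, nrow(x$curve), nrow(x$risk_table),
              ifelse(is.na(x$total_events), "unpublished", x$total_events)))
  invisible(x)
}

#' Plot a published Kaplan-Meier curve with its risk table grid
#'
#' @param object A `km_publication`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_publication <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = object$risk_table$time,
                        linetype = "dotted", colour = "grey60") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Recurrence-free survival") +
    ggplot2::theme_minimal()
}
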