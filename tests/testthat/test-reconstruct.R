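test_that("reconstruction is exact when the publication is lossless and uncensored", {
  rec <- integer_time_records(n = 60)
  pub <- publish(rec |> dplyr::mutate(age = 50, postmenopausal = 0L,
                                      grade2 = 0L, grade3 = 0L),
                 risk_times = c(0, sort(unique(rec$time))),
                 surv_digits = NULL, time_digits = NULL)
  out <- reconstruct(pub)
  expect_equal(nrow(out), 60)
  expect_true(all(out$event == 1))
  expect_equal(sort(out$time), sort(rec$time))
})

test_that("lossless-regime reconstruction recovers event times and interval censor counts", {
  set.seed(19)
  raw <- simulate_arm(tiny_arm_b(n = 90), treated = TRUE, seed = 19) |>
    dplyr::mutate(time = round(time)) # integer days so extraction is lossless
  grid <- c(0, sort(unique(raw$time)))
  pub <- publish(raw, risk_times = grid, surv_digits = NULL, time_digits = NULL)
  out <- reconstruct(pub)
  expect_equal(nrow(out), 90)
  expect_equal(sum(out$event), sum(raw$event))
  # event-time multiset recovered exactly
  expect_equal(sort(out$time[out$event == 1]), sort(raw$time[raw$event == 1]))
  # censor counts agree within every risk-table interval
  cuts <- c(grid, Inf)
  bin <- function(t) cut(t, cuts, right = FALSE)
  expect_equal(
    as.vector(table(bin(out$time[out$event == 0]))),
    as.vector(table(bin(raw$time[raw$event == 0])))
  )
})

test_that("a flat curve reconstructs as all-censored records", {
  rec <- tibble::tibble(arm = "B", age = 50, postmenopausal = 0L, grade2 = 0L,
                        grade3 = 0L, treated = 1L,
                        time = c(100, 700, 1900, 2400), event = 0L)
  pub <- publish(rec)
  out <- reconstruct(pub)
  expect_equal(nrow(out), 4)
  expect_true(all(out$event == 0))
})

test_that("default-fidelity round trip stays within survival tolerance 0.005", {
  raw <- simulate_arm(default_arm_b(1), treated = TRUE, seed = 404)
  pub <- publish(raw)
  out <- reconstruct(pub)
  expect_equal(nrow(out), pub$risk_table$n_at_risk[1])
  km <- km_estimate(out)
  step <- approxfun(km$time, km$survival, method = "constant", rule = 2)
  expect_lt(max(abs(step(pub$curve$time) - pub$curve$survival)), 0.005)
  expect_identical(attr(out, "provenance"), "reconstructed")
})

test_that("inconsistent publications are rejected before reconstruction", {
  raw <- simulate_arm(tiny_arm_b(), treated = TRUE, seed = 5)
  pub <- publish(raw)
  bad1 <- pub; bad1$curve$survival[2] <- 1.2
  expect_error(reconstruct(bad1), "invalid publication")
  bad2 <- pub; bad2$risk_table$n_at_risk <- rev(bad2$risk_table$n_at_risk)
  expect_error(reconstruct(bad2), "invalid publication")
  bad3 <- pub; bad3$curve$survival <- rev(bad3$curve$survival)
  expect_error(reconstruct(bad3), "invalid publication")
})

test_that("validation on duplicated data gives hazard ratios of exactly one", {
  raw <- simulate_arm(tiny_arm_b(n = 100), treated = TRUE, seed = 51)
  dup <- tibble::tibble(time = raw$time, event = raw$event)
  v <- validate_reconstruction(raw, dup)
  expect_true(v$converged)
  expect_equal(v$hr_indicator, 1, tolerance = 1e-6)
  expect_equal(v$hr_timevarying, 1, tolerance = 1e-6)
  expect_true(v$covered_indicator && v$covered_tv)
})

test_that("collapsed partial-likelihood engine matches the survival package", {
  raw <- simulate_arm(tiny_arm_b(n = 120), treated = TRUE, seed = 77)
  out <- reconstruct(publish(raw))
  v_fast <- validate_reconstruction(raw, out, engine = "collapsed")
  v_surv <- validate_reconstruction(raw, out, engine = "survival")
  expect_equal(v_fast$hr_indicator, v_surv$hr_indicator, tolerance = 1e-8)
  expect_equal(v_fast$hr_timevarying, v_surv$hr_timevarying, tolerance = 1e-10)
  expect_equal(v_fast$ci_low_indicator, v_surv$ci_low_indicator,
               tolerance = 1e-8)
  expect_equal(v_fast$ci_high_tv, v_surv$ci_high_tv, tolerance = 1e-10)

  # and under the log-time form as well
  v_fast_log <- validate_reconstruction(raw, out, tt_form = "log",
                                        engine = "collapsed")
  v_surv_log <- validate_reconstruction(raw, out, tt_form = "log",
                                        engine = "survival")
  expect_equal(v_fast_log$hr_timevarying, v_surv_log$hr_timevarying,
               tolerance = 1e-8)
})
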