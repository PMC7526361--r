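# small-scale arm specifications used across tests (full-size defaults are
# exercised in test-acceptance.R)

tiny_arm_a <- function(n = 150) {
  arm_spec(
    n = n, age_mean = 53, age_sd = 11, age_range = c(21, 80),
    p_postmenopausal = 0.40, p_grade = c(0.20, 0.65, 0.15)
  )
}

tiny_arm_b <- function(n = 120, scenario = 1) {
  arm_spec(
    n = n, age_mean = 56, age_sd = 12, age_range = c(23, 85),
    p_postmenopausal = 0.50, p_grade = c(0.10, 0.70, 0.20),
    beta_treatment = if (scenario == 1) -0.5 else -0.4,
    beta_interaction = if (scenario == 1) 0 else -0.2
  )
}

# records with integer event times and no censoring: the regime in which
# publication + reconstruction is an exact round trip
integer_time_records <- function(n = 60, seed = 421, max_day = 400) {
  set.seed(seed)
  tibble::tibble(
    time = as.numeric(sample.int(max_day, n, replace = TRUE)),
    event = 1L
  )
}

# closed-form survival under the generative Weibull model
weibull_surv <- function(t, xb, scale = 4e-8, shape = 2.2) {
  exp(-scale * t^shape * exp(xb))
}
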