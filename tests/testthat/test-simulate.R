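test_that("covariate sampler matches the truncated-normal and categorical targets", {
  spec <- tiny_arm_a(n = 4000)
  set.seed(11)
  cov <- simulate_covariates(spec)
  expect_equal(nrow(cov), 4000)
  expect_true(all(cov$age >= 21 & cov$age <= 80))
  expect_true(all(cov$grade2 * cov$grade3 == 0)) # mutually exclusive

  # truncated-normal mean by the closed form
  a <- (21 - 53) / 11; b <- (80 - 53) / 11
  tn_mean <- 53 + 11 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  tn_var <- 11^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / (pnorm(b) - pnorm(a)) -
                      ((dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)))^2)
  expect_equal(mean(cov$age), tn_mean, tolerance = 4 * sqrt(tn_var / 4000) / tn_mean)

  # indicator proportions within 4 binomial standard errors
  for (col_p in list(c("postmenopausal", 0.40), c("grade2", 0.65),
                     c("grade3", 0.15))) {
    p <- as.numeric(col_p[2])
    expect_lt(abs(mean(cov[[col_p[1]]]) - p), 4 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("degenerate covariate draws behave", {
  spec <- arm_spec(n = 50, age_mean = 53, age_sd = 11, age_range = c(21, 80),
                   p_postmenopausal = 1, p_grade = c(0, 1, 0))
  set.seed(2)
  cov <- simulate_covariates(spec)
  expect_true(all(cov$postmenopausal == 1))
  expect_true(all(cov$grade2 == 1))
  expect_equal(nrow(simulate_covariates(tiny_arm_a(), n = 0)), 0)
})

test_that("invalid specifications are rejected naming the offending field", {
  base <- list(n = 10, age_mean = 53, age_sd = 11, age_range = c(21, 80),
               p_postmenopausal = 0.4, p_grade = c(0.2, 0.65, 0.15))
  expect_error(do.call(arm_spec, modifyList(base, list(n = -1))), "`n`")
  expect_error(do.call(arm_spec, modifyList(base, list(age_range = c(80, 21)))),
               "`age_range`")
  expect_error(do.call(arm_spec, modifyList(base, list(p_postmenopausal = 1.5))),
               "`p_postmenopausal`")
  expect_error(do.call(arm_spec, modifyList(base, list(p_grade = c(0.5, 0.5, 0.5)))),
               "`p_grade`")
  expect_error(do.call(arm_spec, modifyList(base, list(weibull_scale = 0))),
               "`weibull_scale`")
})

test_that("linear predictor reproduces hand-computed sums", {
  one <- function(age, meno, g2, g3) {
    tibble::tibble(age = age, postmenopausal = meno, grade2 = g2, grade3 = g3)
  }
  a <- tiny_arm_a()
  expect_equal(linear_predictor(one(50, 0, 0, 0), a), 1.0)
  expect_equal(linear_predictor(one(0, 0, 0, 0), a), 0)
  b2 <- tiny_arm_b(scenario = 2)
  # 0.02*50 + 0.5 + 0.6 - 0.4 - 0.2
  expect_equal(linear_predictor(one(50, 1, 0, 1), b2, treated = TRUE), 1.5)
  # untreated arm must not see treatment coefficients
  expect_equal(linear_predictor(one(50, 1, 0, 1), b2, treated = FALSE), 2.1)
  expect_error(linear_predictor(one(50, 0, 0, 0), a, treated = TRUE),
               "beta_treatment")
})

test_that("event-time inversion agrees with the closed-form survival function", {
  spec <- tiny_arm_a()
  expect_equal(simulate_event_time(0, spec, u = 1), 0)
  expect_error(simulate_event_time(0, spec, u = 0), "u")

  # S(T) = e^{-1} at xb = 0: solve numerically as an independent oracle
  t_hat <- simulate_event_time(0, spec, u = exp(-1))
  t_oracle <- uniroot(function(t) weibull_surv(t, 0) - exp(-1),
                      c(1, 1e5), tol = 1e-9)$root
  expect_equal(t_hat, t_oracle, tolerance = 1e-6)
  expect_equal(t_hat, (2.5e7)^(1 / 2.2), tolerance = 1e-12)

  # monotone decreasing in u and in xb
  u <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(simulate_event_time(0.3, spec, u)) < 0))
  xb <- seq(-1, 2, by = 0.25)
  expect_true(all(diff(simulate_event_time(xb, spec, u = 0.5)) < 0))
})

test_that("empirical survival of simulated times matches the closed form", {
  spec <- tiny_arm_a()
  set.seed(33)
  xb <- 0.5
  t_sim <- simulate_event_time(xb, spec, u = runif(1e5))
  for (t0 in c(500, 1000, 2000)) {
    s_true <- weibull_surv(t0, xb)
    expect_equal(mean(t_sim > t0), s_true,
                 tolerance = 5 * sqrt(s_true * (1 - s_true) / 1e5) / s_true)
  }
})

test_that("censoring follows min(T, C) with C uniform over follow-up", {
  spec <- tiny_arm_a()
  obs <- apply_censoring(c(100, 3000), spec, u = c(200 / 2500, 0.999))
  expect_equal(obs$time, c(100, 0.999 * 2500))
  expect_equal(obs$event, c(1L, 0L))
  # a latent time beyond the horizon is always censored
  set.seed(9)
  far <- apply_censoring(rep(3000, 500), spec)
  expect_true(all(far$event == 0))
  expect_true(all(far$time < 2500))

  # marginal event probability vs numerical integration of the closed forms:
  # P(T <= C) = int_0^2500 (1 - t/2500) f_T(t) dt at fixed xb
  xb <- 0.8
  f_T <- function(t) {
    h <- 4e-8 * 2.2 * t^1.2 * exp(xb)
    h * weibull_surv(t, xb)
  }
  p_event <- integrate(function(t) (1 - t / 2500) * f_T(t), 0, 2500,
                       rel.tol = 1e-10)$value
  set.seed(14)
  lat <- simulate_event_time(xb, spec, u = runif(2e4))
  obs <- apply_censoring(lat, spec)
  expect_equal(mean(obs$event), p_event,
               tolerance = 5 * sqrt(p_event * (1 - p_event) / 2e4) / p_event)
})

test_that("wider censor_upper lightens random censoring", {
  light <- arm_spec(n = 2000, age_mean = 53, age_sd = 11, age_range = c(21, 80),
                    p_postmenopausal = 0.4, p_grade = c(0.2, 0.65, 0.15),
                    censor_upper = 25000)
  heavy <- tiny_arm_a(n = 2000)
  a_light <- simulate_arm(light, seed = 5)
  a_heavy <- simulate_arm(heavy, seed = 5)
  expect_gt(mean(a_light$event), mean(a_heavy$event))
  expect_true(all(a_light$time <= 2500))
})

test_that("simulate_arm is deterministic given a seed and composes its parts", {
  spec <- tiny_arm_b(scenario = 1)
  x1 <- simulate_arm(spec, treated = TRUE, seed = 77)
  x2 <- simulate_arm(spec, treated = TRUE, seed = 77)
  expect_identical(x1, x2)
  expect_equal(nrow(x1), 120)
  expect_true(all(x1$time <= pmin(x1$latent_time, 2500) + 1e-12))
  expect_true(all(x1$time[x1$event == 1] == x1$latent_time[x1$event == 1]))
  expect_true(all(x1$treated == 1))
})

test_that("moderate-n Cox fit recovers the generative coefficients", {
  spec <- tiny_arm_b(n = 20000, scenario = 1)
  set.seed(55)
  cov <- simulate_covariates(spec)
  xb <- linear_predictor(cov, spec, treated = TRUE)
  cov$time <- simulate_event_time(xb, spec, u = runif(nrow(cov)))
  cov$event <- 1L
  fit <- survival::coxph(
    survival::Surv(time, event) ~ age + postmenopausal + grade2 + grade3,
    data = cov, ties = "breslow")
  expect_lt(max(abs(unname(coef(fit)) - c(0.02, 0.5, 0.3, 0.6))), 0.05)
})
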