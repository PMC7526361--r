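test_that("balancing an arm to its own moments returns uniform weights", {
  a <- simulate_arm(tiny_arm_a(n = 200), seed = 61)
  tgt <- balance_target(aggregate_summary(a), "all")
  w <- entropy_balance(a, tgt)
  # the age target is built from the sample (n-1) variance, so the tilt is
  # only identical to uniform up to that O(1/n) difference
  expect_lt(diff(range(w$weights)) / mean(w$weights), 0.05)
  expect_equal(w$ess, 200, tolerance = 1e-4)
  expect_equal(sum(w$weights), 200) # rescaled to the target arm size
})

test_that("achieved moments hit the published targets within solver tolerance", {
  a <- simulate_arm(default_arm_a(), seed = 62)
  b <- simulate_arm(default_arm_b(1), treated = TRUE, seed = 63)
  agg <- aggregate_summary(b)
  for (st in c("all", "omit_menopause", "omit_menopause_grade")) {
    w <- entropy_balance(a, balance_target(agg, st))
    expect_lt(max(abs(w$achieved - w$targets) / pmax(1, abs(w$targets))), 1e-8)
    expect_true(all(w$weights > 0))
  }
  # the fully balanced weighted mean age equals the published mean age
  w_all <- entropy_balance(a, balance_target(agg, "all"))
  expect_equal(sum(w_all$weights * a$age) / sum(w_all$weights), agg$mean_age,
               tolerance = 1e-8)
  # and the weighted age variance matches the published variance
  wm <- sum(w_all$weights * a$age) / sum(w_all$weights)
  wv <- sum(w_all$weights * (a$age - wm)^2) / sum(w_all$weights)
  expect_equal(wv, agg$var_age + agg$mean_age^2 - wm^2, tolerance = 1e-6)
})

test_that("infeasible or boundary targets raise an infeasibility error", {
  a <- simulate_arm(tiny_arm_a(n = 100), seed = 64)
  agg <- aggregate_summary(a)
  agg$p_postmenopausal <- 1.5
  expect_error(entropy_balance(a, balance_target(agg, "all")),
               class = "maicsim_infeasible_error")
  agg2 <- aggregate_summary(a)
  agg2$mean_age <- max(a$age) + 5
  expect_error(entropy_balance(a, balance_target(agg2, "omit_menopause_grade")),
               class = "maicsim_infeasible_error")
  agg3 <- aggregate_summary(a)
  agg3$p_grade2 <- 1 # boundary of the source range
  expect_error(entropy_balance(a, balance_target(agg3, "all")),
               class = "maicsim_infeasible_error")
})

test_that("effective sample size has the Kish properties", {
  expect_equal(ess(rep(1, 25)), 25)
  expect_equal(ess(rep(0.37, 25)), 25) # uniform at any scale
  expect_equal(ess(c(1, rep(0, 9))), 1) # point mass
  expect_error(ess(rep(0, 4)))
  expect_error(ess(c(-1, 2)))
  set.seed(65)
  for (i in 1:20) {
    w <- rexp(50)
    expect_equal(ess(w), ess(w * runif(1, 0.1, 10))) # scale invariance
    expect_lte(ess(w), 50)
  }
})

test_that("balancing more covariates weakly decreases the effective sample size", {
  a <- simulate_arm(default_arm_a(), seed = 66)
  b <- simulate_arm(default_arm_b(1), treated = TRUE, seed = 67)
  agg <- aggregate_summary(b)
  e_all <- entropy_balance(a, balance_target(agg, "all"))$ess
  e_meno <- entropy_balance(a, balance_target(agg, "omit_menopause"))$ess
  e_age <- entropy_balance(a, balance_target(agg, "omit_menopause_grade"))$ess
  expect_lte(e_all, e_meno + 1e-9)
  expect_lte(e_meno, e_age + 1e-9)
  expect_lte(e_age, nrow(a))
})

test_that("tidy and glance summarise a weight set", {
  a <- simulate_arm(tiny_arm_a(n = 200), seed = 68)
  b <- simulate_arm(tiny_arm_b(n = 160), treated = TRUE, seed = 69)
  w <- entropy_balance(a, balance_target(aggregate_summary(b), "all"))
  td <- tidy(w)
  expect_named(td, c("moment", "target", "achieved"))
  expect_equal(nrow(td), 5)
  gl <- glance(w)
  expect_equal(gl$n, 200)
  expect_true(gl$converged)
})
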