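#' Build the moment targets for one weighting strategy
#'
#' Age is balanced on its first and second raw moments (the second moment
#' is assembled from the published mean and variance as `var + mean^2`);
#' the binary indicators are balanced on their first moments only, since
#' for a dichotomous variable the second moment is determined by the
#' first. The strategy selects which covariates enter the weighting
#' model:
#'
#' * `"all"` - age (mean and variance), menopausal status, both tumour
#'   grade indicators;
#' * `"omit_menopause"` - drops the menopause indicator (in scenario 2
#'   this omits the effect modifier);
#' * `"omit_menopause_grade"` - drops menopause and both grade
#'   indicators, leaving age only;
#' * `"unweighted"` - no balancing at all (empty target).
#'
#' @param aggregates A one-row tibble from [aggregate_summary()] (or the
#'   `aggregates` element of a [publish()] object).
#' @param strategy Character, see above.
#' @return An object of class `balance_target`: a list with `moments`
#'   (named target values), `strategy` and `n_total`.
#' @export
balance_target <- function(aggregates,
                           strategy = c("all", "omit_menopause",
                                        "omit_menopause_grade", "unweighted")) {
  strategy <- match.arg(strategy)
  m <- c(
    age = aggregates$mean_age,
    age2 = aggregates$var_age + aggregates$mean_age^2,
    postmenopausal = aggregates$p_postmenopausal,
    grade2 = aggregates$p_grade2,
    grade3 = aggregates$p_grade3
  )
  keep <- switch(strategy,
    all = names(m),
    omit_menopause = c("age", "age2", "grade2", "grade3"),
    omit_menopause_grade = c("age", "age2"),
    unweighted = character(0)
  )
  if (any(!is.finite(m[keep]))) {
    abort("balance target contains non-finite moments",
          class = "maicsim_config_error")
  }
  structure(
    list(moments = m[keep], strategy = strategy,
         n_total = aggregates$n_total),
    class = "balance_target"
  )
}

# design columns corresponding to the named moments
moment_matrix <- function(covariates, moment_names) {
  cols <- list(
    age = covariates$age,
    age2 = covariates$age^2,
    postmenopausal = covariates$postmenopausal,
    grade2 = covariates$grade2,
    grade3 = covariates$grade3
  )
  do.call(cbind, cols[moment_names])
}

#' Entropy-balancing weights for unanchored MAIC
#'
#' Solves the entropy-balancing program: minimise the Kullback-Leibler
#' divergence of the weights from uniform base weights subject to the
#' weighted covariate moments equalling the published targets and the
#' weights summing to one. The solution has the exponential-tilting form
#' \eqn{w_i \propto \exp(c_i'\lambda)}; the dual multipliers
#' \eqn{\lambda} are found by damped Newton iteration on the convex dual
#' (log-partition minus target inner product), with constraint columns
#' standardised for conditioning and a Levenberg-style ridge fallback
#' when the Hessian is near-singular. On return the weights are rescaled
#' to sum to the published sample size of the target arm, so the two
#' "arms" of the pooled analysis have equal weighted size; the effective
#' sample size is scale-invariant either way.
#'
#' @param covariates Tibble of the IPD arm's covariates (columns `age`,
#'   `postmenopausal`, `grade2`, `grade3`).
#' @param target A [balance_target()].
#' @param tolerance Maximum allowed relative error of any achieved moment
#'   (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return An object of class `maic_weights`: list with `weights`
#'   (length n, summing to the target arm size), `achieved` and `targets`
#'   (named moment vectors), `ess`, `strategy`, `converged`,
#'   `iterations`.
#' @export
#' @examples
#' arm_a <- simulate_arm(default_arm_a(), seed = 3)
#' arm_b <- simulate_arm(default_arm_b(1), treated = TRUE, seed = 4)
#' w <- entropy_balance(arm_a, balance_target(aggregate_summary(arm_b)))
#' glance(w)
entropy_balance <- function(covariates, target, tolerance = 1e-8,
                            max_iter = 200) {
  n <- nrow(covariates)
  if (n == 0) {
    abort("cannot balance an empty covariate table",
          class = "maicsim_domain_error")
  }
  if (target$strategy == "unweighted" || length(target$moments) == 0) {
    w <- rep((target$n_total %||% n) / n, n)
    return(new_maic_weights(w, numeric(0), numeric(0), "unweighted", TRUE, 0L))
  }
  m <- target$moments
  C <- moment_matrix(covariates, names(m))

  # feasibility: each target must lie inside the range of source values
  rng_lo <- apply(C, 2, min); rng_hi <- apply(C, 2, max)
  degenerate <- rng_hi - rng_lo < .Machine$double.eps
  if (any(m < rng_lo - 1e-12) || any(m > rng_hi + 1e-12) ||
      any(degenerate & abs(m - rng_lo) > 1e-12)) {
    off <- names(m)[which(m < rng_lo - 1e-12 | m > rng_hi + 1e-12 |
                            (degenerate & abs(m - rng_lo) > 1e-12))]
    abort(sprintf("infeasible balance target: moment(s) %s outside the source range",
                  paste(off, collapse = ", ")),
          class = "maicsim_infeasible_error")
  }
  # interior targets on non-degenerate columns are required for finite duals
  interior <- degenerate | (m > rng_lo + 1e-12 & m < rng_hi - 1e-12)
  if (!all(interior)) {
    abort(sprintf("infeasible balance target: moment(s) %s on the boundary of the source range",
                  paste(names(m)[!interior], collapse = ", ")),
          class = "maicsim_infeasible_error")
  }
  use <- !degenerate
  Cs <- C[, use, drop = FALSE]
  mu <- colMeans(Cs); sg <- apply(Cs, 2, stats::sd)
  Z <- sweep(sweep(Cs, 2, mu), 2, sg, "/")
  zt <- (m[use] - mu) / sg

  lambda <- rep(0, ncol(Z))
  dual <- function(l) {
    eta <- drop(Z %*% l)
    eta_max <- max(eta)
    log(mean(exp(eta - eta_max))) + eta_max - sum(zt * l)
  }
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% lambda)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    g <- drop(crossprod(Z, w)) - zt
    if (max(abs(g)) < 1e-11) { converged <- TRUE; break }
    Zc <- sweep(Z, 2, drop(crossprod(Z, w)))
    H <- crossprod(Zc, Zc * w)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) {
      step <- solve(H + diag(1e-6, ncol(H)), g)
    }
    # backtracking line search on the dual
    f0 <- dual(lambda)
    alpha <- 1
    repeat {
      cand <- lambda - alpha * step
      if (dual(cand) <= f0 - 1e-4 * alpha * sum(g * step) || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    lambda <- lambda - alpha * step
  }
  eta <- drop(Z %*% lambda)
  w <- exp(eta - max(eta)); w <- w / sum(w)
  achieved <- drop(crossprod(C, w))
  names(achieved) <- names(m)
  rel_err <- abs(achieved - m) / pmax(1, abs(m))
  if (any(rel_err > tolerance)) {
    abort(sprintf("entropy balancing did not converge: max relative moment error %.3g (gradient norm %.3g after %d iterations)",
                  max(rel_err), max(abs(drop(crossprod(Z, w)) - zt)), iter),
          class = "maicsim_solver_error")
  }
  w <- w * (target$n_total %||% n)
  new_maic_weights(w, achieved, m, target$strategy, converged, iter)
}

new_maic_weights <- function(weights, achieved, targets, strategy,
                             converged, iterations) {
  structure(
    list(weights = weights, achieved = achieved, targets = targets,
         strategy = strategy, ess = ess(weights), converged = converged,
         iterations = iterations),
    class = "maic_weights"
  )
}

#' Effective sample size of a weight vector
#'
#' Kish's formula \eqn{(\sum w)^2 / \sum w^2}: the size of an unweighted
#' sample carrying the same information. Scale-invariant, at most `n`,
#' and equal to `n` for uniform weights.
#'
#' @param weights Nonnegative weights, not all zero.
#' @return A single number.
#' @export
#' @examples
#' ess(rep(2, 10)) # 10
ess <- function(weights) {
  if (length(weights) == 0 || any(weights < 0) || all(weights == 0)) {
    abort("weights must be nonnegative and not all zero",
          class = "maicsim_domain_error")
  }
  sum(weights)^2 / sum(weights^2)
}

#' @export
print.maic_weights <- function(x, ...) {
  cat(sprintf("<maic_weights> strategy '%s': n = %d, ESS = %.1f\n",
              x$strategy, length(x$weights), x$ess))
  invisible(x)
}

#' @describeIn entropy_balance One row per balanced moment with its
#'   target and achieved value.
#' @param x A `maic_weights` object.
#' @param ... Unused.
#' @export
tidy.maic_weights <- function(x, ...) {
  tibble(
    moment = names(x$targets),
    target = unname(x$targets),
    achieved = unname(x$achieved)
  )
}

#' @describeIn entropy_balance One-row summary (n, ESS, convergence).
#' @export
glance.maic_weights <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    n = length(x$weights),
    ess = x$ess,
    converged = x$converged,
    iterations = x$iterations
  )
}
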