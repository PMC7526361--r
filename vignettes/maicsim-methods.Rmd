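---
title: "Methods: simulating and evaluating unanchored MAIC for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating unanchored MAIC for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
generative model, the estimators, the numerical choices, and — because a
simulation package is only as informative as its generator — what the
synthetic data do and do not emulate.

## 1. The estimation problem

Two treatments, A and B, have each been studied in a single-arm trial.
The analyst holds individual-patient data (IPD) for trial A; trial B is
available only as a publication: aggregate baseline characteristics, a
Kaplan-Meier figure, a numbers-at-risk table, and (usually) the total
event count. An unanchored matching-adjusted indirect comparison
reweights the A-arm IPD so its covariate moments match B's published
aggregates, reconstructs pseudo-IPD for B from the figure, pools the two
samples, and estimates the B-versus-A hazard ratio by weighted Cox
regression. Because there is no common comparator arm, the comparison
inherits every failure of covariate capture: any prognostic factor that
differs between the trial populations and is not balanced acts as a
confounder, whether or not it modifies the treatment effect.

## 2. Generative model

Each simulated subject carries age, menopausal status and tumour grade
(1/2/3, encoded as two indicators with grade 1 as reference).
Recurrence-free survival follows a Weibull proportional-hazards model
with cumulative hazard

$$H(t \mid x) = \lambda\, t^{\gamma}\, e^{x\beta},$$

inverted exactly for simulation:
$T = \left(-\ln U / (\lambda e^{x\beta})\right)^{1/\gamma}$ with
$U \sim \mathrm{Uniform}(0,1]$. The linear predictor is

$$x\beta = \beta_{age}\,\mathrm{age} + \beta_{meno}\,\mathrm{meno}
  + \beta_{g2}\,I(\mathrm{grade}=2) + \beta_{g3}\,I(\mathrm{grade}=3)
  + \mathrm{treated}\cdot(\beta_{trt} + \beta_{trt\times meno}\,\mathrm{meno}).$$

Defaults (per `default_arm_a()` / `default_arm_b()`):

| parameter | arm A | arm B | units / note |
|---|---|---|---|
| n | 1000 | 800 | subjects |
| age | TN(53, 11²) on [21, 80] | TN(56, 12²) on [23, 85] | years, truncated normal |
| postmenopausal | 40% | 50% | Bernoulli |
| grade 1/2/3 | 20/65/15% | 10/70/20% | categorical |
| λ, γ | 4e-8, 2.2 | 4e-8, 2.2 | per day^γ, — |
| β (age, meno, g2, g3) | .02, .5, .3, .6 | same | log HR |
| β_trt (scenario 1 / 2) | — | −0.5 / −0.4 | log HR |
| β_trt×meno (scenario 2) | — | −0.2 | log HR |
| follow-up | 2500 | 2500 | days |

Arm A is the healthier population by construction, so the unweighted
comparison is confounded in the direction of making B look worse. In
scenario 2 the treatment main effect plus the interaction at B's 50%
postmenopausal prevalence gives the same expected effect as scenario 1
(−0.4 − 0.2 × 0.5 = −0.5), which is the truth used for bias and
coverage throughout.

**Truncated-normal sampling** uses the inverse-CDF on the truncated
interval rather than rejection, so each subject consumes exactly one
uniform and runs are reproducible stream-for-stream from the seed.

**Censoring.** Random censoring is drawn uniform on
(0, `censor_upper`) and capped at the 2500-day horizon, with
`censor_upper = 2500` by default — i.e. censoring uniform over the whole
follow-up window, independent of covariates and treatment. This is one
reading of "uniform censoring truncated at the horizon"; the other is a
wider uniform capped at 2500, which leaves far fewer randomly censored
subjects. The choice matters: the Monte-Carlo variance of any of the
estimators here is approximately $1/d_A + 1/d_B$ in the event counts,
so halving the event fraction roughly doubles the across-repetition
variance and also increases the non-collapsibility attenuation of the
marginal hazard ratio (Section 6). We expose `censor_upper` so users
can probe this sensitivity; the default keeps the heavier-censoring
reading.

## 3. Publication emulation and reconstruction

`publish()` produces exactly the artefacts a journal article exposes:
the Kaplan-Meier step corners (via the product-limit estimator), the
at-risk counts on a reporting grid, aggregate covariates, and the event
count. Digitization is emulated programmatically by rounding times to
whole days and survival to 4 decimals (`extract_curve()`); at n = 800
the survival increments are ~1.25e-3, so 4 decimals preserve individual
drops and the default extraction is nearly lossless. An optional
uniform jitter on both axes mimics hand-digitization error but is off
by default because the error of manual digitizing is unquantified; the
test suite treats the small residual shift of the reconstruction
indicator HR as the property to bound, not a number to match. The
default risk grid {0, 500, ..., 2500} days reflects common journal
practice over a 2500-day horizon and is configurable.

`reconstruct()` implements the Guyot interval algorithm. Within each
risk-table interval the number censored is unknown; given a candidate
count, censoring times are spread evenly across the interval
(deterministically — no random placement), event counts at each
published step are inferred from the relative survival drop
$d = \mathrm{round}(n \cdot (1 - S/\mathrm{KM}))$, and the implied
at-risk count at the next reporting time is compared with the published
one; the count is adjusted by the discrepancy until the two agree
(integer search with an iteration cap; ties resolved toward fewer
censorings). Clicks after the last reporting time use the extrapolated
censoring rate reconciled against the published total event count.
Record count is conserved by construction: events + censorings +
terminal censorings equal the count at risk at time zero. In the
lossless regime (risk table at every event time, rounding disabled) the
algorithm recovers the event-time multiset exactly, which the tests
assert.

**Validation model.** Fidelity is judged by stacking raw and
reconstructed records and fitting a Cox model with a "reconstructed"
indicator and its time-varying effect, entered as indicator × analysis
time (the default of the time-varying-covariate facility in the
software this analysis style comes from; indicator × ln t is available
via `tt_form = "log"`). Both hazard ratios are 1 under perfect
reconstruction. Because this two-parameter model's Breslow partial
likelihood depends on the data only through per-event-time group
counts, the package maximises it directly ("collapsed" engine:
Newton-Raphson on the exact likelihood, model-based variance from the
observed information). This is algebraically the same fit as
`survival::coxph()` with a `tt()` term — the suite verifies agreement
to ~1e-10 — but orders of magnitude faster, which is what makes
per-repetition validation affordable inside a Monte Carlo loop.

## 4. Weighting and estimation

`entropy_balance()` solves: minimise $\sum_i w_i \ln(w_i/q_i)$ over
weights summing to one (uniform base $q$), subject to the weighted
moments equalling the published targets — age first and second raw
moments (the second assembled as published variance + mean², the
sample-variance convention; at n = 800 the n vs n−1 distinction is
below reporting precision), and first moments for the binary
indicators, whose second moments are determined by their first. The
dual is a smooth convex function of one multiplier per constraint;
weights have the exponential-tilting form $w_i \propto \exp(c_i'\lambda)$.
Numerics: constraint columns are standardised, a damped Newton
iteration with Armijo backtracking runs on the dual, a Levenberg ridge
handles near-singular Hessians, and convergence requires every achieved
moment within 1e-8 relative error. Infeasible targets — outside or on
the boundary of the source range — are detected before solving and
reported per moment. On return the weights are rescaled to sum to the
comparator's sample size, matching the convention that entropy
balancing gives the two groups equal weighted size.

`pooled_weighted_cox()` fits the treatment indicator alone on the
pooled sample — A-arm subjects with their balancing weights,
reconstructed B-arm subjects with unit weights — using Breslow ties and
the robust sandwich variance (weights as sampling weights), Wald CIs on
the log scale. The estimate is invariant to rescaling *all* weights by
a constant; rescaling one arm alone is a different analysis, which is
why the normalization convention above is fixed rather than free.

Strategies: `unweighted` (no balancing), `all` (every prognostic
factor), `omit_menopause` (age + grades), `omit_menopause_grade` (age
only). Scenario 1 evaluates the first, second and fourth; scenario 2
all four; the omit-menopause strategy is added to scenario-1 runs when
the bias-factor adjustment is requested, since menopause is the omitted
confounder being adjusted for.

## 5. Monte Carlo evaluation and the bias factor

`run_study()` derives one sub-seed per repetition from the master seed,
runs simulate → publish → reconstruct → (validate) → estimate, and
aggregates only converged repetitions (failures are logged and
excluded, never imputed; a warning fires above 5% exclusions). Metrics
per strategy: bias, Monte-Carlo variance (squared empirical SE), MSE
and CI coverage against the true log HR of −0.5, and mean effective
sample size. The identity
$\mathrm{MSE} = \mathrm{bias}^2 + \tfrac{N-1}{N}\mathrm{MCV}$ holds
exactly and is asserted to machine precision.

The bias factor for an omitted binary confounder U bounds
$HR_{obs}/HR_{true}$ by $(HR_{UD} \times RR_{EU})/(HR_{UD} + RR_{EU} - 1)$.
With menopausal status as U, the package derives $HR_{UD}$ from the
generative coefficients among treated subjects (main effect plus
interaction: $e^{0.5}$ in scenario 1, $e^{0.3}$ in scenario 2) and
$RR_{EU}$ as the prevalence ratio 0.50/0.40, giving a scenario-2 factor
of 1.05 at 2-decimal precision. The scenario-1 convention is less
settled — the same construction gives ≈1.09, and a realized-sample
prevalence ratio would give a slightly different value — so both
arguments are explicit inputs to `bias_factor()` rather than constants.
The adjustment divides the omit-menopause strategy's hazard-ratio
estimate and its lower confidence limit by the factor; summaries report
the mean adjusted log-scale bias and the fraction of repetitions whose
adjusted lower limit falls at or below the true hazard ratio.

## 6. What the generator does and does not emulate

The simulator encodes one specific study design: Weibull
proportional hazards with identical baseline parameters in both arms,
covariate imbalance in A's favour, covariate-independent censoring, and
a comparator published at journal fidelity. Passing tests therefore
demonstrate correctness of the pipeline *under these conditions*; they
do not certify unanchored MAIC on real data, where baseline hazards
differ across trials, hazards are non-proportional (early drop-outs,
cure plateaus), censoring is informative, and digitization is manual.
Three caveats deserve emphasis:

* **Non-collapsibility.** Even with all covariates balanced, the
  marginal B-vs-A hazard ratio in the B population is attenuated toward
  1 relative to the conditional −0.5 (frailty selection over time), so
  a small positive bias of the fully weighted strategy is a property of
  the estimand, not a bug; its size grows with follow-up and event
  fraction.
* **Digitization fidelity.** Programmatic extraction keeps every step
  corner; manual digitization does not, and tends to shift the
  reconstructed hazard slightly. Results driven by reconstruction
  error will therefore look cleaner here than in a manual workflow; the
  jitter options exist to explore that gap.
* **Censoring intensity** (Section 2) shifts every strategy's variance
  and bias; comparisons of absolute bias numbers across studies are
  only meaningful at matched censoring.

## 7. Problem sizes and test design

The acceptance tests run two 200-repetition studies at the full default
arm sizes (1000/800) — enough for bias checks with Monte-Carlo standard
errors of a few thousandths on the log-HR scale — plus a 3e5-subject
uncensored Cox fit whose ±0.02 coefficient-recovery band is then ~4
sampling SEs wide for the least-precise coefficients. Unit tests use
arms of 100–300 subjects and verify: hand-computed product-limit
corners and linear predictors, closed-form Weibull inversion against a
numerical root-finder, censoring proportions against numerical
integration, exact reconstruction in the lossless regime, solver moment
fidelity at 1e-8, the collapsed-vs-`coxph` engine equivalence, Kish ESS
properties, and bit-identical reproducibility from the master seed.

## 8. Known limitations

Single-index Weibull outcomes only (no cure fractions or piecewise
hazards); covariate-independent censoring; equal baseline hazards
across arms; moment (not distribution) balancing; no anchored MAIC,
simulated treatment comparison, or network meta-regression. The
bias-factor adjustment assumes the omitted confounder makes the
treatment look worse (factor ≥ 1); for suspected overestimation the
upper limit would be multiplied instead, which is left to the user.
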