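---
title: "Estimating causal effects of capped dietary substitution strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of capped dietary substitution strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietsub)
```

## The causal question

Nutritional cohorts routinely ask what would happen if people replaced one
food with another — say, processed red meat with chicken. A realistic
version of that intervention depends on each person's *natural* intake:
whoever would have eaten `a` weekly servings of the replaced food `A` and
`b` servings of the substitute `B` is asked to eat 0 servings of `A` and

$$ d(a, b) = \min(a + b,\; x) $$

servings of `B`, with a cap `x` (for example, at most 7 servings of
chicken per week) guarding against pushing anyone beyond intake levels the
data support. Other food groups `C` stay at their natural levels. This is
an intervention that depends on the natural value of several exposures at
once — a multivariate modified treatment policy. The estimand is the
counterfactual mean outcome under that strategy,
$\mu_g = E(Y_g)$, and the risk difference $\Delta = E(Y) - \mu_g$.

## Identification

With consistency, determinism of planned versus actual intake,
exchangeability of $(A, B)$ given $(C, L)$, and positivity — every
covariate stratum must contain people with $A = 0$ at each attainable
substitute dose — the estimand is identified by the g-formula

$$ \mu_g = \sum_{a,b,c,l} E(Y \mid A=0, B=d(a,b), C=c, L=l)\,
   p(a,b,c \mid l)\, p(l). $$

Marginalising the degenerate dose kernel over the natural joint law of
$(A, B)$ yields the intervened-dose pmf

$$ \tilde q(b^\dagger \mid c, l) = \sum_{a}\Big\{ I(a \le b^\dagger \le x)\,
   p_B(b^\dagger - a \mid a, c, l) + I(b^\dagger = x)\,
   [1 - F_B(x - a \mid a, c, l)] \Big\}\, p_A(a \mid c, l), $$

with $F_B(t) = 0$ for $t < 0$, so that natural `A` values exceeding the
cap contribute their full mass to the capped dose. `qtilde_pmf()`
implements this sum directly; the test suite verifies it against
exhaustive enumeration of all $(a, b)$ pairs pushed through the dose map.
The same quantity defines the inverse-probability weight

$$ W = \frac{I(A = 0)\, \tilde q(B \mid C, L)}
   {p(A = 0 \mid C, L)\, p(B \mid A = 0, C, L)}, $$

which has mean one under the true exposure laws.

A note on the strategy's published description: one display of the
intervention states the substitute dose as a maximum of `x` and `a + b`,
while the dose-map display and the derivation of $\tilde q$ use the
minimum. The two are inconsistent with each other, and only the min form
yields a dose bounded by the cap and a normalised $\tilde q$; the package
therefore implements $d(a,b) = \min(a+b, x)$ throughout.

## Estimators

Three estimators are provided, all through `dietsub()`:

* **ORE** (outcome regression): fit $m(A,B,C,L) = E(Y \mid A,B,C,L)$,
  evaluate it at the intervened exposures $(0, d(A,B), C, L)$, average.
* **IPW**: the self-normalised weighted mean $\sum W_i Y_i / \sum W_i$,
  the root of $0 = P_n[W(Y - \mu)]$.
* **TMLE**: starting from the outcome regression, fit a one-parameter
  logistic fluctuation — an intercept-only weighted logistic regression
  of `Y` with offset $\mathrm{logit}\, \hat m$ and weights $W$ — and
  plug the updated $\hat m^*$ into the ORE average. The intercept-only
  weighted fluctuation solves the efficient-influence-function equation

  $$ 0 = P_n\Big[ W\{Y - \hat m^*(A,B,C,L)\} +
     \hat m^*(0, d(A,B), C, L) - \hat\mu_g \Big] $$

  exactly in a single step, which is the defining property of the
  targeting update; no iteration is needed. Whether the weight enters
  the fluctuation as a regression weight or as a covariate is not
  determined by the score equation alone — both choices solve it — and
  the package uses the weight form. TMLE is doubly robust: consistent
  if either the outcome regression or the joint exposure model is
  correctly specified.

Standard errors: the TMLE uses the influence-function (sandwich)
variance $\widehat{\mathrm{Var}}(\varphi)/n$. ORE and IPW report
influence-function standard errors that treat the fitted nuisances as
fixed; these are labelled `naive` in the output and a nonparametric
bootstrap (`boot = TRUE`, 500 seeded resamples by default) is the
recommended alternative for those two.

## Working marginal structural models

To summarise effect modification, the conditional counterfactual mean
$E(Y_g \mid Z)$, $Z \subseteq L$, is projected onto a logistic working
model $g(Z;\theta) = \mathrm{expit}\{s(Z)^\top\theta\}$. The target
$\theta$ is the *least-false* parameter solving
$0 = E[s(Z)\{\xi(L) - g(Z;\theta)\}]$ with
$\xi(L) = E[m(0, d(A,B), C, L) \mid L]$ — a well-defined summary even
when the working model is wrong. The three estimators carry over
(`msm = ~ modifier`): the ORE projects the intervened outcome-regression
predictions, the IPW fits a weighted logistic regression of `Y` on
$s(Z)$, and the targeted version runs a $p$-dimensional fluctuation
along $s(Z)$ before projecting. Since the published algorithm and the
ORE/IPW estimating equations for this projection appear only in
supplementary material, the package reconstructs them as the natural
score equations whose solutions annihilate the corresponding terms of
the efficient influence function — each is the unique choice with that
property. All estimators report the empirical sandwich
$\hat C^{-1} P_n[s s^\top \tilde\phi^2] \hat C^{-\top}/n$ with
$\hat C = P_n[s s^\top g(1-g)]$; for ORE and IPW the residual
$\tilde\phi$ is that of their own estimating equation, which assumes the
corresponding equation is correctly targeted. With an intercept-only
design every projection reproduces the corresponding scalar estimator
through $\mathrm{expit}(\hat\theta_0)$, a reduction the tests check to
`1e-10`. The IPW-MSM uses plain (unnormalised) weighted scores.

Solver details: Newton iteration from $\theta = 0$ with step-halving on
the score norm, tolerance `1e-10` (mean-score max-norm), at most 100
iterations; rank-deficient designs are refused up front.

## Nuisance learners

Outcome regression: parametric logistic (`glm`) from a formula, or a
smooth additive model (`mgcv::gam`) for flexible fits. Exposure pmfs
over their finite supports: multinomial logistic (optionally with
natural-spline bases for continuous covariates), Binomial-logistic with
size equal to the support maximum, or saturated empirical conditional
pmfs on exact covariate cells (the nonparametric MLE; appropriate when
all conditioning variables are discrete with few levels). Predicted
outcome probabilities are bounded to $[10^{-6}, 1-10^{-6}]$ before any
logit transform; estimated denominator densities in the weights are
floored at `1e-6` (configurable), with truncations counted and reported
rather than silently absorbed — truncation guards against empirical
positivity failures without redefining the estimand. Optional K-fold
cross-fitting (`folds`, seeded) gives every record out-of-fold
predictions, supporting flexible learners whose convergence rates are
slower than parametric ones. The original development used the Highly
Adaptive Lasso as its flexible learner; this package instead exposes a
pluggable learner interface with the defaults above, since the
asymptotic requirements are product-rate conditions that other flexible
learners also satisfy.

Exposures must be non-negative integers on a finite support (weekly
servings). Fractional servings — for instance from frequency-category
conversions of food questionnaires — must be rounded or binned by the
caller; the validator refuses silent coercion because every
identification display is a sum over the discrete support. Missing
records are rejected, not imputed.

## The simulation designs and their oracles

Two generators reproduce the package's study conditions exactly.
Design 1: $U \sim \mathrm{Unif}(0,1)$ latent,
$L \sim \mathrm{Ber}(0.5)$,
$A \sim \mathrm{Bin}(3, \mathrm{expit}(-2+L+U))$,
$B \sim \mathrm{Bin}(3, \mathrm{expit}(1-2L+U))$,
$C \sim \mathrm{Bin}(3, \mathrm{expit}(-1+L+U))$,
$Y \sim \mathrm{Ber}(\mathrm{expit}(-1-A+B+C-2L))$, working model
$\mathrm{expit}(\theta_0 + \theta_1 L)$. Design 2 replaces the single
binary covariate with $L_1 \sim \mathrm{Ber}(0.5)$,
$L_2 \sim \mathrm{Unif}(0,2)$ and uses the stated nonlinear predictors,
with working model $\mathrm{expit}(\theta_0 + \theta_1 L_2)$. Both use
cap $x = 3$, the maximum of the support of `B`. The latent factor `U`
induces dependence among the exposures and is never emitted.

Because `U` is shared, the *observed-covariate* conditionals of the
exposures are not Binomial-logistic; the "correctly specified" exposure
arm therefore uses saturated empirical pmfs over the $(C, L)$ /
$(A, C, L)$ cells, which are consistent for the marginalised laws. The
misspecification arms use exactly the printed working models: outcome
$\mathrm{expit}(\beta_0+\beta_1 A+\beta_2 BL+\beta_3 CL)$, or exposures
$\mathrm{expit}(\alpha_{b0}+\alpha_{b1}A+\alpha_{b2}C)$ and
$\mathrm{expit}(\alpha_{a0}+\alpha_{a1}C)$.

Ground truth comes from two independent routes. The deterministic
oracles (`true_mu_oracle()`, `least_false_oracle()`) enumerate
$(A,B,C) \in \{0..3\}^3$ exactly and integrate `U` (and `L2`) with
64-node Gauss–Legendre quadrature, verified by node doubling to below
$10^{-8}$ and refused below 16 nodes; the least-false projection is then
solved by Newton to score norm $10^{-12}$. The Monte Carlo oracles
(`mc_counterfactual_mean()`, `mc_least_false()`) simulate the
counterfactual world directly at $10^7$ draws. The acceptance suite
checks the two routes against each other within 3 Monte Carlo standard
errors; under design 2 the deterministic projection gives
$\theta = (0.933, 0.268)$ after rounding.

```{r oracle}
cmd_oracle(2)
```

## Replication harness and problem sizes

`run_replications()` seeds each replicate from the master seed by a
counter scheme (`seed + 9973 * r`, kept below $2^{31}$), so runs are
bitwise reproducible and any single replicate can be re-run in
isolation. Aggregates are bias, empirical SE, MSE, and 95% Wald
coverage against the deterministic oracles; replicate-level failures are
excluded with a count and the aggregate is refused if more than 1% fail.
The package's own validation uses design 1 at $n = 5000$ with 200
replicates for bias comparisons and 250 for coverage — large enough that
a bias of 0.03 on the $\theta$ scale is several Monte Carlo standard
errors, while keeping the full suite inexpensive. One replicate at these
sizes:

```{r replicate}
d <- generate_study1(5000, seed = 1)
specs <- scenario_specs(1, "correct")
fit <- dietsub(d, x = 3, estimator = "tmle",
               outcome = specs$outcome,
               exposure_a = specs$exposure_a,
               exposure_b = specs$exposure_b,
               msm = ~ L)
summary(fit)
```

## What the generators do and do not emulate

The synthetic designs reproduce discrete multi-exposure intake driven by
a shared latent preference factor, confounding of intake and outcome by
measured covariates, and a binary outcome — the structural features the
estimators engage with. They do not emulate measurement error in
food-frequency instruments, survey weighting, missing data, rare
outcomes, or time-varying (sustained) interventions; passing tests on
these designs demonstrates correctness of the estimators under the
stated laws, not robustness to those real-data complications. The
`simulate_nhs_like()` fixture is likewise purely synthetic, with invented
coefficients, and exists to exercise the CSV-to-JSON pipeline end to
end.

## Numerical choices and degenerate inputs

* Dose map and kernel are exact integer arithmetic; $\tilde q$ input
  pmfs are checked to normalise within `1e-8`.
* The scalar fluctuation is solved by safeguarded Newton to score
  `1e-12`; an already-solved score returns $\hat\varepsilon = 0$ and the
  TMLE collapses to the ORE on the same fit.
* A constant outcome column short-circuits to a calibrated constant fit
  (the degenerate MLE), so `Y` identically 0 returns $\hat\mu_g = 0$
  without a spurious convergence failure.
* Records with $A \ne 0$ receive weight exactly 0 without evaluating the
  denominator; datasets with no $A = 0$ records make IPW and TMLE fail
  loudly.
* The MSM sandwich is projected onto the PSD cone to remove eigenvalue
  roundoff (an exactly-zero residual direction can land at $-10^{-30}$).
* Positivity diagnostics coarsen continuous covariates at empirical
  quartiles by default; empty strata are skipped and counted.

## Known limitations

* The influence-function variance is the asymptotic variance only when
  both nuisances converge to the truth. Under the union model it remains
  valid for point estimation (double robustness) but the sandwich can be
  mis-calibrated: with a correct outcome model and badly wrong exposure
  models, the package's own replications show conservative intervals for
  the MSM intercept (empirical coverage ≈ 0.99) and anti-conservative
  ones for the scalar mean. Bootstrap variance is the safer choice when
  exposure-model misspecification is suspected.
* ORE/IPW naive standard errors ignore nuisance estimation entirely.
* Only point (single time) interventions are supported; sustained
  strategies, continuous exposures, and time-to-event outcomes are out
  of scope.
* The alternative strategy that caps `B` while holding total `A + B`
  fixed is not implemented; its identification formula is not part of
  the package's scope.
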