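---
title: "Bayesian sample-size determination for censored cost-effectiveness trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian sample-size determination for censored cost-effectiveness trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedesign)
```

## The problem

Trials that compare treatments on cost-effectiveness observe, for each
subject, a survival time $T$ and an accrued cost $C$, both cut short when
the subject is right-censored by study end or dropout. The decision
quantity is the incremental net monetary benefit at a willingness-to-pay
value $\mathrm{WTP}$,
$$ \mathrm{INMB}(\mathrm{WTP}) = \big[E(T\mid Z{=}1) - E(T\mid Z{=}0)\big]
   \cdot \mathrm{WTP} - \big[E(C\mid Z{=}1) - E(C\mid Z{=}0)\big], $$
and the trial is a success when the posterior satisfies
$\Pr(\mathrm{INMB} > 0 \mid \text{data}) \ge 1 - \phi$ (default
$\phi = 0.05$). At the planning stage `cedesign` estimates, by Monte
Carlo, the probability $r^{(n)}$ that a trial of total size $n$ ends in
success — *power* when the generating parameters are fixed, *assurance*
(expected power) when they are drawn from a design prior — and selects
the smallest $n$ on a grid with $r^{(n)}$ at or above a target (default
0.8).

## The two joint models

Both models factorize $f(t, c) = f_T(t)\, f_{C\mid T}(c \mid t)$ with
arm-specific parameters.

**Weibull-gamma.** $T$ is Weibull with shape $\alpha_k$ and scale
$\lambda_k$ (survival form $S(t) = \exp[-(t/\lambda)^\alpha]$, mean
$\lambda\Gamma(1+1/\alpha)$, evaluated with the standard log-gamma
special function). Cost given $t$ is gamma with shape $\nu_k$
reparameterized to mean $\mu_k(t) = \beta_k + \gamma_k t$ and variance
$\mu_k(t)^2/\nu_k$; $\beta_k$ is the start-up cost of the arm and
$\gamma_k$ the accrual per unit time, both constrained positive so that
expected cost grows with follow-up. Time and cost units are abstract —
the shipped fixtures use years and \$k — and the package never converts
units; WTP is cost units per time unit.

**Normal-normal.** $T \sim N(\mu_k, \tau^2_{Tk})$ and
$C \mid t \sim N(\theta_{\mathrm{int},k} + \theta_{\mathrm{sl},k}\, t,
\tau^2_{Ck})$, the conditional parameterization of a bivariate normal.
`nn_marginal_summary()` converts it to the marginal display (cost mean,
cost sd, time-cost correlation). The simulator resamples the rare
negative time or cost draw (budget 1000 per subject, then an error
naming the arm); the fitted model itself is untruncated, which is
harmless at the fixture's parameter values where negative draws have
probability below $10^{-2}$.

## Censoring mechanisms

`censoring_spec()` provides study-end censoring uniform on a window
(e.g. 2.5–3.5 years for a 12-month accrual with 3-year average
follow-up), a normal study-end time (redrawing non-positive values), a
dropout mixture (with probability 0.2 the subject instead drops out
uniformly on $(0, 2.5)$ — far more variable, hitting short follow-up
times), an exponential-dropout variant, and no censoring. A censored
record stores the censoring time and the cost accrued by then, with
event indicator 0.

**Censored-cost convention.** The generative model specifies the total
cost at death, not the accrued cost at censoring, so the simulator must
choose one. The default (`"accrued"`) draws the observed censored cost
from the conditional cost law evaluated at the censoring time — accrual
follows the same law up to any observation time. The alternative
(`"scaled"`) records the fraction $U/T$ of the subject's latent total
cost, which is pathwise below the total. Both are available because
neither is canonical.

## Censored-data likelihood and the augmentation sampler

A record contributes
$$ L_i = d_i\big[\ln f_T(t_i) + \ln f_{C|T}(c_i|t_i)\big] +
   (1-d_i)\,\ln \int_{t_i}^\infty f_T(u)
   \Big(\int_{c_i}^\infty f_{C|T}(x|u)\,dx\Big)\,du , $$
treating the accrued cost of a censored record as a lower bound for the
latent total cost. `loglik_record()` evaluates the outer integral by
adaptive quadrature (the inner integral is the parametric cost survival
function in closed form); it is the reference route only. The sampler
(`fit_trial()`) never evaluates it: each iteration imputes, for every
censored record, a latent time from $f_T$ truncated to $(t_i,\infty)$
and tilted by $S_{C|T}(c_i\mid\cdot)$ — an independence
Metropolis–Hastings step whose proposal is an exact inverse-CDF
truncated draw and whose acceptance ratio is the ratio of tilts — and
then a latent total cost by exact inverse-CDF truncated sampling. With
no censored records the imputation loop is skipped, so the target is
exactly the complete-data posterior. `impute_censored()` exposes a
rejection-sampling reference version of the same conditional.

Parameter updates are exact conjugate Gibbs draws for the normal-normal
model (normal and inverse-gamma full conditionals). For the
Weibull-gamma model no conditional is conjugate, so each parameter takes
a random-walk Metropolis step on the log scale (positivity is automatic
and the Jacobian is included); proposal scales adapt toward a 0.44
acceptance rate in windows of 25 iterations during burn-in only and are
frozen afterwards, preserving detailed balance for retained draws.
Starting values are moment-based (Weibull shape from the coefficient of
variation of uncensored times; cost coefficients from a linear fit);
chains beyond the first are jittered for overdispersion. Convergence is
summarized by split-chain scale reduction (flagged above 1.05 with a
warning, never an error — flagged fits still count in the design loop,
with the flag rate reported) and a Geyer-style effective sample size.

Default analysis priors are the diffuse choices of the worked examples:
gamma(0.1, 0.1) on Weibull and cost shapes and scales, gamma(10, 0.1) on
cost intercepts and slopes (shape/rate throughout, so the latter has
mean 100, weakly centered at cost magnitudes); normal(0, $10^4$) on
normal-model means and cost coefficients — read as variance $10^4$, the
diffuse-precision idiom — with inverse-gamma(0.01, 0.01) and
(0.001, 0.001) on time and cost variances.

## The design loop

`run_design()` executes, for every grid size $n$ and replicate
$k = 1,\dots,B$ (default $B = 300$): draw $\theta$ from the design prior
(fixed values for power; independent normals truncated at zero by
resampling for assurance), simulate a censored trial of size $n$ (split
1:1, odd subject to control), fit it with the analysis priors, and
record for every WTP on the grid whether
$\Pr(\mathrm{INMB}>0 \mid \text{data})$ exceeded $1-\phi$. One posterior
fit serves the whole WTP grid, since the INMB is a deterministic map of
the draws. The rejection proportion
$r^{(n)} = B^{-1}\sum_k I\{\cdot\}$ has Monte-Carlo standard error
$\sqrt{r(1-r)/B}$. Ties at exactly zero INMB count as failures (strict
inequality). Each replicate runs on its own RNG stream pre-drawn from
the top-level seed, so results are bit-identical for any worker count
and any replicate can be replayed in isolation.

## Numerical choices and degenerate inputs

* Truncated gamma/normal/Weibull draws use inverse-CDF sampling with the
  uniform variate clamped at $1 - 10^{-16}$; imputed values are nudged
  strictly above their truncation point by one part in $10^{12}$.
* The standalone rejection sampler in `impute_censored()` falls back to
  the best-tilt proposal after 1000 vectorized rounds — reachable only
  for astronomically improbable observed costs.
* Empty arms and fully censored arms are rejected before fitting;
  quadrature failures in `loglik_record()` report the offending record.
* `weibull_mean` and the parameter containers validate positivity at
  construction; containers are plain immutable value objects.

## What the synthetic generator does and does not emulate

The simulators reproduce the joint parametric laws, balanced two-arm
randomization, and independent censoring — the study conditions of the
worked examples (Weibull-gamma fixtures in years/\$k with uniform
study-end windows; normal-normal fixture in months with a normal window
at 36 or 48 months). They do not emulate staggered accrual calendars
beyond those windows, informative censoring, unbalanced allocation
(available via the internal splitter but not exercised), covariates, or
non-parametric cost distributions. Passing tests therefore certify the
method's behaviour *under its own parametric assumptions*, not
robustness to model misspecification.

## A caution on censored costs

The censored-record likelihood treats the accrued cost as a pure lower
bound, but under any realistic accrual mechanism the observed accrued
cost is correlated with (or independently redrawn regardless of) the
latent total, and no complementary cost-censoring event enters the
likelihood — the coarsening is informative. The practical consequence,
visible in this package's validation suite, is that cost-accrual
parameters ($\gamma_k$; $\theta_{\mathrm{sl},k}$) are systematically
inflated when the censoring fraction is large, even though the sampler
provably targets the stated likelihood (it matches an independent
lattice-quadrature posterior on small datasets). The biases largely
cancel inside the INMB at moderate-to-high WTP, which is why the
power/assurance operating characteristics remain broadly in line with
the worked examples, but users analysing heavily censored data should
not interpret the cost coefficients themselves. This is a property of
the estimand construction, not of the sampler. A related effect shows
up in the validation suite's reproduction of the worked examples'
operating characteristics: the assurance penalty relative to power
(roughly ten percentage points at $n = 200$, WTP = 250) reproduces
cleanly, while both absolute levels come out several points above the
examples' printed curves — consistent with this implementation's
posteriors being somewhat tighter than the engine used for those
curves.

## Problem sizes used by the validation suite

The suite runs everything at desk scale, chosen once as sizes a
reviewer can re-run: moment-recovery checks at $10^5$ subjects per arm;
the likelihood-vs-Monte-Carlo oracle at $3\times10^5$ forward draws per
record; the type-I calibration of the success rule at $B = 500$
replicates of $n = 200$ (normal-normal, uncensored, single short
chains); the power/assurance reproduction at $B = 100$ with single
2400-iteration chains (about ±4–5 percentage points of Monte-Carlo
error at the observed proportions); parameter recovery at 2000 subjects
per arm under a uniform 1–2 year censoring window (≈30% censored); and
interval-coverage calibration over 200 replicates of 100 subjects per
arm. The full-scale defaults ($B = 300$, three chains of 12000
iterations) remain the package defaults for real planning runs.

## Worked example

```{r example, eval = FALSE}
library(cedesign)

# a small power surface for the Weibull-gamma fixture (reduced B)
spec <- design_spec(
  design_prior_fixed(wg_design_values()),
  wg_analysis_prior(),
  censoring_spec("uniform_window", window_lo = 2.5, window_hi = 3.5),
  wtp_grid = c(150, 250, 350),
  n_grid = c(100, 200, 300),
  B = 50,
  mcmc = mcmc_settings(chains = 1, burn_in = 400, keep = 2000),
  seed = 7)
res <- run_design(spec, verbose = TRUE)
res
select_sample_size(res, wtp = 250)
plot(res)
```
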