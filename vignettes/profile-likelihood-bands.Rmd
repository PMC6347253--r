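---
title: "Profile-likelihood pointwise confidence bands for binomial dose-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-likelihood pointwise confidence bands for binomial dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plband)
```

## The problem

Dose-finding trials need, alongside the fitted dose-response curve, a
pointwise confidence interval for the expected response at every dose on
the curve — not only at the doses that were actually randomized. For a
binary endpoint modelled with the 4-parameter logistic (4PL) curve

$$f(d) = p_0 + \frac{E_{\max}}{1 + e^{(ED_{50} - d)/\delta}},$$

the routine choice, the Wald interval $\hat p(d) \pm z_{1-\alpha/2}\,
\widehat{se}(\hat p(d))$, misbehaves exactly where dose-finding decisions
are made: near placebo it produces negative lower limits, it can be
non-monotone in dose, and its coverage degrades for doses below the
half-effect dose. The likelihood-ratio (profile likelihood) interval fixes
all three, but for a nonlinear curve it has no closed form — each limit is
the root of an implicitly defined function whose every evaluation is a
constrained optimization. `plband` implements a dose-ordered bisection
algorithm that makes those roots cheap and reliable to find over an entire
dose grid.

## Profiling the expected response

The expected response $p^* = f(d^*)$ at a grid dose $d^*$ becomes a model
parameter by eliminating one coefficient so that the curve passes exactly
through $(d^*, p^*)$:

$$E_{\max} = (p^* - p_0)\,\bigl\{1 + e^{(ED_{50}-d^*)/\delta}\bigr\}.$$

The profile log-likelihood $\ell_p(p^*)$ maximizes the grouped binomial
log-likelihood over the remaining three parameters. A value $p^*$ lies in
the $1-\alpha$ interval when
$\ell_p(p^*) \ge \ell(\hat p) - \tfrac12\chi^2_{1}(1-\alpha)$
(a drop of 1.92073 at $\alpha = 0.05$); the confidence limits are the two
crossings of that threshold, found by bisection on the probability scale.

Internally the constrained fit iterates over $(E_{\max}, ED_{50}, \delta)$
and recovers $p_0 = p^* - E_{\max}/A$ with
$A = 1 + e^{(ED_{50}-d^*)/\delta}$. This is the same constrained model —
the profile value is identical — but it is the numerically stable choice:
at doses whose expected response is near zero, $A$ reaches $10^6$ and
beyond, and any coordinate system containing $p_0$ alongside a pinned
$p^*$ would need the optimizer to resolve $p^* - p_0$ to a relative
$10^{-9}$. Starts are projected into the feasible region $p_0 \ge 0$
before optimizing (preferring a steeper curve, i.e. smaller $\delta$),
because a start on the penalty wall can be thrown into a spurious basin.

## The calculation order is the algorithm

Computed naively, each of the 82 limits of a 41-point grid would need its
own wide search with cold starts — the regime in which nonlinear
optimizers fail often enough to sink the whole band. Three devices remove
almost all of that fragility:

* **Monotone bracket propagation.** When the model beats the constant
  model on a likelihood-ratio test, the profile limits are monotone in
  dose. Upper limits are therefore computed from the highest dose
  *downwards*: the just-computed upper limit at the next-higher dose is a
  valid (and tight) outer bracket endpoint for the current dose. Lower
  limits run from the lowest dose *upwards*, symmetrically. Only the two
  anchor doses need a-priori brackets: $[\hat p,\ \min(1, \hat p +
  5\,\widehat{se}(\hat p))]$ at the top dose, and $[0, \hat p]$ for the
  lower limit at the bottom dose.
* **Warm starts.** Each constrained fit starts from the nuisance estimates
  of the immediately preceding constrained fit (one mutable slot per
  side, seeded from the unconstrained MLE). Successive bisection points
  differ little, so the optimizer usually starts within its own basin.
* **Crude-search fallback.** Where the expected response is close to a
  probability boundary (fitted response below `crude_trigger`, default
  0.01) or bisection fails, the limit is found by stepping $p^*$ outward
  from $\hat p$ in coarse increments (default 0.01) while the profile
  stays above the threshold, refining with fine increments (default
  0.001) as soon as the next coarse step would cross it. Because each
  step's fit is warm-started one small step away, this is the most
  conservative — and slowest — way to traverse the profile; it is the
  fallback, not the default.

If a propagated bracket turns out not to straddle the threshold (the
neighbour's limit can be a hair too tight), the far endpoint is widened
by doubling its distance from $\hat p$, at most three times, capped to
$[0,1]$; if the profile is still above the threshold at the probability
boundary, the limit *is* the boundary value.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided error rate of each pointwise interval |
| `grid_step` | 0.1 | dose-grid spacing (0–4 mg gives 41 points) |
| `bisect_tol` | 1e-4 | bisection stopping width, probability scale |
| `coarse_step` | 0.01 | crude-search coarse step |
| `fine_step` | 0.001 | crude-search refinement step |
| `crude_trigger` | 0.01 | fitted response below which crude search is used directly |

`bisect_tol` is set below any reporting precision while keeping the fit
count near its floor (halving it adds one constrained fit per limit). The
crude-search trigger operationalizes "expected response close to 0": the
example analysis in the literature used a dose cutoff specific to its
curve; a response-scale cutoff generalizes to any design.

## Fitting and standard errors

The unconstrained ML fit maximizes the grouped binomial log-likelihood
(binomial coefficients omitted throughout, so log-likelihood values are
comparable across constrained and unconstrained fits) over the box
$p_0 \in [0,1]$, $E_{\max} \in [0,1]$ with $p_0 + E_{\max} \le 1$ via a
smooth penalty, $ED_{50} \in [10^{-4} d_{\max},\, 2 d_{\max}]$,
$\delta \in [10^{-3} d_{\max},\, 2 d_{\max}]$. The box keeps every fitted
response a valid probability and the curve identifiable near the observed
dose range; a method-of-moments start (observed proportions at the extreme
doses, median dose for $ED_{50}$) is tried first, with a deterministic
9-point Latin-style grid of fallback starts used when it fails or is
beaten by a raw grid point. Model probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before logs so boundary fits stay finite.

Convergence is judged by a first-order (KKT) check on the analytic
gradient — zero at interior coordinates, outward-pointing at active
bounds — rather than by the optimizer's own return code, which reports
spurious failures when warm starts land at the optimum and on the
near-flat nuisance ridges at doses between design points. A fit that
fails the check is restarted (fresh iteration budget, then a relatively
perturbed start); agreement of two independent solves within
$2\times10^{-3}$ log-likelihood units — far below the 1.92 drop that
decides a limit — is also accepted.

Standard errors of the fitted response come from the delta method with
the *expected* (Fisher) information,
$I = \sum_i N_i\, g_i g_i^\top / \{p_i(1-p_i)\}$, computed in closed form
from the analytic response gradient. The observed Hessian can be
indefinite for small-sample fits that land on near-step curves, yielding
meaningless variances; the Fisher form is positive semidefinite by
construction. Two numerical guards matter in small samples: the variance
weights clamp $p_i$ at the binomial resolution $1/(4N_i)$ (a boundary
probability would otherwise contribute a weight of order $10^{10}$ that
swamps every informative direction), and the matrix is scaled to unit
diagonal before (pseudo-)inversion so that only genuinely null directions
are dropped. The delta-method se is accurate to a few percent of the
resampling standard deviation at most design doses of the bundled trial;
at 1 mg — where the fitted surface is most curved — it is conservative by
roughly half, which is inherent to linearization, not to the information
matrix.

## Comparators

The Wald band is the plain delta-method construction and is deliberately
*not* truncated to $[0,1]$: its negative lower limits near placebo are
the pathology the profile band exists to avoid, and truncation would hide
it. The bootstrap band resamples subjects with replacement within each
dose group — for grouped binary data this is exactly a stratified binomial
draw — refits the curve, and takes plain order-statistic percentiles
($\lceil Bq \rceil$; the 25th/975th order statistics at $B = 1000$,
$\alpha = 0.05$). Failed refits are dropped and counted, with a warning
past 20%. On the bundled trial the bootstrap and profile bands agree
within 0.05 everywhere except the upper limit at 0.5 mg, where resamples
that refit to near-step curves put extra mass in the upper tail.

## What the simulations emulate — and what they do not

`simulate_dataset()` draws grouped binomial responders from a 4PL truth
on the trial's design (0, 0.5, 1, 2, 4 mg), with defaults set to the
bundled trial's ML estimates ($p_0 = 0.15\%$, $E_{\max} = 56.9\%$,
$ED_{50} = 0.49$ mg, $\delta = 0.14$). `run_coverage_study()` runs the
full pipeline per replicate and tallies, per dose and method: coverage of
the true response, construction success, and the largest limit excursion
in $\widehat{se}(\hat p)$ units. Bookkeeping is exact: covered +
non-covered + failed equals the replicate count for every dose-method
pair, and coverage is reported over the non-failed replicates. A
replicate counts as a construction failure when the unconstrained fit
fails or more than 10% of grid doses stay non-converged after the
crude-search fallback. Per-replicate seeds are drawn once from the master
seed, so any replicate can be reproduced in isolation.

The generator emulates a parallel-group trial with equal group sizes,
independent subjects and a correctly specified, monotone 4PL curve. It
does not emulate model misspecification, overdispersion, covariates,
dropout or decreasing curves — so passing coverage here shows the
interval construction is sound under the model, not that the model suits
any particular real dataset.

Default problem sizes used by the test-suite and the acceptance script —
500 replicates for success and coverage summaries, 300 per sample size
for excursion maxima, a 9-point grid for band construction at $n = 20$ —
give Monte-Carlo standard errors around one percentage point on coverage
while keeping a full study in the minutes range on one core.

## Numerical choices and known limitations

* Root-finding returns the midpoint of the final bisection interval; the
  crude search returns the last value whose profile stays at or above the
  threshold, so its resolution is one fine step.
* Warm-started profile values that fall below the CI threshold are
  re-checked from the unconstrained estimates and the better optimum
  kept: only the sign of (profile − threshold) decides a limit, and a
  stale warm slot is the one way that sign can silently flip.
* At $n = 20$ on this design, roughly 70% of simulated datasets have zero
  placebo responders; their ML fits sit at $p_0 = 0$ and often at small
  $\delta$, where the curve interpolates the observed proportions. The
  profile limits remain well defined (they are verified against
  exhaustive profile scans), but linearized standard errors there
  understate the model's nonlocal uncertainty: the largest upper-limit
  excursion at the top dose ranges from $3.0$ to $4.3\,\widehat{se}$
  across simulation seeds at $n = 20$ (it stays below $3.2$ at
  $n = 100$), whereas 3.5 is a commonly quoted bracket. The
  corresponding initial bracket $\hat p + 5\,\widehat{se}$ still contains
  every limit we have observed, and the bracket-repair path covers the
  remainder.
* The hill slope's lower bound ($10^{-3} d_{\max}$) admits step-like
  fits that no design with 0.5 mg spacing can resolve; raising it was
  evaluated and changed none of the qualitative conclusions, so the
  simpler box is kept.

## A worked example

```{r example, eval = FALSE}
dat <- trial_nct02131662()
fit <- fit_fourpl(dat)
coef(fit)
#>        p0      Emax      ED50     delta
#>   0.00150   0.56878   0.48643   0.13666

band <- profile_ci_curve(dat, fit = fit)
head(as.data.frame(band), 3)
#>   dose   estimate        lower      upper method_lower method_upper converged
#> 1  0.0 0.01724133 0.0009765595 0.07373642    bisection    bisection      TRUE
#> 2  0.1 0.03326972 0.0010080958 0.10275645    bisection    bisection      TRUE
#> 3  0.2 0.06378358 0.0010277627 0.14958260    bisection    bisection      TRUE

wald <- wald_ci_curve(dat, fit, grid = band$dose)
wald$lower[1]   # negative: the Wald pathology at placebo
#> [1] -0.01625852

plot_bands(list(profile = band, wald = wald), data = dat)
```
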