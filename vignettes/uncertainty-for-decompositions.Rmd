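---
title: "Standard errors for Arriaga decompositions: methods and design"
author: "lexpdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard errors for Arriaga decompositions}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexpdecomp)
```

## The problem

Life expectancy at birth, $e_0$, summarises a whole schedule of
age-specific death rates. When $e_0$ differs between two populations (or
two periods), Arriaga's decomposition attributes the difference to age
groups: each group receives the years of $e_0$ change due to mortality
change within it, combining a *direct* effect (person-years gained inside
the interval) and an *indirect/interaction* effect (extra survivors
exposed to the other population's mortality above the interval). The
contributions are additive: they sum exactly to $e_0^2 - e_0^1$.

Demographic practice usually treats such quantities as free of sampling
error, because vital statistics cover the whole population. But when the
inputs are a sample — a 50% vital-statistics sample, a survey-based
event-history analysis, a small area treated as a hypothetical random
sample — the decomposition inherits sampling variance, and readers
increasingly expect standard errors. This package computes them by four
routes and makes the machinery reusable for any estimator that is a pure
function of demographic rates.

## From rates to the decomposition

A `mortality_schedule` holds, per abridged age group $[x, x+n)$: deaths
${}_nD_x$, person-years ${}_nN_x$, rates ${}_nm_x = {}_nD_x/{}_nN_x$,
and ${}_na_x$, the average years lived in the interval by those dying in
it. `life_table()` builds the standard abridged columns with radix 1:

$$ {}_nq_x = \frac{n\,{}_nm_x}{1 + (n - {}_na_x)\,{}_nm_x}, \qquad
   l_{x+n} = l_x (1 - {}_nq_x), $$
$$ {}_nL_x = n\,l_{x+n} + {}_na_x (l_x - l_{x+n}), \qquad
   L_\omega = l_\omega / m_\omega, \qquad e_x = T_x / l_x, $$

with the open-ended group $\omega$ (85+ by default) having
$q_\omega = 1$ and $e_\omega = 1/m_\omega$. `arriaga_decompose()` then
computes, for closed groups,

$$ \Delta_x = \frac{l^1_x}{l^1_0}\left(\frac{{}_nL^2_x}{l^2_x}
   - \frac{{}_nL^1_x}{l^1_x}\right)
   + \frac{e^2_{x+n}}{l^1_0}\left({}_np^2_x\,l^1_x - l^1_{x+n}\right), $$

and $\Delta_\omega = (l^1_\omega/l^1_0)(e^2_\omega - e^1_\omega)$ for the
open group; population 1 is always the baseline. This life-table-column
form is algebraically identical to chaining products of survival
probabilities but numerically better behaved. Survivorship is built by
sequential double-precision products rather than `cumprod()` (whose
extended-precision accumulator would leave residues of order $10^{-15}$),
so that identical inputs decompose to an exactly zero vector and
additivity holds to machine precision.

The cause-of-death split distributes each $\Delta_x$ over causes in
proportion to cause-specific rate changes,
$\Delta_{x,i} = \Delta_x\,( m^2_{x,i} - m^1_{x,i})/(m^2_x - m^1_x)$, and
sums back across causes exactly. When the all-cause rate change in a
group is numerically zero (below $10^{-15}$) the ratio is undefined: if
the group's contribution is also near zero, every cause gets 0;
otherwise the function stops rather than return arbitrarily large
ratios.

## The four variance engines

**Delta method** (`delta_se()`). The decomposition is linearised in its
parameters: the closed-group survival probabilities ${}_np_i$ of both
populations and the two open-group death counts $D_\omega$ (the open
group contributes variance through the Poisson assumption
$\mathrm{var}(D_\omega)=D_\omega$; treating it as variance-free is
common but understates uncertainty when the open group carries many
deaths). `arriaga_jacobian()` evaluates the exact closed-form
derivatives; the sparsity pattern (baseline probabilities above $x$ and
comparator probabilities below $x$ cannot affect a closed $\Delta_x$) is
exact zeros. Parameter variances are binomial,
$\mathrm{var}({}_n\hat p_i) = (1-{}_np_i)^2\,{}_np_i/{}_nD_i$, or
survey-supplied squared standard errors (`survey_variances()`, which
converts rate SEs to probability SEs through the exact derivative
$dq/dm = n/(1+(n-a)m)^2$). The variance of each $\Delta_x$ is the usual
diagonal quadratic form; the total's derivative w.r.t. each parameter is
the column sum of per-age derivatives, which is what captures the
covariance between age contributions that share parameters. A printed
form of the derivative of $e_{x+n}$ circulates with an ambiguous
subscript ("$e_{x+2n}$"); this package implements the term as
$e_{i+n}$, the value at the end of the *parameter's* interval, which is
the exact derivative — the test suite verifies every entry of the
Jacobian against central finite differences of the implemented
decomposition at relative tolerance $10^{-5}$, so the finite-difference
oracle, not any printed rendering, is the arbiter.

A useful internal consistency check: since the contributions sum to
$e_0^2 - e_0^1$ and the two samples are independent, the delta-method SE
of the total must equal
$\sqrt{\mathrm{var}(\hat e_0^1) + \mathrm{var}(\hat e_0^2)}$ computed by
the independent single-population routine `e0_var_delta()`. The package
tests this identity at $10^{-8}$ relative.

**Monte Carlo** (`mc_se()`). The generic engine for any rate-based
estimator: each replicate draws every rate independently from
$\mathcal N\!\left(m,\; m/N\right)$ — the normal approximation to a
Poisson count over fixed exposure — or from
$\mathcal N(m, \mathrm{SE}^2)$ when survey rate SEs are supplied, then
re-evaluates the estimator. The replicate SD is the SE; percentile
points give the CI. The normal-on-rates approximation is endorsed down
to roughly five deaths per group; below that no method gives sensible
standard errors. Negative draws (vanishingly rare in that regime) are
truncated to zero and counted in the result's `truncated` field so
violations are visible rather than silent.

**Parametric bootstraps** (`poisson_bootstrap()`,
`binomial_bootstrap()`). Death counts are redrawn per group —
Poisson with mean ${}_nD_x$, or binomial with probability ${}_nq_x$ and
trials $\mathrm{round}({}_nD_x/{}_nq_x)$ (floored at 1; the trials
formula does not define an integerisation, so nearest-integer is fixed
here) — rates recomputed over fixed exposures, and the estimator
re-evaluated. Because $q_\omega = 1$ gives the open group zero binomial
variance, its counts are drawn Poisson in both bootstraps. The binomial
bootstrap tends to produce slightly smaller SEs at ages where $q$ is
large (65–84 in the worked example), a known artefact of tying the
number of trials to $D/q$; the test suite asserts this ordering rather
than hiding it.

**Delete-one jackknife** (`jackknife_microdata()`). For person-level
records, each replicate omits one record and
$\widehat{\mathrm{var}} = \frac{N-1}{N}\sum_j (\hat\theta_{(j)} -
\hat\theta)^2$ with $\hat\theta$ the full-sample estimate. It is
provided for modest-sized simple random samples; PSU-level survey
jackknifes and replicate-weight bootstraps need design-specific
machinery and are out of scope, as is the nonparametric bootstrap for
complex surveys.

### Numerical and interface choices

* **Draw order is part of the contract.** Replicates draw population 1
  then population 2, ages ascending, causes ascending within age, with
  one generator stream; identical `sim_config(reps, seed)` and inputs
  give bit-identical results. The command-line interface refuses to run
  a stochastic method without an explicit seed.
* **Percentile CIs** use linear interpolation between order statistics
  (the type-7 quantile definition), fixed permanently so published
  intervals are reproducible.
* **Failure budget.** A replicate on which the estimator errors (e.g. a
  Poisson bootstrap draws zero open-group deaths, leaving $e_\omega$
  undefined) is recorded as failed; more than 1% failures aborts with a
  diagnostic, preventing silently biased SEs.
* **Zero-death groups** are accepted with a warning and contribute zero
  variance — no method assigns positive variance to a group with no
  observed events; the warning keeps the caveat visible.
* **Default `nax`** when a file does not supply it: $n/2$ for closed
  groups, except $a_0 = 0.07 + 1.7\,m_0$ (capped to $(0,1)$) and
  $a_{1\text{–}4} = 1.5$ on grids starting at age 0. The bundled
  worked-example fixtures carry their published `nax` verbatim rather
  than recomputing them, since their provenance is not stated; the
  defaults exist mainly for synthetic data and are overridable per row.
* **Probabilities are clamped** at 1 (with a warning) if extreme inputs
  push $n m/(1+(n-a)m)$ past 1, keeping downstream survivorship defined.
* **No symmetrised decomposition.** The decomposition is directional
  (baseline → comparator); averaging both directions is sometimes done
  but is not implemented, and the direction is printed in all output.

## What the synthetic generator emulates — and what it does not

`synth_schedule()` draws schedules around a Siler hazard
$\mu(x) = c + b e^{\theta x} + A e^{-Bx}$, with group rates defined as
survivorship-weighted hazard averages
$\int \mu S \,dx \big/ \int S \,dx$ on a $1/64$-year grid (the open
group integrated to age 130, beyond which survivorship is negligible) —
the stationary-population rate a real schedule would exhibit. Defaults
were fixed once to emulate the package's worked-example setting:
low-mortality female schedules on the 0, 1–4, …, 85+ grid, exposures of
a 50% sample of an urban region (about 6 million person-years, with a
realistic age pyramid), $e_0 \approx 84.6$ under the default hazard and
$\approx 79.1$ under the documented higher-mortality companion set. At
these sizes every group expects well over five deaths, which is the
regime all four engines are designed for.

Synthetic schedules are Poisson (or binomial) around a smooth hazard
with *independent* groups and *fixed* exposures. Real data violate this
in ways the generator deliberately does not model: population counts are
themselves estimates, rates are measured with error (age misstatement,
late registration), adjacent-age counts can be correlated, and surveys
have design effects. Tests passing on synthetic data therefore validate
the *statistical machinery* — that each engine reproduces the sampling
variance implied by its own assumptions, that CIs attain nominal
coverage under the assumed data-generating process (93–97% over 500
known-truth pairs in the test suite) — not that those assumptions hold
for any particular real dataset.

## Problem sizes used in the test suite

The suite exercises the engines at the sizes a careful analyst would
use: 10,000 replicates for cross-method concordance on the worked
example (delta, Monte Carlo and Poisson bootstrap agree within 10% per
age group there; 1,000 replicates already lands within 5% of the
10,000-replicate answer, which is why 1,000 is the default), 2,000
known-truth simulations for SE calibration (empirical SD within 15% of
the analytic delta SE in every group with at least five expected
deaths), and 500 pairs × 1,000 replicates for CI coverage. The
finite-difference Jacobian check runs on the worked example plus 50
random synthetic pairs.

## Known limitations

* Sampling covariance between age groups within a population is assumed
  zero (independent binomial/Poisson sampling per group), exactly as the
  variance formulas require; estimators of smoothed or model-based rates
  violate this, and then only the survey-SE route (with its independence
  caveat) or a user-supplied estimator over correlated draws would be
  appropriate.
* Exposures are treated as nonrandom throughout.
* Only Arriaga's decomposition ships with analytic derivatives; other
  decompositions (stepwise replacement, continuous-change, Kitagawa) can
  be run through `mc_se()` as user callables but are not implemented.
* The jackknife is delete-one only and reports SEs, not percentile
  intervals.

## A worked call

```{r example, eval = FALSE}
s1990 <- pacific_women("1990", counts = TRUE)
s2019 <- pacific_women("2019", counts = TRUE)
fit <- arriaga(s1990, s2019, se = "delta")
summary(fit)
confint(fit)

# the same decomposition with Monte Carlo percentile intervals
fit_mc <- arriaga(s1990, s2019, se = "montecarlo", reps = 1000, seed = 1)
```
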