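---
title: "Estimating diversification and preservation rates for lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversification and preservation rates for lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagerates)
```

This vignette documents the models behind `lineagerates`, the choices
made where the design was genuinely open, and what the package's tests
do and do not establish.

## The data and the time axis

Two data structures are supported. *Range data* give, per lineage, an
exact origination time and extinction time (or an extant flag) — the
situation for well-documented modern objects such as production runs of
car models. *Occurrence data* give only dated finds per lineage — the
archaeological situation — so the observed age span understates the
true lifespan and the true endpoints must be treated as latent.

All times are "time before reference": non-negative, increasing into
the past, with 0 at the reference (the most recent year in a calendar
dataset, or the cal BP origin for radiocarbon data). One axis serves
both data types, so a single likelihood codebase handles both. The
reference year for calendar data is configurable and affects only
labels, never rates. Year-grain data are treated as continuous times at
integer values; a mid-year offset would cancel in every rate estimate.

A production series with interior gaps is coded as distinct lineages
when a gap exceeds three consecutive missing years (`split_on_gaps()`,
`max_gap = 3`); a gap of exactly three years does not split. Richness
counts use closed intervals on both ends, matching the convention that
a model is "in production" during both its first and last year.

## Birth–death likelihood for ranges

With piecewise-constant origination rate $\lambda(t)$ and extinction
rate $\mu(t)$, the log-likelihood reduces to per-interval sufficient
statistics (births $B_i$, deaths $D_i$, lineage-time $S_i$):

$$\log L = \sum_i B_i \log\lambda_i + D_i \log\mu_i -
(\lambda_i + \mu_i)\, S_i .$$

Conventions chosen here, where the inference literature leaves room:

* Lineages already alive at the old edge of the observation window
  contribute exposure but no birth event; extant lineages contribute
  exposure but no death event. This is the standard survival-likelihood
  treatment of left- and right-censoring at the window edges.
* The likelihood conditions on the observed lineage set: range data are
  treated as complete, with no correction for never-observed lineages.
* No conditioning on survival of the process to the present is applied.
* $\lambda$ and $\mu$ have independent shift-time partitions, so an
  extinction-rate shift can be inferred without a simultaneous
  origination-rate shift.

The constant-rate maximum-likelihood estimates are the classical
occurrence/exposure ratios $\hat\lambda = B/S$, $\hat\mu = D/S$.

## Reversible-jump MCMC over rate shifts

The sampler starts from the constant-rate model and explores models of
any number of shifts. Priors: the number of shifts per rate model is
Poisson($\nu$), shift times are uniform over the window (order
statistics), rates are Gamma(shape, rate), the preservation rate is
Exponential(0.01) (vague: prior mean 100, accommodating the large
preservation rates typical of dense historical records), and the
gamma-heterogeneity shape is Exponential(0.1).

The default $\nu = 0.5$ makes the constant-rate model the prior mode
(61% prior mass on zero shifts) while leaving shift detection easy when
the data demand it. A Poisson on the *shift* count, with uniform times,
also has the property that the number of shifts falling in any bin of
width $w$ is exactly Poisson($\nu w/W$), which gives a closed form for
the prior per-bin shift frequency used by the Bayes-factor machinery —
and an analytic oracle for testing it.

The dimension-changing move draws a split time uniformly in the window
and perturbs the old rate symmetrically in log space with a Gaussian
auxiliary variable $z$: if the split divides an interval of length
$\ell$ into parts $\ell_L, \ell_R$, the new rates are
$\log r_{L,R} = \log r \pm (\ell_{R,L}/\ell)\, z$, so the reverse merge
restores the length-weighted geometric mean. The acceptance ratio
includes the Poisson/order-statistics prior ratio, the proposal and
reverse-choice densities, and the Jacobian $r_L r_R / r$. This
construction is not dictated by the underlying theory — many valid
split/merge pairs exist — so its correctness is established by
sampling-the-prior tests: with the likelihood disabled, 10^5 thinned
samples must reproduce the Poisson shift-count prior (mean and
chi-square), uniform shift times and gamma rates (Kolmogorov–Smirnov),
and the exponential preservation prior. This is the decisive test of
transdimensional bookkeeping; an error in any Jacobian or density term
shows up immediately as a distorted marginal.

Within-model moves are standard: log-scale multiplier proposals on
rates (with the $r'/r$ Hastings correction), sliding-window shift-time
proposals reflected at the neighboring shifts, and, in occurrence mode,
sliding-window proposals on each lineage's latent times truncated at
its occurrence bounds. Default move weights (rates 40%, shift times
20%, add/remove 20%, latent times 15%, preservation 5%; range mode
redistributes the latter two) are config-exposed; they affect mixing
speed, not the stationary distribution.

Caching: each rate model keeps its sufficient statistics and likelihood
component; latent-time updates apply O(1) count deltas and O(k)
exposure deltas. `run_chain(..., debug = TRUE)` recomputes the
likelihood from scratch every 10^4 iterations and stops on any drift
beyond 1e-8.

## Occurrence mode: preservation and latent times

Occurrences of a lineage alive on $[t_e, t_s]$ form a Poisson process
with intensity $q(t)$. All preservation likelihoods condition on the
lineage being observed at least once — the $-\log(1 - e^{-\Lambda})$
term with $\Lambda = \int q$ — because never-sampled lineages cannot
enter the data. Occurrence times are treated as ordered; the $k!$ count
multiplicity is constant in the parameters and is dropped.

The bell-shaped (NHPP) intensity is
$q(t) = q \cdot \mathrm{Beta}\!\big((t_s - t)/s;\, a, b\big)$ with
$s = t_s - t_e$, so $\Lambda = q\,s$ exactly and the model reduces to
the homogeneous one at $a = b = 1$. The default shapes $a = b = 2$ give
a symmetric bell — production starts small, peaks, and declines — and
both shapes can instead be estimated by maximum likelihood. The
epoch-piecewise (TPP) model takes its epoch boundaries as user
configuration, since they encode domain periodization.

For the maximum-likelihood model test (run before any MCMC), each
lineage's lifespan is a plug-in: the observed occurrence span padded
per side by span/(k − 1), the expected overshoot of the true endpoints
beyond the extreme order statistics of k uniformly placed occurrences.
(An unpadded or under-padded span places the extreme occurrences at the
bell intensity's zero-density edges and spuriously penalizes the
bell-shaped model.) The model test fits the bell shapes by maximum
likelihood, so the bell model nests the homogeneous one and the AICc
comparison is well-posed; the full joint treatment of the latent
endpoints lives in the sampler. Gamma
heterogeneity across lineages uses the standard discretization: four
equal-probability categories of a mean-one gamma, category means via
the incomplete-gamma identity. AICc uses the number of analyzed
lineages as the sample size; report flags mark AICc differences of 2,
6, and 10.

In the sampler, the observation window is fixed at the oldest
occurrence plus a 20% pad of the observed span (configurable), and
latent origination times are constrained inside it; every origination
strictly inside the window counts as a birth event. A window tied to
the current latent maximum would make the shift-time prior
normalization depend on a moving parameter for no inferential gain.
Latent times are initialized at the observed span padded by one
expected occurrence gap $1/\hat q$.

## Radiocarbon calibration

Calibration evaluates, on a calendar grid (default 1 yr), the Normal
density of the measured radiocarbon age given the curve mean, with
variance equal to the measurement and curve variances summed, then
normalizes. The curve mean and error are linearly interpolated; tails
below cumulative mass 1e-6 per side are truncated to bound storage. No
reservoir corrections or curve mixing are applied. Dating uncertainty
is propagated by drawing, per replicate dataset, one age per occurrence
from its calibrated distribution (100 replicates by default), analyzing
each replicate, and pooling post-burn-in posterior samples with equal
weight per replicate. Per-date normalization before resampling is
assumed. The bundled curve file is synthetic (a smooth wiggle-added
stand-in in the IntCal text layout) and is for examples and tests only.

## Simulators and what the tests show

`simulate_bd()` is an exact event-driven implementation: founders start
at the old window edge (matching the edge convention of the
likelihood, rather than growing a tree from a single root), waiting
times are exponential with memoryless restarts at rate-shift
boundaries, and survivors at the young edge are marked extant.
`simulate_preservation()` thins each lineage's lifespan by the chosen
intensity and reports dropped (never-observed) lineages so conditioning
effects can be tested explicitly. `simulate_radiocarbon()` inverts
calibration by pushing calendar ages through the curve with Gaussian
noise.

The named fixtures fix the study conditions used by the tests:
`constant_rates` (λ = 0.2, μ = 0.1, window [25, 0], 30 founders —
roughly 700 lineages), `two_regime` (λ drops 0.3 → 0.05 at the window
midpoint, μ = 0.1 constant — roughly 1000 lineages),
`car_like` (a century-long near-critical range dataset), and
`neolithic_like` (22 observed lineages on a [3, 0] window in units of
1000 years, bell preservation with q = 80 occurrences per lineage per
time unit — the scale of a densely dated archaeological compilation;
the founder seed is scanned deterministically until exactly 22 lineages
are observed).

These simulations match the generative assumptions of the likelihoods
exactly. Passing recovery tests therefore demonstrates internal
consistency — correct likelihoods, correct sampler, correct
bookkeeping — not robustness to the ways real data violate the model:
age-heaping and calendar rounding, non-Poisson clustered sampling,
taxonomic lumping/splitting of lineages, preservation correlated with
lifespan, or diversity-dependent rates. Those effects are outside the
scope of the tests.

## Problem sizes and numerical choices

Test and example runs use desk-scale settings: chains of 10^5
iterations on fixtures of 500–1200 lineages, prior-recovery runs of a
few million likelihood-free iterations, and two-replicate calibration
workflows; full-scale profiles (tens of millions of iterations, 100
replicates) are configuration, not code. Rates are floored at 1e-4 at
initialization; boundary MLEs (zero event counts) warn rather than
fail; `log(1 - e^{-x})` uses the stable split at `log 2`; HPD intervals
use the sorted sliding-window method with mass `ceiling(0.95 n)`;
model-selection ties are broken by model name for determinism. Every
stochastic entry point takes or respects a seed, and chains are
bit-reproducible given one.

## Known limitations

* The sampler's preservation layer supports the homogeneous and
  bell-shaped models; the epoch-piecewise model is available in the
  ML model test, where its fixed epochs are interpretable, but not as
  a sampler component.
* Net diversification can only be summarized where both rate models
  share the window; disjoint windows across replicate logs are
  rejected rather than aligned.
* No covariate-dependent or diversity-dependent rate models.
* Calibration assumes a single terrestrial curve; no marine/reservoir
  handling, and no summed-probability population proxies.
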