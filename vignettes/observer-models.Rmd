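---
title: "Bayesian observer models of interval timing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of interval timing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlntiming)
```

## The generative model

In a temporal reproduction trial an observer is presented a duration $t_s$,
forms a noisy internal measurement $t_m$, maps it to an internal estimate
$t_e$, and reproduces it as $t_p$. `mlntiming` implements the standard
three-stage Bayesian observer:

1. **Measurement.** $t_m \sim N(t_s,\, w_m t_s)$. The Weber fraction $w_m$
   is the clock (perception) noise; the SD grows linearly with the timed
   duration, which is the scalar property of interval timing.
2. **Estimation.** $t_e$ is the posterior mean (Bayes least squares) of the
   duration given $t_m$:
   $t_e = \int t\, \pi(t)\, L(t \mid t_m)\, dt \,/\! \int \pi(t)\, L(t \mid t_m)\, dt$,
   where $\pi$ is the prior over durations and
   $L(t \mid t_m) = N(t_m;\, t,\, w_m t)$ the Weber-scaled likelihood.
3. **Reproduction.** $t_p \sim N(t_e,\, \mathrm{SD}_{rep})$ adds motor
   noise.

The central tendency effect — over-reproduction of short and
under-reproduction of long durations — falls out of stage 2: the noisier the
clock, or the more concentrated the prior, the more $t_e$ is pulled toward
the prior's centre of mass.

### Prior families

Three families are available on a shared integration grid
(`make_grid()`; by default 0.5–1.5 times the stimulus range, e.g.
0.585–2.52 s for the 1.17/1.4/1.68 s task):

* **uniform** (`prior_uniform`): constant on the stimulus range, zero
  outside. Its edges snap to the nearest grid points so that all families
  live on one grid.
* **gaussian** (`prior_gaussian`): normal with mean at the median stimulus
  duration and SD `p_sd`, truncated below zero. Truncation is implemented
  implicitly: the grid support is strictly positive and the density is
  renormalized on it.
* **mixture lognormal, "mln"** (`prior_mln`): one lognormal component per
  presented duration, equal weights. Component means follow the geometric
  series $m_i = 1.4 \times p_r^{k_i}$, $k_i \in \{-1, 0, 1\}$, so the pull
  ratio `p_r` moves the outer components: `p_r` equal to the stimulus ratio
  (1.2) places them at the presented durations (no pull encoded in the
  prior), `p_r = 1` collapses them all onto the middle duration (maximal
  pull, a single lognormal). Component SDs scale with their means (scalar
  property): $s_i = p_{sd}\, m_i / 1.4$, so `p_sd` is the SD of the middle
  component in seconds.

**Lognormal parametrization.** `p_sd` and the component means are
*linear-space* moments; each component is moment-matched,
$\sigma^2 = \ln(1 + s^2/m^2)$, $\mu = \ln m - \sigma^2/2$. This choice makes
the pull arithmetic exact on the linear scale (a `p_r` of 1.05 yields means
$1.4/1.05 = 1.333$, $1.4$, $1.47$), which is how the component locations are
conventionally reported. The alternative — treating `p_sd` as the log-scale
$\sigma$ — would make the stated means the component *medians*; we document
the moment-matched reading as the package's definition.

`prior_mln_free()` admits arbitrary locations, SDs and weights; with many
narrow equidistant components the mixture mimics a uniform prior with sharp
shoulders, with wide components it becomes unimodal. This matters
behaviourally: a sudden transition from negligible to substantial prior
density produces a sigmoid (strongly curved) central tendency pattern,
which `bias_curve()` exposes as the second difference of the noiseless
bias curve.

### Noise decomposition

For the uniform and gaussian families the reproduction Weber fraction $w_p$
is a free parameter, so the fit may choose $w_p < w_m$ — implying a *less*
noisy reproduction than perception, which is theoretically awkward since
reproduction involves the same clock plus a motor act. The mln family
instead ties the stages: $w_p = w_m + \Delta w_p$ with $\Delta w_p \ge 0$
the additive motor noise. Two readings of the reproduction SD are
selectable via `observer_params(reproduction_noise=)`:

* `"scaled"` (default): $\mathrm{SD}_{rep} = (w_m + \Delta w_p)\, t_e$ —
  the whole reproduction noise obeys the scalar property;
* `"literal"`: $\mathrm{SD}_{rep} = w_m t_e + \Delta w_p$ — the motor term
  is a constant number of seconds.

The scaled reading keeps $w_p$ a genuine Weber fraction and is used
throughout; the literal variant exists for sensitivity analyses.

Durations are positive, so non-positive draws of $t_m$ or $t_p$ are
rejected and redrawn rather than truncated at zero; truncation would bias
the noiseless limit upward. With the parameter ranges used here a
non-positive draw requires a $z$ below $-1/w_m \le -5$, so rejection is
vanishingly rare and the means are essentially unaffected.

### Numerical evaluation of the posterior mean

All integrals use the rectangle (Riemann-sum) rule on an equidistant grid,
1024 points by default — at second-scale durations the quadrature error is
orders of magnitude below the fitting tolerance. The posterior weights are
accumulated in log space with a per-measurement max shift: the naive
product of prior and likelihood underflows double precision when a narrow
prior meets a measurement far outside its mass, which would spuriously
discard legitimate parameter vectors. A degenerate-posterior error is
raised only when prior and likelihood genuinely share no support.

The likelihood includes the proper density normalization $1/(w_m t)$ in
the candidate duration $t$ (`likelihood_over_grid(normalized = TRUE)`).
This makes the estimator exact in the conjugate constant-SD limit, which
the test suite exploits as a closed-form oracle. The raw standardized
kernel without the Jacobian is available behind the flag for sensitivity
checks; with Weber scaling the two differ slightly because the Jacobian
down-weights long candidate durations.

During simulation the map $t_m \mapsto t_e$ is precomputed on a 512-point
lattice spanning 0.5–1.5 times the grid and interpolated linearly; the
lattice is recomputed per (prior, $w_m$) combination. Interpolation error
is far below the Monte-Carlo resolution of the fitting objective, and the
lattice makes the exhaustive grid search tractable on one CPU.

## Fitting

`fit_observer()` implements an exhaustive ("linear") grid search. For every
parameter vector in the Cartesian grid it simulates `n_sim` trials per
stimulus duration (1000 by default), computes the 10/30/50/70/90%
reproduction quantiles per duration (type-7 interpolated order statistics,
the default estimator of mainstream statistical environments), and scores
the vector by the RMSE against the observed quantiles across all
duration-by-probability cells. Ties are broken by the first vector in grid
order. The default ("full") grids are:

| parameter | range | values | families |
|---|---|---|---|
| $w_m$ | 0.005–0.2 | 20 | all |
| $w_p$ | 0.005–0.2 | 20 | uniform, gaussian |
| $\Delta w_p$ | 0.0001–0.15 | 20 | mln |
| $p_{sd}$ | 0.01–0.3 s | 20 | gaussian, mln |
| $p_r$ | 1.02–1.2 | 10 | mln |

**Centering.** Structural over- or under-reproduction is not of interest
when studying central tendency, so observed reproductions are mean-centered
before fitting: $t_p' = t_p - \bar t_p + \bar t_s$. The package applies the
*same* centering to the simulated reproductions of every candidate vector.
This makes the objective invariant to a uniform shift on both sides; if only
the observed side were centered, a candidate's own structural shift
(typically ~0.01 s for mln observers, whose bias at the three durations does
not sum to zero) would contaminate every quantile cell and systematically
displace the minimizer — in self-recovery experiments the generating vector
then no longer wins even with unlimited data.

**Common random numbers and stratification.** All grid vectors share one
set of base standard-normal draws derived from the seed, so RMSE
differences across the grid reflect the parameters rather than sampling
noise. The draws are additionally stratified per duration
(Latin-hypercube pairing of the measurement and reproduction stages):
the simulated quantiles estimate exactly the same model quantiles as plain
sampling, with a much smaller variance. Rejection redraws come from a
deterministic reserve pool, so a fit is a pure function of
(trials, grid, seed).

**Model averaging.** Point estimates ignore the flatness of the RMSE
surface, so parameters are also summarised by AIC-weighted model averaging
over all grid vectors. The RMSE objective is converted to an AIC through a
Gaussian quasi-likelihood on the quantile residuals:
$AIC_i = n \ln(\mathrm{RMSE}_i^2) + 2k$ with $n$ the number of quantile
cells (15 for three durations) and $k$ the number of free parameters
(2 uniform, 3 gaussian, 4 mln); weights are
$\exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ and each parameter is averaged
marginally. Vectors with infinite RMSE (degenerate posterior) get weight
zero. With only 15 cells the weights are deliberately mild, so the average
shrinks toward the interior of the grid when the surface is flat — the
best vector and the average bracket the plausible region.

**Reduced profile.** `grid_spec(profile = "reduced")` keeps every second or
third value of the full grids (6 × 7 × 7 × 5 for mln). Thinning — rather
than re-spacing — means every reduced value is also a full-grid value, so a
data-generating vector that sits on the full grid keeps exact or adjacent
representatives. The CLI `--reduced` flag pairs these grids with
`n_sim = 300` for quick looks; programmatic use can keep `n_sim = 1000`.

### Identifiability

Parameter recovery on synthetic data is exact in the limit: with very large
trial tables the search returns the generating vector. At realistic data
sizes (around 1000 trials per duration) the quantile profile constrains
$(w_m, \Delta w_p)$ well, but $p_{sd}$ and $p_r$ trade off along a ridge —
a slightly wider prior with less pull predicts nearly the same quantiles as
a narrower prior with more pull (profile distances of ~0.003–0.005 s
against an observed sampling noise of ~0.01 s). Estimates can therefore
wander one or two grid steps along this ridge between datasets. Fits to a
single participant should be read accordingly: $w_m$ and $\Delta w_p$ are
sharp, the prior-shape parameters are best interpreted at the group level
or with the averaged estimate. The pull is much better identified when it
is strong (small $p_r$) than when it is absent.

## Prior recovery from density curves

`fit_mixture()` approximates a target prior-density curve by a
six-component lognormal mixture, minimizing the summed squared difference
(SSD) over a 200–1600 ms window with Nelder-Mead. The target is first
interpolated onto a 1-ms lattice so the SSD does not depend on the file's
native resolution. Three modes: `free` (locations, weights and one shared
CV), `fixed_weights` (weights 1/6), `fixed_locations` (locations at the
presented durations). One shared CV scales all component SDs by their means,
mirroring the scalar property of the prior construction.

Weights are constrained to [1/15, 10/15] by a bounded logistic
transformation followed by renormalization; because renormalization alone
can nudge a weight past a bound, a steep smooth penalty on
post-renormalization violations keeps optima feasible. Starts are
randomized, except the first restart, which is always the canonical start
(equal weights at the stimulus locations, CV 0.15) — the returned best fit
can therefore never be worse than that start. Nelder-Mead's relative
tolerance (1e-8, 5000 iterations) tends to trigger early on the ridge of
this objective, so each restart chains up to five simplex runs, each
starting from the previous optimum, until the SSD stops improving. Ten
restarts are the default.

## Synthetic cohorts

`generate_cohort()` draws per-participant mln parameters from group-level
Gaussians truncated to the grid ranges and simulates each participant's
trial table. The default two-group design mirrors a healthy-control
(n = 25) versus memory-impaired (n = 10) contrast: the impaired group has a
noisier clock (mean $w_m$ 0.11 vs 0.06) and a more compact prior (mean
$p_r$ 1.06 vs 1.15), the pattern by which a stronger central tendency in a
memory-affected population decomposes into clock and memory contributions.
Sizes and distributions are configurable; the defaults are a synthetic
stand-in, not an empirical claim.

What the generator emulates: the scalar property, central tendency with the
correct signs and its dependence on $w_m$, $p_{sd}$ and $p_r$, and
between-participant parameter variation. What it does not emulate: sequence
effects (the prior is static within a fit), lapses and outliers, structural
over-/under-reproduction (centering would remove it anyway), non-Gaussian
motor noise, and feedback-driven learning. Passing recovery tests on this
generator therefore validates the estimation machinery under the model's
own assumptions; they say nothing about misspecification on real data.

## Problem sizes used by the test suite

The shipped tests run reduced grids (6 × 7 × 7 × 5) with 300–1000 simulated
trials per duration, ten-seed recovery studies at 1000 observed trials per
duration, and six-participant cohorts — sizes chosen so the full suite
completes in minutes on a single core while still exercising every code
path at the fidelity the analyses above require. Full-grid searches
(80 000 mln vectors) use the same code path and simply take longer.

## Known limitations

* The $(p_{sd}, p_r)$ ridge discussed under *Identifiability*.
* The AIC construction from an RMSE objective is a quasi-likelihood
  convention; alternative information criteria would reweight, not reorder,
  the grid.
* The grid search is embarrassingly parallel but runs serially here.
* MCMC or gradient-based estimation, sequential prior updating, and readouts
  other than the posterior mean are out of scope.
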