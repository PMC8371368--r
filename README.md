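# mlntiming

Bayesian observer models of interval-timing reproduction, with a
mixture-lognormal prior.

## The problem

In temporal reproduction tasks, people's reproductions regress toward the
mean of the durations they have experienced: short intervals are
over-reproduced and long ones under-reproduced (the *central tendency
effect*), and reproduction variability grows with the timed duration (the
*scalar property*). Bayesian observer models explain both: a presented
duration $t_s$ is measured with Weber-scaled clock noise,
$t_m \sim N(t_s, w_m t_s)$, combined with a prior $\pi(t)$ over durations,
read out as the posterior mean

$$t_e = \frac{\int t\,\pi(t)\,N(t_m;\,t,\,w_m t)\,dt}
             {\int \pi(t)\,N(t_m;\,t,\,w_m t)\,dt},$$

and reproduced with additional motor noise,
$t_p \sim N(t_e, \mathrm{SD}_{rep})$.

`mlntiming` implements three prior families — uniform over the stimulus
range, truncated Gaussian, and a **mixture of lognormal components** (mln),
one per presented duration, with equal weights, component means on a
geometric lattice $m_i = 1.4\,p_r^{k_i}$ and SDs scaling with the means.
The pull ratio $p_r$ encodes how far previous experience has dragged the
outer components toward the centre; the mln family also ties reproduction
noise to clock noise, $w_p = w_m + \Delta w_p$, so motor noise is estimated
as a separate, nonnegative quantity. Fitting is by exhaustive grid search
minimizing the RMSE between observed and model-simulated 10/30/50/70/90%
reproduction quantiles, with AIC-weighted model averaging across the grid.
The package is aimed at computational cognitive modellers who want a
tested, reproducible implementation of this model class — including prior
recovery from density curves and synthetic cohorts with known ground truth.

## Worked example

Simulate an mln observer on the standard 1.17/1.4/1.68 s task and recover
its parameters:

```r
library(mlntiming)

stim <- geometric_durations(1.4, 1.2, -1:1)   # 1.167, 1.4, 1.68 s
truth <- observer_params("mln", w_m = 0.0871, delta_w_p = 0.0474,
                         p_sd = 0.1168, p_r = 1.1)
trials <- simulate_dataset(truth, stim, 1000, seed = 1)

central_tendency_slope(trials)
#> [1] 0.623565

fit <- fit_observer(trials, spec = grid_spec("mln", profile = "reduced"),
                    stimuli = stim, n_sim = 1000, seed = 2)
fit
#> Bayesian observer fit (mln prior family)
#>   grid vectors: 1470, simulated trials per duration: 1000, seed 2
#>   best quantile RMSE: 0.008336 s
#>   best vector:      w_m = 0.08711, delta_w_p = 0.04744, p_sd = 0.1168, p_r = 1.1
#>   AIC-averaged:     w_m = 0.08715, delta_w_p = 0.04737, p_sd = 0.1362, p_r = 1.066
```

The slope of mean reproduction on presented duration is 0.62 — well below
1, the signature of central tendency. The best-fitting grid vector here
equals the generating one; the AIC-averaged estimate agrees on the noise
parameters and spreads along the prior-shape ridge (`p_sd` up, `p_r` down —
a wider prior with more pull predicts almost the same quantiles). Residual
quantile errors are a few milliseconds:

```r
round(residuals(fit), 3)
#>             10%    30%    50%    70%   90%
#> 1.166667 -0.020 -0.004 -0.002  0.006 0.016
#> 1.400000 -0.016 -0.008 -0.002 -0.004 0.010
#> 1.680000 -0.001 -0.003 -0.008 -0.004 0.013
```

`summary()`, `predict()`, `plot()`, `simulate()` and `coef()` work as for
any fitted model. Priors are first-class objects
(`prior_uniform`, `prior_gaussian`, `prior_mln`, `prior_mln_free`),
`bias_curve()` traces the predicted central tendency over a dense duration
sweep, `fit_mixture()` recovers a six-component lognormal mixture from a
target prior-density curve, and `generate_cohort()` builds synthetic
two-group cohorts (noisy-clock / compact-prior contrast) with ground truth
for end-to-end recovery studies.

A small CLI wraps the same functions
(`simulate`, `fit`, `prior-fit`, `recover`, `bias-curve`):

```sh
Rscript inst/cli/mlntiming simulate --model mln --n 1000 --seed 1 --out trials.csv
Rscript inst/cli/mlntiming fit --trials trials.csv --model mln --reduced --out-prefix fit
```

Every run writes a JSON manifest (settings, seed, version) next to its
outputs.

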