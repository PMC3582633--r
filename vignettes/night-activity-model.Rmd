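---
title: "Modelling nocturnal at-sea activity from immersion loggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nocturnal at-sea activity from immersion loggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`moonbird` analyses the nightly at-sea activity of seabirds carrying
leg-mounted immersion loggers, relating the proportion of the night a bird
spends on the water to the fraction of the moon illuminated and to
sea-surface temperature (SST). This vignette is the package's account of
the science: the data model, the hierarchical model and its sampler, the
synthetic-data generator, and the numerical and design choices behind them.

```{r setup}
library(moonbird)
```

## From logger blocks to nightly binomial counts

The loggers score wet/dry every 3 s and sum the scores within 10-min
blocks, so each block carries an integer 0–200. Over a 12-hour night
window there are 72 blocks and the aggregate nightly count is at most
72 × 200 = 14,400; `night_constants()` computes these from the sampling
geometry rather than hard-coding them.

Blocks are assigned to nights by their **start** time: with the default
18:00–06:00 window (local study time; the Galápagos have no
daylight-saving shifts, so a fixed UTC−6 offset suffices), blocks from
18:00 to midnight belong to that evening's date and blocks before 06:00 to
the previous evening's. Assignment by start time is one unambiguous
convention among several defensible ones; nothing downstream depends on
which edge of a 10-min block is used.

Nights with missing blocks are **kept**, with the binomial trial count
shrunk to 200 × (observed blocks). This preserves data and models the
missingness as ignorable; the alternative — dropping incomplete nights —
is available through the `min_blocks` filter of `aggregate_nights()`
(setting it to 72 keeps complete nights only). Duplicate
(bird, timestamp) rows are a hard error rather than last-wins, because a
silent overwrite would hide logger faults.

A **wet bout** is a maximal run of consecutive blocks each containing at
least one wet 3-s sub-period (at least 3 s on the water); all-dry blocks
form the complementary flying bouts. We deliberately use the weakest
literal threshold (count ≥ 1) for a block to join a bout; a stricter
per-block threshold would only merge or drop short bouts, and
`detect_wet_bouts()` is verified against a brute-force run counter, so the
rule is easy to change without risk.

`proportion_bout_regression()` is a diagnostic ordinary-least-squares fit
of the nightly aggregate count on the bout count, mirroring a standard
field check that time on the water and number of landings track each
other. On real data these are strongly coupled; on data from this
package's generator they are not (see below), so the diagnostic mainly
serves as an audited OLS surface.

## Covariates

The nightly design row is `(1, SST, moon fraction)`. Moon fraction is a
single calendar value per night (0 new to 1 full); no moonrise/moonset or
within-night interpolation is attempted, because the model consumes one
phase value per night. SST is treated as a daily series and is **not**
centred or scaled by default, so the SST coefficient is a per-degree
effect on the log-odds scale; `standardize_sst = TRUE` is available for
numerical conditioning, with the scaling recorded in attributes.

Nights whose date is absent from the covariate table are dropped by
default (with a message counting them); linear interpolation between the
nearest observed dates is available via `policy = "interpolate"`.
Imputation beyond that is a modelling choice the package does not make
silently.

## The hierarchical model

For bird $i$ on night $t$, with aggregate count $y_{it}$ out of $n_{it}$
trials:

$$
y_{it} \sim \mathrm{Binomial}(n_{it},\ p_{it}), \qquad
\mathrm{logit}(p_{it}) = \mathbf{x}_t' \boldsymbol\beta_i
$$

$$
\boldsymbol\beta_i \sim \mathrm{MVN}(\boldsymbol\mu_\beta, \Sigma), \qquad
\boldsymbol\mu_\beta \sim \mathrm{MVN}(\boldsymbol\mu_0, \Sigma_0), \qquad
\Sigma^{-1} \sim \mathrm{Wishart}(\nu_0, S_0).
$$

The trial count is the large per-night $n$ (up to 14,400 3-s
sub-periods), matching the aggregated-count likelihood exactly rather
than re-expanding to per-block Bernoullis. The likelihood is plain
binomial — there is no overdispersion term beyond the bird-level random
coefficients; within-night extra-binomial clustering (a bird that lands
once and stays) is therefore absorbed into, and can inflate, the
bird-night variation. This is a known limitation.

**Priors.** Defaults are weakly informative and proper:
$\boldsymbol\mu_0 = \mathbf{0}$, $\Sigma_0 = 100\,I$ (SD 10 per
coefficient, diffuse on the logit scale), $\nu_0 = 4$ (the minimal proper
choice one above the dimension) and $S_0 = I$. All are overridable via
`prior_spec()` or a YAML file read by `read_fit_config()`. Two practical
consequences of the identity Wishart scale at small bird counts: the
posterior of $\Sigma$ cannot concentrate much below $S_0/(\nu_0 + m)$
per entry, so population-mean components whose true between-bird spread
is tiny (the per-degree SST slope) carry conservative posterior SDs, and
new-bird predictive bands stay wide until $m$ is large. Both effects
shrink as birds accumulate and are the honest price of a proper prior
that never degenerates.

**Sampler.** `sample_posterior()` is Metropolis-within-Gibbs:

1. $\boldsymbol\mu_\beta \mid \cdot$ — exact multivariate-normal
   conjugate draw (`conjugate_mu_update()`).
2. $\Sigma^{-1} \mid \cdot$ — exact Wishart conjugate draw
   (`conjugate_precision_update()`), unless a `fixed_sigma` is supplied
   for degenerate checks.
3. Each $\boldsymbol\beta_i \mid \cdot$ — random-walk Metropolis on the
   3-vector with a multivariate-normal proposal.

Because SST is uncentered, the three coefficients live on very different
scales and a spherical proposal would mix poorly. The proposal covariance
is therefore preconditioned once at initialisation by the bird's
Gaussian-approximation posterior covariance
$(X_i' W_i X_i + \Sigma^{-1})^{-1}$ (with $W_i = n\,p(1-p)$ at the
initial state), and only a scalar step size adapts during burn-in — a
Robbins–Monro update with gain $\min(0.2,\ 3/\sqrt{t})$ targeting 30%
acceptance, the centre of the usual 20–40% band for random-walk
proposals. Adaptation freezes at the end of burn-in, preserving detailed
balance for the retained draws. Initial values: each
$\boldsymbol\beta_i$ at the bird's empirical pooled logit (clipped to
$[10^{-6}, 1-10^{-6}]$ before the transform) with zero covariate
effects, $\boldsymbol\mu_\beta$ at their mean, $\Sigma$ at the identity.

Defaults are 10,000 iterations with the first 1,000 discarded as
burn-in, one chain, and full seeded determinism: identical seed, config
and data give byte-identical draws (and byte-identical CSVs from
`write_posterior()`).

**Numerical choices.** `log1p(exp(x))` switches to `x` above 35 to avoid
overflow; conditional covariance matrices are symmetrised
(`(V + V')/2`) before Cholesky factorisation to absorb round-off; a
singular conditional covariance raises a diagnostic error rather than
propagating `NaN`s; a constant covariate column triggers a
weak-identifiability warning, not an error; `n = 0` observations
contribute zero log-likelihood, so a no-data run reproduces the prior.

## Inference outputs

`summarize_population()` (also available as `tidy()`) reports the
empirical mean, SD and **equal-tailed** 2.5/97.5 percentile interval per
population coefficient — percentile rather than highest-posterior-density
intervals, the common default when a "95% CI" is reported without
qualification — plus an `excludes_zero` flag, which is exactly the
significance criterion used for such models.

`posterior_predictive_p()` propagates draws through the logit link for
each night. In the default `"population"` mode, each retained draw first
samples a fresh coefficient vector from
$\mathrm{MVN}(\boldsymbol\mu_\beta, \Sigma)$ of that draw — the
predictive for an unobserved bird, which is what a single population band
over the study nights represents; `"bird"` mode uses a tagged bird's own
coefficient draws. The new-bird randomness uses a seed separate from the
chain so prediction never perturbs a stored fit.

`actogram_matrix()` averages `wet_count / 200` across birds per
(night, block-of-night) cell; on complete single-bird nights its row sums
equal the nightly proportion × 72, which ties it back to
`aggregate_nights()` in the tests.

## The synthetic-data generator

`simulation_spec()` + `simulate_birds()` form the generative twin of the
model, so the full pipeline runs with no field data:

* **Moon**: a deterministic raised cosine
  $(1 - \cos 2\pi t / 29.53)/2$ from a configurable new-moon start —
  the model consumes only the illuminated fraction, so no ephemeris is
  needed.
* **SST**: seasonal cosine at its maximum on the first night (so the
  series declines over a half-period study, as tropical SST does from
  late boreal winter), plus optional linear trend and Gaussian noise.
  Defaults: mean 25 °C, amplitude 3 °C, noise SD 0.3 °C — a realistic
  equatorial Pacific range that stays well inside the reader's physical
  validation bounds.
* **Birds**: $\boldsymbol\beta_i \sim \mathrm{MVN}$ around the true
  population mean; nightly $y \sim \mathrm{Binomial}(14{,}400, p)$.
  Defaults are the parameter-recovery study conditions: 20 birds,
  180 nights, $\boldsymbol\mu_\beta = (-5.8,\ 0.04,\ -0.74)$ (the scale
  a fitted model of this kind reports), $\Sigma =
  \mathrm{diag}(0.25,\ 4\times10^{-4},\ 0.04)$ — between-bird SDs of
  0.5 on the intercept, 0.02 per degree of SST and 0.2 per unit moon
  fraction.
* **Block allocation**: each nightly count is spread over the 72 blocks
  as $k$ contiguous wet runs separated by at least one dry block, with
  $k - 1$ geometric (default mean 3 extra bouts), the count partitioned
  multinomially across bouts, runs filled with full blocks (200) plus a
  remainder, and dry gaps placed by a uniform composition. Allocation
  conserves the nightly total exactly.
* **Daytime**: blocks are emitted dry except on rest-on-water days
  (default rate 11/4,518 per bird-day, the order observed in tropical
  deployments of this kind), when daytime blocks are wet. Logger gaps
  can be introduced with `missing_block_rate`.

`simulate_study()` writes the two CSV formats plus `truth.json`, so
recovery checks are self-contained; a thin command-line wrapper lives at
`inst/scripts/simulate.R`.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: bout count is drawn independently of the
nightly total, so the strong empirical coupling between time on the water
and number of landings is absent (the bout-regression diagnostic on
synthetic data has a slope near zero by construction); nights are
conditionally independent given $\boldsymbol\beta_i$ (no behavioural
autocorrelation, migration or breeding-stage structure); moonlight enters
only through the calendar fraction (no cloud cover, no moonrise/moonset
geometry); and within-night wet counts have no extra-binomial clustering.
Parameter recovery on this generator validates the estimator under the
model's own assumptions, not the assumptions themselves.

## Verification and problem sizes

The test-suite oracles are independent of the code paths they check:
brute-force run counting for bouts, normal-equation OLS for the
regression, `dbinom` for the likelihood, hand-derived closed forms for
the conjugate updates, and 1-D grid quadrature for the sampler.

The degenerate sampler check uses one bird with a fixed random-effect
covariance and all-zero covariates, making the intercept posterior
exactly one-dimensional: posterior $\propto$
$N(0, \Sigma_{0,11} + \Sigma_{11})$ × binomial likelihood, computed by
quadrature on a 0.002-wide grid. The sampled and quadrature densities are
compared by total-variation distance after smoothing **both** with the
same Gaussian kernel (bandwidth 0.6 × the draw SD). Identical smoothing
keeps the comparison unbiased while suppressing the Monte-Carlo noise of
a raw histogram: with ~9,000 correlated draws (integrated autocorrelation
time ≈ 12 for a well-tuned 3-D random walk), an unsmoothed 10-bin TV
estimate would carry ~0.03 of pure noise, swamping real discrepancies,
whereas the smoothed distance still flags location shifts of a tenth of
a posterior SD or scale errors of ~15%.

Parameter recovery runs 20 independent replicates of the default
20-bird × 180-night study, each fitted with the default 10,000/1,000
sampler settings (about 10 s per fit), checking that posterior means land
within 3 posterior SDs of truth, that 95% credible intervals cover each
component in 85–100% of replicates, and that the negative moon-phase
effect is recovered as significant. Smaller fixtures (5–8 birds, 30–60
nights, 1,500–3,000 iterations) back the unit-level properties:
determinism, positive-definiteness of every covariance draw,
prior-reproduction with no trials, and credible-interval contraction when
nights per bird double.

## Known limitations

* No overdispersion beyond the bird-level random effects.
* One chain by default; between-chain convergence diagnostics are left
  to the user (the seeded determinism makes multi-seed comparisons easy).
* The Wishart prior's identity scale is conservative for coefficients
  whose between-bird spread is orders of magnitude below 1 (see above).
* Moon fraction and SST enter linearly on the logit scale; threshold or
  interactive effects of moonlight are outside the model family.
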