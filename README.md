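# moonbird

Lunar-phase effects on the nocturnal at-sea activity of seabirds carrying
leg-mounted immersion (wet/dry) loggers.

Nocturnal foragers such as the swallow-tailed gull feed on squid and fish
that rise to the sea surface at night with the diel vertical migration — a
migration that bright moonlight suppresses. Immersion loggers score seawater
contact every 3 s and sum the scores into 10-min blocks (0–200), so a
bird's time on the water each night is a binomial count that can be related
to the fraction of the moon illuminated and to sea-surface temperature
(SST). `moonbird` provides the full analysis pipeline for such data:

* **Logger processing** — parse decoded block streams, assign blocks to
  nights (default window 18:00–06:00 local time, 72 blocks, maximum
  aggregate count 72 × 200 = 14,400), aggregate nightly binomial counts,
  and detect *wet bouts* (maximal runs of blocks with ≥ 3 s of water
  contact).
* **Covariates** — read and validate nightly SST / moon-fraction tables and
  join them to the nightly observations.
* **Hierarchical model** — a Bayesian binomial-logit GLMM with a custom
  Metropolis-within-Gibbs sampler.
* **Inference** — posterior summaries with equal-tailed 95% credible
  intervals, posterior predictive bands for the nightly wet probability,
  and actogram matrices.
* **Synthetic data** — a generator that emulates the logger and covariate
  formats with known truth, so the whole pipeline is testable end-to-end
  and parameter recovery can be verified.

## The model

For bird *i* on night *t*, with aggregate wet count *y*<sub>*it*</sub> out
of *n*<sub>*it*</sub> (≤ 14,400) 3-s trials:

```
y_it ~ Binomial(n_it, p_it)
logit(p_it) = x_t' beta_i,        x_t = (1, SST_t, moon_t)
beta_i      ~ MVN(mu_beta, Sigma)
mu_beta     ~ MVN(mu_0, Sigma_0)
Sigma^-1    ~ Wishart(nu_0, S_0)
```

Each bird has its own reaction to the environment (`beta_i`); inference
targets the population-level mean `mu_beta`. The sampler alternates exact
conjugate draws for `mu_beta` and `Sigma^-1` with an adaptive random-walk
Metropolis step for each `beta_i` (proposal preconditioned by the bird's
Gaussian-approximation posterior covariance; scalar step adapted during
burn-in only). Defaults: 10,000 iterations, 1,000 burn-in, weakly
informative proper priors (`mu_0 = 0`, `Sigma_0 = 100 I`, `nu_0 = 4`,
`S_0 = I`). A coefficient is reported *significant* when its 95% credible
interval excludes zero.

## Worked example

```r
library(moonbird)

spec <- simulation_spec(n_birds = 8, n_nights = 120, seed = 42)
simulate_study(spec, "demo")          # writes blocks.csv, covariates.csv, truth.json

records <- read_block_records("demo/blocks.csv")
covs    <- read_covariates("demo/covariates.csv")
nights  <- aggregate_nights(records)
head(nights, 3)
#> # A tibble: 3 × 6
#>   bird_id night_date     y     n n_blocks proportion
#>   <chr>   <date>     <int> <int>    <int>      <dbl>
#> 1 bird_01 2010-03-01   191 14400       72     0.0133
#> 2 bird_01 2010-03-02   178 14400       72     0.0124
#> 3 bird_01 2010-03-03   170 14400       72     0.0118

fit <- nights |>
  join_design(covs) |>
  sample_posterior(config = mcmc_config(seed = 7))
tidy(fit)
#> # A tibble: 3 × 6
#>   parameter       mean    sd ci_low ci_high excludes_zero
#>   <chr>          <dbl> <dbl>  <dbl>   <dbl> <lgl>
#> 1 mu_intercept -5.58   0.265 -6.10   -5.05  TRUE
#> 2 mu_sst        0.0439 0.135 -0.218   0.314 FALSE
#> 3 mu_phase     -0.923  0.143 -1.20   -0.640 TRUE
```

The generator's population truth here was `(-5.8, 0.04, -0.74)`. With only
8 birds the SST effect (a small per-degree slope) is not yet separable from
zero, but the negative moon-phase effect — less time on the water on
bright nights — is recovered as significant: `mu_phase` has posterior mean
−0.92 with 95% CrI (−1.20, −0.64), excluding zero. The intercept is the
log-odds of being wet in any 3-s interval at SST 0 °C and new moon; −5.58
corresponds to a baseline wet probability of about 0.4% per 3-s interval
before the covariates act.

Per-bird predictive bands through the lunar cycle:

```r
bands <- posterior_predictive_p(fit, covs, mode = "bird", bird_id = "bird_01")
head(bands, 3)
#> # A tibble: 3 × 4
#>   night_date mean_p ci_lower_p ci_upper_p
#>   <date>      <dbl>      <dbl>      <dbl>
#> 1 2010-03-01 0.0128     0.0124     0.0132
#> 2 2010-03-02 0.0124     0.0120     0.0127
#> 3 2010-03-03 0.0121     0.0118     0.0125
```

Averaged over nights, this bird's predicted wet probability is 0.0115 on
dark nights (moon fraction < 0.1) versus 0.0042 under a bright moon
(> 0.9) — roughly a three-fold reduction in at-sea activity at full moon.
`autoplot(fit)`, `plot_predictive_bands()` and `plot_actogram()` draw the
corresponding figures, and `write_posterior()` / `write_night_table()`
export the results as CSV.

The default `posterior_predictive_p()` mode (`"population"`) draws a fresh
coefficient vector per posterior draw and therefore reflects between-bird
spread as well; with few birds the Wishart prior keeps that spread wide, so
population-mode bands are much broader than bird-mode bands.

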