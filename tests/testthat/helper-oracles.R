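# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# maximal-run counter by explicit scan (oracle for detect_wet_bouts)
brute_bout_count <- function(x) {
  n_bouts <- 0L
  in_bout <- FALSE
  for (v in x) {
    if (v >= 1) {
      if (!in_bout) n_bouts <- n_bouts + 1L
      in_bout <- TRUE
    } else {
      in_bout <- FALSE
    }
  }
  n_bouts
}

# closed-form OLS via the normal equations (oracle for the bout regression)
ols_oracle <- function(x, y) {
  xm <- cbind(1, x)
  coefs <- solve(t(xm) %*% xm, t(xm) %*% y)
  resid <- y - xm %*% coefs
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(intercept = coefs[1], slope = coefs[2], r_squared = r2)
}

# 1-D grid quadrature of the binomial-logit posterior for the degenerate
# single-bird case: intercept-only likelihood, Gaussian marginal prior with
# variance prior_var (population prior variance + fixed random-effect
# variance, both diagonal).
grid_posterior <- function(y, n, prior_var, grid = seq(-3, 1.5, by = 0.002)) {
  lp <- dnorm(grid, 0, sqrt(prior_var), log = TRUE) +
    vapply(grid,
           function(b) sum(dbinom(y, n, plogis(b), log = TRUE)),
           numeric(1))
  f <- exp(lp - max(lp))
  dx <- grid[2] - grid[1]
  list(grid = grid, density = f / (sum(f) * dx), dx = dx)
}

# total variation between draws and a grid density after smoothing BOTH with
# the same Gaussian kernel (bandwidth bw_factor x draw SD); identical
# smoothing keeps the comparison unbiased while suppressing Monte-Carlo
# noise in the kernel density estimate.
smoothed_tv <- function(draws, oracle, bw_factor = 0.6) {
  h <- bw_factor * sd(draws)
  dx <- oracle$dx
  kde <- density(draws, bw = h, from = min(oracle$grid),
                 to = max(oracle$grid), n = length(oracle$grid))
  kk <- seq(-4 * h, 4 * h, by = dx)
  pad <- length(kk) %/% 2
  smoothed <- as.numeric(stats::filter(
    c(rep(0, pad), oracle$density, rep(0, pad)),
    dnorm(kk, 0, h) * dx, sides = 2
  ))[(pad + 1):(pad + length(oracle$grid))]
  0.5 * sum(abs(kde$y - smoothed)) * dx
}

# block-record builder: one bird, one night window's worth of blocks
night_blocks <- function(counts, bird = "b1", date = "2010-03-05",
                         tz = "Etc/GMT+6") {
  start <- lubridate::ymd_hms(paste(date, "18:00:00"), tz = tz)
  tibble::tibble(
    bird_id = bird,
    block_start = start + (seq_along(counts) - 1) * 600,
    wet_count = as.integer(counts)
  )
}

# degenerate single-bird fixture shared by the MCMC oracle checks: fixed
# random-effect covariance, flat (all-zero) covariates, so the intercept
# posterior is exactly 1-D.
degenerate_fixture <- function() {
  list(
    data = tibble::tibble(
      bird_id = "b1",
      y = c(12, 17, 14, 15, 18, 11),
      n = 50,
      sst = 0,
      moon_fraction = 0
    ),
    prior = prior_spec(mu0 = c(0, 0, 0),
                       sigma0 = diag(c(2.25, 0.09, 0.09))),
    fixed_sigma = diag(0.25, 3),
    prior_var = 2.25 + 0.25
  )
}

# fabricated fit object with known draws (for predictive-band unit checks)
fake_fit <- function(mu_draws, sigma_value = 1e-12, n_birds = 1) {
  n_draws <- nrow(mu_draws)
  colnames(mu_draws) <- c("mu_intercept", "mu_sst", "mu_phase")
  sigma <- array(0, c(3, 3, n_draws))
  for (s in seq_len(n_draws)) sigma[, , s] <- diag(sigma_value, 3)
  beta <- array(rep(mu_draws, each = 1), c(n_draws, n_birds, 3))
  for (i in seq_len(n_birds)) beta[, i, ] <- mu_draws
  structure(list(
    mu = mu_draws, sigma = sigma, beta = beta,
    acceptance = setNames(rep(0.3, n_birds), paste0("b", seq_len(n_birds))),
    bird_ids = paste0("b", seq_len(n_birds)),
    n_birds = n_birds, n_nights = 0,
    prior = prior_spec(), config = mcmc_config(n_iter = n_draws + 1,
                                               n_burn = 1),
    fixed_sigma = NULL
  ), class = "moonbird_fit")
}
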