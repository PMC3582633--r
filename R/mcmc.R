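#' Prior specification for the hierarchical activity model
#'
#' The population mean coefficient vector gets a multivariate-normal prior
#' `MVN(mu0, sigma0)`; the precision matrix (inverse of the random-effect
#' covariance) gets a Wishart prior with `wishart_df` degrees of freedom and
#' scale `wishart_scale`. Defaults are weakly informative and proper:
#' zero mean with variance 100 per coefficient, and the minimal proper
#' Wishart (`df = 4` for 3 coefficients) with identity scale.
#'
#' @param mu0 Length-3 prior mean for the population coefficients.
#' @param sigma0 3x3 positive-definite prior covariance for the population
#'   mean.
#' @param wishart_df Wishart degrees of freedom; must be at least the
#'   coefficient dimension.
#' @param wishart_scale 3x3 positive-definite Wishart scale matrix.
#' @return An object of class `moonbird_prior`.
#' @export
prior_spec <- function(mu0 = c(0, 0, 0), sigma0 = diag(100, 3),
                       wishart_df = 4, wishart_scale = diag(3)) {
  mu0 <- as.numeric(mu0)
  if (length(mu0) != 3) abort("mu0 must have length 3")
  check_pd(sigma0, "sigma0")
  check_pd(wishart_scale, "wishart_scale")
  if (wishart_df < 3) abort("wishart_df must be >= 3 (the dimension)")
  structure(list(mu0 = mu0, sigma0 = sigma0, wishart_df = wishart_df,
                 wishart_scale = wishart_scale),
            class = "moonbird_prior")
}

check_pd <- function(m, name) {
  m <- as.matrix(m)
  if (nrow(m) != 3 || ncol(m) != 3 || any(abs(m - t(m)) > 1e-8)) {
    abort(paste0(name, " must be a symmetric 3x3 matrix"))
  }
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  if (!ok) abort(paste0(name, " must be positive definite"))
  invisible(m)
}

#' MCMC configuration
#'
#' @param n_iter Total iterations (default 10,000).
#' @param n_burn Burn-in iterations discarded from the front (default 1,000).
#' @param seed Integer seed; identical seed, config and data give identical
#'   draws.
#' @param proposal_scale Initial scalar multiplier for the random-walk
#'   proposal.
#' @param adapt Adapt the proposal scale during burn-in (frozen afterwards,
#'   preserving detailed balance), targeting `target_accept`.
#' @param target_accept Target Metropolis acceptance rate (default 0.3,
#'   inside the usual 20-40% band for random-walk proposals).
#' @return An object of class `moonbird_config`.
#' @export
mcmc_config <- function(n_iter = 10000, n_burn = 1000, seed = 1L,
                        proposal_scale = 1, adapt = TRUE,
                        target_accept = 0.3) {
  if (n_burn < 0 || n_burn >= n_iter) abort("need 0 <= n_burn < n_iter")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 adapt = isTRUE(adapt), target_accept = target_accept),
            class = "moonbird_config")
}

safe_solve <- function(m, what) {
  tryCatch(solve(m), error = function(e) {
    abort(paste0("singular ", what,
                 "; check for degenerate data or priors (",
                 conditionMessage(e), ")"))
  })
}

#' Full-conditional update of the population mean
#'
#' Normal-normal conjugate step: given the bird coefficients, the
#' random-effect covariance and the prior, the population mean is
#' multivariate normal with precision `sigma0^-1 + m * sigma^-1` and mean
#' pulled between the prior mean and the bird average.
#'
#' @param beta m x 3 matrix of current bird coefficient vectors.
#' @param sigma Current 3x3 random-effect covariance.
#' @param prior A [prior_spec()].
#' @param params_only If `TRUE`, return the conditional `mean` and `cov`
#'   instead of a draw.
#' @return A length-3 draw, or a list with `mean` and `cov`.
#' @export
conjugate_mu_update <- function(beta, sigma, prior, params_only = FALSE) {
  beta <- rbind(beta)
  m <- nrow(beta)
  sigma_inv <- safe_solve(sigma, "random-effect covariance")
  prior_inv <- safe_solve(prior$sigma0, "prior covariance")
  v <- safe_solve(prior_inv + m * sigma_inv, "conditional precision")
  v <- (v + t(v)) / 2
  mean <- drop(v %*% (prior_inv %*% prior$mu0 + sigma_inv %*% colSums(beta)))
  if (params_only) return(list(mean = mean, cov = v))
  rmvn(1, mean, v)
}

#' Full-conditional update of the precision matrix
#'
#' Normal-Wishart conjugate step: given the bird coefficients and the
#' population mean, the precision matrix is Wishart with degrees of freedom
#' `wishart_df + m` and scale `(wishart_scale^-1 + S)^-1`, where `S` is the
#' centred scatter matrix of the coefficients.
#'
#' @param beta m x 3 matrix of bird coefficient vectors.
#' @param mu_beta Length-3 current population mean.
#' @param prior A [prior_spec()].
#' @param params_only If `TRUE`, return the conditional `df` and `scale`.
#' @return A 3x3 precision-matrix draw, or a list with `df` and `scale`.
#' @export
conjugate_precision_update <- function(beta, mu_beta, prior,
                                       params_only = FALSE) {
  beta <- rbind(beta)
  m <- nrow(beta)
  centred <- sweep(beta, 2, mu_beta)
  scatter <- crossprod(centred)
  scale <- safe_solve(safe_solve(prior$wishart_scale, "wishart scale") +
                        scatter, "wishart conditional scale")
  scale <- (scale + t(scale)) / 2
  df <- prior$wishart_df + m
  if (params_only) return(list(df = df, scale = scale))
  rWishart(1, df, scale)[, , 1]
}

# Gaussian-approximation covariance of one bird's coefficient posterior at
# the initial state; used as a fixed proposal preconditioner so the three
# coefficients (which sit on very different scales when SST is uncentered)
# are proposed along the right ellipse.
proposal_chol <- function(x, n, p0, sigma_inv) {
  w <- n * p0 * (1 - p0)
  prec <- crossprod(x, x * w) + sigma_inv
  cov <- tryCatch(solve(prec), error = function(e) diag(3))
  cov <- (cov + t(cov)) / 2
  tryCatch(t(chol(cov)), error = function(e) diag(3) * 0.1)
}

#' Sample the posterior of the hierarchical activity model
#'
#' Fits the Bayesian hierarchical binomial-logit model: nightly wet counts
#' `y` are binomial with trial count `n` and wet probability
#' `inv_logit(x' beta_i)` where `x = (1, sst, moon_fraction)`; each bird's
#' coefficient vector `beta_i` is multivariate normal around a population
#' mean with covariance `sigma`; the population mean has a normal prior and
#' the precision matrix a Wishart prior. Sampling is Metropolis-within-Gibbs:
#' exact conjugate draws for the population mean and precision matrix, and an
#' adaptive random-walk Metropolis step for each bird's coefficient vector
#' (scale adapted during burn-in only).
#'
#' @param data Model-ready tibble from [join_design()]: columns `bird_id`,
#'   `y`, `n`, `sst`, `moon_fraction`.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param fixed_sigma Optional 3x3 positive-definite matrix; if supplied the
#'   random-effect covariance is held fixed instead of sampled (used for
#'   degenerate single-bird checks). At least 2 birds are required unless
#'   `fixed_sigma` is given.
#' @return An object of class `moonbird_fit` with post-burn-in draws:
#'   `mu` (draws x 3, columns `mu_intercept`, `mu_sst`, `mu_phase`),
#'   `sigma` (3 x 3 x draws), `beta` (draws x birds x 3), per-bird
#'   Metropolis `acceptance` rates, the `prior`, `config` and bird ids.
#' @seealso [tidy.moonbird_fit()], [posterior_predictive_p()],
#'   [write_posterior()]
#' @export
sample_posterior <- function(data, prior = prior_spec(),
                             config = mcmc_config(), fixed_sigma = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c("bird_id", "y", "n", "sst", "moon_fraction")
  if (!all(needed %in% names(data))) {
    abort(paste0("data must have columns: ", paste(needed, collapse = ", ")))
  }
  if (!inherits(prior, "moonbird_prior")) abort("prior must be a prior_spec()")
  if (!inherits(config, "moonbird_config")) {
    abort("config must be an mcmc_config()")
  }
  if (!is.null(fixed_sigma)) check_pd(fixed_sigma, "fixed_sigma")

  data <- dplyr::arrange(data, .data$bird_id)
  bird_ids <- unique(data$bird_id)
  m <- length(bird_ids)
  if (m < 2 && is.null(fixed_sigma)) {
    abort("need at least 2 birds (or supply fixed_sigma)")
  }
  if (any(tapply(data$y, data$bird_id, length) < 1)) {
    abort("every bird needs at least one night")
  }
  x <- design_matrix(data)
  for (j in 2:3) {
    if (var(x[, j]) == 0) {
      warn(paste0("covariate '", colnames(x)[j],
                  "' is constant: its coefficient is weakly identified"))
    }
  }
  y <- data$y
  n <- data$n
  if (any(y < 0 | y > n)) abort("need 0 <= y <= n for every night")
  ib <- match(data$bird_id, bird_ids)

  set.seed(config$seed)
  n_keep <- config$n_iter - config$n_burn

  # init: per-bird empirical logit (clipped), flat covariate effects
  pool_y <- as.vector(rowsum(y, ib))
  pool_n <- as.vector(rowsum(n, ib))
  p_hat <- ifelse(pool_n > 0, pool_y / pool_n, 0.5)
  p_hat <- pmin(pmax(p_hat, 1e-6), 1 - 1e-6)
  beta <- cbind(qlogis(p_hat), 0, 0)
  mu <- colMeans(beta)
  sigma <- if (is.null(fixed_sigma)) diag(3) else as.matrix(fixed_sigma)
  sigma_inv <- solve(sigma)

  prop_l <- lapply(seq_len(m), function(i) {
    rows <- which(ib == i)
    proposal_chol(x[rows, , drop = FALSE], n[rows],
                  rep(p_hat[i], length(rows)), sigma_inv)
  })
  log_s <- rep(log(config$proposal_scale), m)

  quad <- function(b) {
    d <- sweep(b, 2, mu)
    rowSums((d %*% sigma_inv) * d)
  }
  bird_lik <- function(b) {
    psi <- rowSums(x * b[ib, , drop = FALSE])
    as.vector(rowsum(y * psi - n * log1pexp(psi), ib))
  }
  lik_cur <- bird_lik(beta)

  mu_draws <- matrix(NA_real_, n_keep, 3,
                     dimnames = list(NULL,
                                     c("mu_intercept", "mu_sst", "mu_phase")))
  sigma_draws <- array(NA_real_, c(3, 3, n_keep))
  beta_draws <- array(NA_real_, c(n_keep, m, 3),
                      dimnames = list(NULL, bird_ids,
                                      c("intercept", "sst", "moon_fraction")))
  acc_post <- rep(0L, m)

  for (t in seq_len(config$n_iter)) {
    mu <- conjugate_mu_update(beta, sigma, prior)
    if (is.null(fixed_sigma)) {
      sigma_inv <- conjugate_precision_update(beta, mu, prior)
      sigma <- chol2inv(chol(sigma_inv))
    }

    s <- exp(log_s)
    z <- matrix(rnorm(3 * m), nrow = 3)
    eps <- t(vapply(seq_len(m),
                    function(i) s[i] * drop(prop_l[[i]] %*% z[, i]),
                    numeric(3)))
    prop <- beta + eps
    lik_prop <- bird_lik(prop)
    logr <- (lik_prop - 0.5 * quad(prop)) - (lik_cur - 0.5 * quad(beta))
    acc <- log(runif(m)) < logr
    if (any(acc)) {
      beta[acc, ] <- prop[acc, , drop = FALSE]
      lik_cur[acc] <- lik_prop[acc]
    }
    if (config$adapt && t <= config$n_burn) {
      gain <- min(0.2, 3 / sqrt(t))
      log_s <- log_s + gain * (as.numeric(acc) - config$target_accept)
    }
    if (t > config$n_burn) {
      k <- t - config$n_burn
      mu_draws[k, ] <- mu
      sigma_draws[, , k] <- sigma
      beta_draws[k, , ] <- beta
      acc_post <- acc_post + as.integer(acc)
    }
  }

  structure(list(
    mu = mu_draws,
    sigma = sigma_draws,
    beta = beta_draws,
    acceptance = setNames(acc_post / n_keep, bird_ids),
    bird_ids = bird_ids,
    n_birds = m,
    n_nights = nrow(data),
    prior = prior,
    config = config,
    fixed_sigma = fixed_sigma
  ), class = "moonbird_fit")
}

#' @export
print.moonbird_fit <- function(x, ...) {
  cat("Hierarchical binomial-logit activity model\n")
  cat(sprintf("  %d birds, %d bird-nights, %d retained draws (of %d, burn-in %d)\n",
              x$n_birds, x$n_nights, nrow(x$mu), x$config$n_iter,
              x$config$n_burn))
  cat(sprintf("  Metropolis acceptance: %.2f-%.2f (median %.2f)\n",
              min(x$acceptance), max(x$acceptance),
              stats::median(x$acceptance)))
  print(summarize_population(x), ...)
  invisible(x)
}
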