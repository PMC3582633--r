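#' Posterior summary of the population-level coefficients
#'
#' Empirical mean, SD and equal-tailed 95% credible interval (2.5 and 97.5
#' percentiles) for each population-level coefficient. A coefficient is
#' flagged significant when its credible interval excludes zero.
#'
#' @param x A `moonbird_fit`, or a draws matrix with one column per
#'   parameter.
#' @param level Credible level (default 0.95, equal-tailed).
#' @return A tibble with `parameter`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `excludes_zero`.
#' @export
summarize_population <- function(x, level = 0.95) {
  draws <- if (inherits(x, "moonbird_fit")) x$mu else as.matrix(x)
  if (nrow(draws) < 100) {
    abort("need at least 100 post-burn-in draws to summarise")
  }
  a <- (1 - level) / 2
  purrr::map_dfr(seq_len(ncol(draws)), function(j) {
    d <- draws[, j]
    q <- unname(quantile(d, c(a, 1 - a), type = 7))
    tibble::tibble(
      parameter = colnames(draws)[j] %||% paste0("param_", j),
      mean = mean(d),
      sd = sd(d),
      ci_low = q[1],
      ci_high = q[2],
      excludes_zero = q[1] > 0 | q[2] < 0
    )
  })
}

#' Tidy a fitted activity model
#'
#' Broom-style one-row-per-parameter summary of the population-level
#' posterior; see [summarize_population()].
#'
#' @param x A `moonbird_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble with `parameter`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `excludes_zero`.
#' @method tidy moonbird_fit
#' @export
tidy.moonbird_fit <- function(x, level = 0.95, ...) {
  summarize_population(x, level = level)
}

#' One-row summary of a fitted activity model
#'
#' @param x A `moonbird_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_birds`, `n_nights`, `n_draws`, `n_iter`,
#'   `n_burn`, `seed`, `mean_acceptance`.
#' @method glance moonbird_fit
#' @export
glance.moonbird_fit <- function(x, ...) {
  tibble::tibble(
    n_birds = x$n_birds,
    n_nights = x$n_nights,
    n_draws = nrow(x$mu),
    n_iter = x$config$n_iter,
    n_burn = x$config$n_burn,
    seed = x$config$seed,
    mean_acceptance = mean(x$acceptance)
  )
}

#' Study bookkeeping percentages
#'
#' Turns count/total pairs (devices recovered, loggers covering a breeding
#' attempt, ...) into the rounded percentages a field report quotes.
#'
#' @param counts Data frame with columns `label`, `count`, `total`.
#' @param digits Decimal places for the percentage (default 0, reporting
#'   style).
#' @return The input with a `percent` column appended.
#' @examples
#' study_tally(tibble::tibble(
#'   label = c("devices recovered", "loggers with breeding data"),
#'   count = c(46, 37), total = c(50, 45)
#' ))
#' @export
study_tally <- function(counts, digits = 0) {
  stopifnot(all(c("label", "count", "total") %in% names(counts)))
  if (any(counts$total <= 0)) abort("totals must be positive")
  if (any(counts$count < 0 | counts$count > counts$total)) {
    abort("counts must lie in [0, total]")
  }
  dplyr::mutate(tibble::as_tibble(counts),
                percent = round(100 * .data$count / .data$total, digits))
}

#' Serialise posterior draws
#'
#' Writes one row per retained draw with the population mean
#' (`mu_intercept`, `mu_sst`, `mu_phase`) and the upper triangle of the
#' random-effect covariance (`sigma_11` ... `sigma_33`), plus a JSON
#' metadata sidecar (`<path>.json`) with the configuration, prior, bird ids
#' and acceptance rates. Runs with the same seed, config and data produce
#' byte-identical CSVs.
#'
#' @param fit A `moonbird_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "moonbird_fit"))
  s <- fit$sigma
  out <- tibble::as_tibble(fit$mu) |>
    dplyr::mutate(
      sigma_11 = s[1, 1, ], sigma_12 = s[1, 2, ], sigma_13 = s[1, 3, ],
      sigma_22 = s[2, 2, ], sigma_23 = s[2, 3, ], sigma_33 = s[3, 3, ]
    )
  readr::write_csv(out, path)
  meta <- list(
    package = "moonbird",
    version = as.character(utils::packageVersion("moonbird")),
    n_birds = fit$n_birds,
    n_nights = fit$n_nights,
    bird_ids = fit$bird_ids,
    acceptance = as.list(fit$acceptance),
    config = unclass(fit$config),
    prior = list(
      mu0 = fit$prior$mu0,
      sigma0 = fit$prior$sigma0,
      wishart_df = fit$prior$wishart_df,
      wishart_scale = fit$prior$wishart_scale
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read priors and MCMC settings from a YAML config file
#'
#' Accepts a file with optional `prior` and `mcmc` blocks, e.g.
#' ```yaml
#' prior:
#'   mu0: [0, 0, 0]
#'   sigma0_diag: [100, 100, 100]
#'   wishart_df: 4
#'   wishart_scale_diag: [1, 1, 1]
#' mcmc:
#'   n_iter: 10000
#'   n_burn: 1000
#'   seed: 42
#' ```
#' Unspecified entries fall back to [prior_spec()] / [mcmc_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `prior` and `config`.
#' @export
read_fit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- raw$prior %||% list()
  m <- raw$mcmc %||% list()
  defaults <- prior_spec()
  prior <- prior_spec(
    mu0 = p$mu0 %||% defaults$mu0,
    sigma0 = if (!is.null(p$sigma0_diag)) diag(as.numeric(p$sigma0_diag))
             else defaults$sigma0,
    wishart_df = p$wishart_df %||% defaults$wishart_df,
    wishart_scale = if (!is.null(p$wishart_scale_diag))
                      diag(as.numeric(p$wishart_scale_diag))
                    else defaults$wishart_scale
  )
  dm <- mcmc_config()
  config <- mcmc_config(
    n_iter = m$n_iter %||% dm$n_iter,
    n_burn = m$n_burn %||% dm$n_burn,
    seed = m$seed %||% dm$seed,
    proposal_scale = m$proposal_scale %||% dm$proposal_scale,
    adapt = m$adapt %||% dm$adapt,
    target_accept = m$target_accept %||% dm$target_accept
  )
  list(prior = prior, config = config)
}
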