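#' Posterior predictive distribution of the nightly wet probability
#'
#' Propagates posterior draws through the logit link for each requested
#' night. In `"population"` mode each draw first samples a fresh coefficient
#' vector from the population distribution `MVN(mu, sigma)` of that draw —
#' the predictive for an unobserved bird; in `"bird"` mode the retained
#' coefficient draws of one tagged bird are used directly. The band is the
#' equal-tailed 95% interval across draws.
#'
#' @param fit A `moonbird_fit`.
#' @param covs Covariate tibble with `night_date`, `sst`, `moon_fraction`
#'   for the nights to predict.
#' @param mode `"population"` (default) or `"bird"`.
#' @param bird_id Which bird, when `mode = "bird"`.
#' @param level Credible level of the band.
#' @param seed Seed for the new-bird draws in population mode (kept separate
#'   from the fit's chain so prediction never perturbs the fit).
#' @return A tibble with `night_date`, `mean_p`, `ci_lower_p`, `ci_upper_p`.
#' @export
posterior_predictive_p <- function(fit, covs, mode = c("population", "bird"),
                                   bird_id = NULL, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "moonbird_fit"))
  mode <- match.arg(mode)
  needed <- c("night_date", "sst", "moon_fraction")
  if (!all(needed %in% names(covs))) {
    abort(paste0("covs must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyNA(covs$sst) || anyNA(covs$moon_fraction)) {
    abort("covariates contain missing values for requested nights")
  }
  x <- design_matrix(covs)
  n_draws <- nrow(fit$mu)

  if (mode == "population") {
    set.seed(seed)
    z <- matrix(rnorm(3 * n_draws), nrow = n_draws)
    b <- t(vapply(seq_len(n_draws), function(s) {
      l <- t(chol(fit$sigma[, , s]))
      fit$mu[s, ] + drop(l %*% z[s, ])
    }, numeric(3)))
  } else {
    if (is.null(bird_id) || !(bird_id %in% fit$bird_ids)) {
      abort("bird mode needs a bird_id present in the fit")
    }
    b <- fit$beta[, match(bird_id, fit$bird_ids), ]
  }

  p <- inv_logit(b %*% t(x)) # draws x nights
  a <- (1 - level) / 2
  qs <- apply(p, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    night_date = covs$night_date,
    mean_p = colMeans(p),
    ci_lower_p = qs[1, ],
    ci_upper_p = qs[2, ]
  )
}

#' Actogram matrix of mean wet proportion
#'
#' Averages `wet_count / 200` across birds for every (night, block-of-night)
#' cell of the night window, the raw material of an actogram heat map.
#'
#' @param records Block records (see [read_block_records()]).
#' @param night_window Passed to [assign_night()].
#' @return A tibble in long form with `night_date`, `block_index` (1 = first
#'   block after the window opens) and `mean_wet` in \[0, 1\].
#' @seealso [plot_actogram()]
#' @export
actogram_matrix <- function(records, night_window = c("18:00", "06:00")) {
  validate_block_records(records)
  if (nrow(records) == 0) abort("need at least one block record")
  w0 <- parse_clock(night_window[1])
  records$night_date <- assign_night(records$block_start, night_window)
  records <- dplyr::filter(records, !is.na(.data$night_date))
  secs <- lubridate::hour(records$block_start) * 3600 +
    lubridate::minute(records$block_start) * 60
  records$block_index <- ((secs - w0) %% 86400) %/% 600 + 1
  records |>
    dplyr::group_by(.data$night_date, .data$block_index) |>
    dplyr::summarise(mean_wet = mean(.data$wet_count) / max_wet_per_block,
                     .groups = "drop")
}

#' Export an actogram matrix as CSV
#'
#' Wide layout: one row per night, one column per block of the night window.
#'
#' @param acto Output of [actogram_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_actogram <- function(acto, path) {
  wide <- tidyr::pivot_wider(acto, names_from = "block_index",
                             names_prefix = "block_",
                             values_from = "mean_wet")
  readr::write_csv(wide, path)
  invisible(path)
}
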