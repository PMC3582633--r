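#' Simulation settings for a synthetic tracking study
#'
#' Defines the generative twin of the hierarchical model: bird coefficient
#' vectors drawn from `MVN(true_mu_beta, true_sigma)`, nightly wet counts
#' binomial given the lunar/SST design, counts spread over 10-min blocks in
#' contiguous wet runs so bout structure exists. Defaults mirror the
#' parameter-recovery study: 20 birds over 180 nights with population
#' coefficients on the fitted-model scale (intercept -5.8, +0.04 per degree
#' C of SST, -0.74 per unit moon fraction).
#'
#' @param n_birds Number of tagged birds.
#' @param n_nights Number of consecutive nights.
#' @param true_mu_beta Length-3 population mean (intercept, SST, moon).
#' @param true_sigma 3x3 PD covariance of the bird coefficient vectors.
#' @param lunar_period_days Synodic period of the moon-fraction series.
#' @param new_moon_offset Days from `start_date` to the first new moon.
#' @param sst_mean,sst_amplitude,sst_period_days,sst_trend_per_day,sst_noise_sd
#'   Mean level, seasonal cosine amplitude (declining from a start-of-study
#'   maximum), seasonal period, linear trend and Gaussian noise SD of the
#'   SST series, all in degrees C.
#' @param start_date First night's date.
#' @param seed Integer master seed for all generator randomness.
#' @param missing_block_rate Fraction of logger blocks dropped at random
#'   (default 0: complete records).
#' @param bout_geom_prob Success probability of the geometric draw for the
#'   number of extra wet bouts per wet night (mean bouts = 1 + (1-p)/p).
#' @param day_rest_rate Probability per bird-day of resting on the water
#'   through daylight hours (daytime blocks otherwise emit dry).
#' @return An object of class `moonbird_sim_spec`.
#' @export
simulation_spec <- function(n_birds = 20, n_nights = 180,
                            true_mu_beta = c(-5.8, 0.04, -0.74),
                            true_sigma = diag(c(0.25, 0.0004, 0.04)),
                            lunar_period_days = 29.53,
                            new_moon_offset = 0,
                            sst_mean = 25, sst_amplitude = 3,
                            sst_period_days = 365.25,
                            sst_trend_per_day = 0,
                            sst_noise_sd = 0.3,
                            start_date = "2010-03-01",
                            seed = 1L,
                            missing_block_rate = 0,
                            bout_geom_prob = 0.25,
                            day_rest_rate = 11 / 4518) {
  if (n_birds < 1) abort("n_birds must be >= 1")
  if (n_nights < 1) abort("n_nights must be >= 1")
  if (lunar_period_days <= 0) abort("lunar_period_days must be positive")
  if (missing_block_rate < 0 || missing_block_rate > 1 ||
      day_rest_rate < 0 || day_rest_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  true_mu_beta <- as.numeric(true_mu_beta)
  if (length(true_mu_beta) != 3) abort("true_mu_beta must have length 3")
  check_pd(true_sigma, "true_sigma")
  structure(list(
    n_birds = as.integer(n_birds), n_nights = as.integer(n_nights),
    true_mu_beta = true_mu_beta, true_sigma = as.matrix(true_sigma),
    lunar_period_days = lunar_period_days,
    new_moon_offset = new_moon_offset,
    sst_mean = sst_mean, sst_amplitude = sst_amplitude,
    sst_period_days = sst_period_days,
    sst_trend_per_day = sst_trend_per_day,
    sst_noise_sd = sst_noise_sd,
    start_date = lubridate::as_date(start_date),
    seed = as.integer(seed),
    missing_block_rate = missing_block_rate,
    bout_geom_prob = bout_geom_prob,
    day_rest_rate = day_rest_rate
  ), class = "moonbird_sim_spec")
}

#' Deterministic lunar-fraction series
#'
#' Raised cosine `(1 - cos(2 pi t / period)) / 2` starting at a new moon:
#' 0 at `t = new_moon_offset`, 1 half a period later.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with `night_date` and `moon_fraction`.
#' @export
simulate_lunar_series <- function(spec) {
  stopifnot(inherits(spec, "moonbird_sim_spec"))
  t <- seq_len(spec$n_nights) - 1 - spec$new_moon_offset
  tibble::tibble(
    night_date = spec$start_date + (seq_len(spec$n_nights) - 1),
    moon_fraction = (1 - cos(2 * pi * t / spec$lunar_period_days)) / 2
  )
}

#' Seeded SST series
#'
#' Seasonal cosine (at its maximum on the first night, so temperature
#' declines over a half-period study) plus linear trend plus Gaussian noise.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with `night_date` and `sst` (degrees C).
#' @export
simulate_sst_series <- function(spec) {
  stopifnot(inherits(spec, "moonbird_sim_spec"))
  set.seed(spec$seed + 1L)
  t <- seq_len(spec$n_nights) - 1
  tibble::tibble(
    night_date = spec$start_date + t,
    sst = spec$sst_mean +
      spec$sst_amplitude * cos(2 * pi * t / spec$sst_period_days) +
      spec$sst_trend_per_day * t +
      rnorm(spec$n_nights, 0, spec$sst_noise_sd)
  )
}

#' Simulated nightly covariate table
#'
#' Joins [simulate_lunar_series()] and [simulate_sst_series()].
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with `night_date`, `sst`, `moon_fraction`.
#' @export
simulate_covariates <- function(spec) {
  dplyr::inner_join(simulate_sst_series(spec), simulate_lunar_series(spec),
                    by = "night_date")
}

#' Simulated nightly observations (no block stream)
#'
#' Fast path of the generator: draws the bird coefficient vectors and the
#' nightly binomial counts without expanding them into 10-min blocks. Used
#' for parameter-recovery studies where only the nightly table matters.
#'
#' @param spec A [simulation_spec()].
#' @param covariates Optional covariate table; defaults to
#'   [simulate_covariates()].
#' @return A list: `nights` (model-ready tibble with `bird_id`,
#'   `night_date`, `y`, `n`, `n_blocks`, `proportion`, `sst`,
#'   `moon_fraction`) and `truth` (`mu_beta`, `sigma`, `beta`, per-night
#'   wet probabilities `p`).
#' @export
simulate_nightly <- function(spec, covariates = NULL) {
  stopifnot(inherits(spec, "moonbird_sim_spec"))
  if (is.null(covariates)) covariates <- simulate_covariates(spec)
  if (nrow(covariates) < spec$n_nights) {
    abort("covariates do not cover all simulated nights")
  }
  consts <- night_constants()
  n_max <- consts$max_nightly_count
  set.seed(spec$seed + 2L)
  beta <- rmvn(spec$n_birds, spec$true_mu_beta, spec$true_sigma)
  beta <- rbind(beta)
  bird_ids <- sprintf("bird_%02d", seq_len(spec$n_birds))
  rownames(beta) <- bird_ids

  x <- cbind(1, covariates$sst, covariates$moon_fraction)
  nights <- purrr::map_dfr(seq_len(spec$n_birds), function(i) {
    psi <- drop(x %*% beta[i, ])
    p <- plogis(psi)
    tibble::tibble(
      bird_id = bird_ids[i],
      night_date = covariates$night_date,
      p = p,
      y = rbinom(length(p), n_max, p)
    )
  })
  truth <- list(mu_beta = spec$true_mu_beta, sigma = spec$true_sigma,
                beta = beta,
                nightly = nights[c("bird_id", "night_date", "p", "y")])
  nights <- nights |>
    dplyr::mutate(n = n_max, n_blocks = consts$blocks_per_night,
                  proportion = .data$y / .data$n) |>
    dplyr::select("bird_id", "night_date", "y", "n", "n_blocks",
                  "proportion") |>
    dplyr::left_join(covariates, by = "night_date")
  list(nights = nights, truth = truth)
}

# Spread a nightly count over n_blocks blocks (each 0..200) as k contiguous
# wet runs separated by at least one dry block. k is 1 + a geometric draw,
# reduced until the runs (plus separators) fit; within a run all blocks are
# full (200) except a final remainder. Conservation is exact.
allocate_bout_blocks <- function(y, n_blocks = 72, geom_prob = 0.25) {
  blocks <- integer(n_blocks)
  if (y == 0) return(blocks)
  if (y > n_blocks * max_wet_per_block) abort("y exceeds block capacity")
  k <- 1L + rgeom(1, geom_prob)
  k <- min(k, y) # each bout holds at least one wet sub-period
  repeat {
    parts <- if (k == 1) y else
      as.vector(rmultinom(1, y - k, rep(1 / k, k))) + 1
    lens <- ceiling(parts / max_wet_per_block)
    if (sum(lens) + k - 1 <= n_blocks) break
    k <- k - 1L
  }
  dry_free <- n_blocks - sum(lens) - (k - 1L)
  gap_extra <- if (dry_free > 0)
    as.vector(rmultinom(1, dry_free, rep(1 / (k + 1), k + 1))) else
    integer(k + 1)
  gaps <- gap_extra + c(0L, rep(1L, k - 1), 0L)
  pos <- 1L
  for (j in seq_len(k)) {
    pos <- pos + gaps[j]
    run <- rep(max_wet_per_block, lens[j])
    run[lens[j]] <- parts[j] - max_wet_per_block * (lens[j] - 1)
    blocks[pos:(pos + lens[j] - 1)] <- run
    pos <- pos + lens[j]
  }
  blocks
}

#' Simulate immersion-logger block streams
#'
#' Full generator: nightly binomial counts from the hierarchical model are
#' spread over the 72 night blocks as contiguous wet runs (see the vignette
#' for the allocation rule), daytime blocks are emitted dry except on
#' occasional rest-on-water days, and blocks may be dropped at
#' `missing_block_rate` to emulate logger gaps.
#'
#' @param spec A [simulation_spec()].
#' @param covariates Optional covariate table; defaults to
#'   [simulate_covariates()].
#' @param emit_daytime Emit the 06:00-17:50 blocks as well (default `TRUE`).
#' @param tz Time zone of the emitted timestamps.
#' @return A list: `records` (block tibble accepted by
#'   [aggregate_nights()]), `covariates`, and `truth` as in
#'   [simulate_nightly()].
#' @export
simulate_birds <- function(spec, covariates = NULL, emit_daytime = TRUE,
                           tz = "Etc/GMT+6") {
  stopifnot(inherits(spec, "moonbird_sim_spec"))
  if (is.null(covariates)) covariates <- simulate_covariates(spec)
  sim <- simulate_nightly(spec, covariates)
  nightly <- sim$truth$nightly
  consts <- night_constants()
  nb <- consts$blocks_per_night

  night_offsets <- (seq_len(nb) - 1) * 600 # seconds from 18:00
  day_offsets <- (seq_len(nb) - 1) * 600   # seconds from 06:00

  records <- purrr::map_dfr(seq_len(nrow(nightly)), function(r) {
    counts <- allocate_bout_blocks(nightly$y[r], nb, spec$bout_geom_prob)
    start <- lubridate::as_datetime(nightly$night_date[r], tz = tz) +
      18 * 3600
    out <- tibble::tibble(
      bird_id = nightly$bird_id[r],
      block_start = start + night_offsets,
      wet_count = counts
    )
    if (emit_daytime) {
      rest <- runif(1) < spec$day_rest_rate
      day_start <- lubridate::as_datetime(nightly$night_date[r], tz = tz) +
        6 * 3600
      out <- dplyr::bind_rows(
        tibble::tibble(
          bird_id = nightly$bird_id[r],
          block_start = day_start + day_offsets,
          wet_count = if (rest) rep(max_wet_per_block, nb) else integer(nb)
        ),
        out
      )
    }
    out
  })
  if (spec$missing_block_rate > 0) {
    keep <- runif(nrow(records)) >= spec$missing_block_rate
    records <- records[keep, , drop = FALSE]
  }
  records <- dplyr::arrange(records, .data$bird_id, .data$block_start)
  list(records = records, covariates = covariates, truth = sim$truth)
}

#' Run the generator and write its files
#'
#' Emits `blocks.csv` (logger stream), `covariates.csv` (nightly SST and
#' moon fraction) and `truth.json` (the generating parameters and per-bird
#' coefficients) into `dir`, so recovery studies are self-contained.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @param emit_daytime Passed to [simulate_birds()].
#' @return Invisibly, the [simulate_birds()] result with a `paths` element.
#' @export
simulate_study <- function(spec, dir, emit_daytime = TRUE) {
  sim <- simulate_birds(spec, emit_daytime = emit_daytime)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    blocks = file.path(dir, "blocks.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_block_records(sim$records, paths$blocks)
  write_covariates(sim$covariates, paths$covariates)
  truth <- sim$truth
  jsonlite::write_json(
    list(
      mu_beta = truth$mu_beta,
      sigma = truth$sigma,
      beta = truth$beta,
      bird_ids = rownames(truth$beta),
      seed = spec$seed
    ),
    paths$truth, digits = NA, pretty = TRUE
  )
  sim$paths <- paths
  invisible(sim)
}
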