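#' Read the nightly covariate table
#'
#' One row per date with sea-surface temperature (degrees C) and the fraction
#' of the moon illuminated (0 new to 1 full). Expected header is
#' `date,sst_c,moon_fraction`.
#'
#' @param path Path to a CSV file.
#' @param sst_range Allowed physical SST range in degrees C; values outside
#'   it are a validation error.
#' @return A tibble with `night_date` (Date), `sst` and `moon_fraction`.
#' @export
read_covariates <- function(path, sst_range = c(10, 35)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      sst_c = readr::col_double(),
      moon_fraction = readr::col_double()
    )
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row(s) at line(s): ",
                 paste(head(unique(probs$row), 5), collapse = ", ")))
  }
  out <- tibble::tibble(
    night_date = raw$date,
    sst = raw$sst_c,
    moon_fraction = raw$moon_fraction
  )
  validate_covariates(out, sst_range)
  out
}

validate_covariates <- function(covs, sst_range = c(10, 35)) {
  bad_moon <- which(is.na(covs$moon_fraction) |
                      covs$moon_fraction < 0 | covs$moon_fraction > 1)
  if (length(bad_moon) > 0) {
    abort(paste0("moon_fraction outside [0, 1] in row(s): ",
                 paste(head(bad_moon, 5), collapse = ", ")))
  }
  bad_sst <- which(is.na(covs$sst) |
                     covs$sst < sst_range[1] | covs$sst > sst_range[2])
  if (length(bad_sst) > 0) {
    abort(paste0("sst outside [", sst_range[1], ", ", sst_range[2],
                 "] degrees C in row(s): ",
                 paste(head(bad_sst, 5), collapse = ", ")))
  }
  if (anyDuplicated(covs$night_date)) {
    abort("duplicate dates in covariate table")
  }
  invisible(covs)
}

#' Write the nightly covariate table
#'
#' @param covs Tibble with `night_date`, `sst`, `moon_fraction`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covs, path) {
  out <- tibble::tibble(
    date = covs$night_date,
    sst_c = covs$sst,
    moon_fraction = covs$moon_fraction
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Join nightly observations to their covariates
#'
#' Pairs each bird-night with its design row (intercept, SST, moon fraction).
#' Nights without a covariate row are dropped (default) or the covariates are
#' linearly interpolated between the nearest observed dates. SST is left on
#' its natural scale unless `standardize_sst = TRUE`, which centres and
#' scales it (the scaling is recorded in attributes `sst_center`/`sst_scale`
#' so coefficients can be mapped back).
#'
#' @param nights Nightly observations from [aggregate_nights()].
#' @param covs Covariate table from [read_covariates()].
#' @param policy `"drop"` (default) or `"interpolate"` for nights whose date
#'   is missing from `covs`.
#' @param standardize_sst Centre/scale SST before modelling (off by default
#'   so coefficients stay on the per-degree scale).
#' @return A tibble with the night columns plus `sst` and `moon_fraction`;
#'   never more rows than `nights`.
#' @export
join_design <- function(nights, covs, policy = c("drop", "interpolate"),
                        standardize_sst = FALSE) {
  policy <- match.arg(policy)
  validate_covariates(covs, sst_range = c(-Inf, Inf))
  joined <- dplyr::left_join(nights, covs, by = "night_date")
  miss <- is.na(joined$sst) | is.na(joined$moon_fraction)
  if (any(miss)) {
    if (policy == "drop") {
      inform(paste0(sum(miss), " night(s) dropped: no covariates for their ",
                    "date(s)"))
      joined <- joined[!miss, , drop = FALSE]
    } else {
      xd <- as.numeric(covs$night_date)
      xq <- as.numeric(joined$night_date)
      joined$sst <- ifelse(miss,
                           stats::approx(xd, covs$sst, xout = xq,
                                         rule = 2)$y,
                           joined$sst)
      joined$moon_fraction <- ifelse(miss,
                                     stats::approx(xd, covs$moon_fraction,
                                                   xout = xq, rule = 2)$y,
                                     joined$moon_fraction)
      inform(paste0(sum(miss), " night(s) had covariates interpolated"))
    }
  }
  if (nrow(joined) == 0) abort("no nights remain after covariate join")
  if (standardize_sst) {
    ctr <- mean(joined$sst)
    scl <- sd(joined$sst)
    if (scl == 0) scl <- 1
    joined$sst <- (joined$sst - ctr) / scl
    attr(joined, "sst_center") <- ctr
    attr(joined, "sst_scale") <- scl
  }
  joined
}

#' Design matrix for a model-ready dataset
#'
#' @param data Output of [join_design()].
#' @return Numeric matrix with columns `intercept`, `sst`, `moon_fraction`;
#'   the first column is identically 1.
#' @export
design_matrix <- function(data) {
  cbind(intercept = rep(1, nrow(data)),
        sst = data$sst,
        moon_fraction = data$moon_fraction)
}
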