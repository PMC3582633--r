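#' Immersion-logger geometry constants
#'
#' The loggers score wet/dry every `sample_seconds` and sum the scores within
#' `block_minutes`-long blocks, so a block can hold at most
#' `block_minutes * 60 / sample_seconds` wet sub-periods. Over a
#' `night_hours`-long night window this caps the nightly aggregate count.
#'
#' @param block_minutes Length of one logger block, minutes.
#' @param night_hours Length of the night window, hours.
#' @param sample_seconds Wet/dry sampling interval, seconds.
#'
#' @return A one-row tibble with `blocks_per_night`, `max_count_per_block`
#'   and `max_nightly_count`.
#' @examples
#' night_constants()
#' @export
night_constants <- function(block_minutes = 10, night_hours = 12,
                            sample_seconds = 3) {
  blocks <- night_hours * 60 / block_minutes
  per_block <- block_minutes * 60 / sample_seconds
  tibble::tibble(
    blocks_per_night = blocks,
    max_count_per_block = per_block,
    max_nightly_count = blocks * per_block
  )
}

max_wet_per_block <- 200L

validate_block_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("bird_id", "block_start", "wet_count")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("block records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(records$wet_count) |
                 records$wet_count < 0 |
                 records$wet_count > max_wet_per_block |
                 records$wet_count != round(records$wet_count))
  if (length(bad) > 0) {
    abort(paste0("wet_count outside 0..200 (or non-integer) in row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  off_grid <- which(lubridate::minute(records$block_start) %% 10 != 0 |
                      lubridate::second(records$block_start) != 0)
  if (length(off_grid) > 0) {
    abort(paste0("block_start not aligned to the 10-min grid in row(s): ",
                 paste(head(off_grid, 5), collapse = ", ")))
  }
  dup <- duplicated(records[c("bird_id", "block_start")])
  if (any(dup)) {
    abort(paste0("duplicate (bird_id, block_start) pairs, e.g. row ",
                 which(dup)[1],
                 "; duplicate logger blocks are a hard error"))
  }
  invisible(records)
}

#' Read immersion-logger block records
#'
#' Reads a decoded logger stream: one row per 10-min block with the number of
#' wet 3-s sub-periods (0-200). Expected header is
#' `bird_id,timestamp,wet_count` with ISO-8601 timestamps in local study time
#' (Galapagos has no daylight-saving shifts, so a fixed offset suffices).
#'
#' @param path Path to a CSV file.
#' @param tz Time zone used to interpret the timestamps. The default,
#'   `"Etc/GMT+6"`, is fixed UTC-6 local study time.
#'
#' @return A tibble with columns `bird_id` (character), `block_start`
#'   (POSIXct) and `wet_count` (integer), sorted by bird then time.
#' @seealso [write_block_records()], [aggregate_nights()]
#' @export
read_block_records <- function(path, tz = "Etc/GMT+6") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      timestamp = readr::col_character(),
      wet_count = readr::col_double()
    )
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row(s) at line(s): ",
                 paste(head(unique(probs$row), 5), collapse = ", ")))
  }
  ts <- lubridate::ymd_hms(raw$timestamp, tz = tz, quiet = TRUE)
  if (anyNA(ts)) {
    abort(paste0("unparseable timestamp at data row(s): ",
                 paste(head(which(is.na(ts)), 5), collapse = ", ")))
  }
  out <- tibble::tibble(
    bird_id = raw$bird_id,
    block_start = ts,
    wet_count = as.integer(raw$wet_count)
  )
  validate_block_records(out)
  dplyr::arrange(out, .data$bird_id, .data$block_start)
}

#' Write immersion-logger block records
#'
#' Inverse of [read_block_records()]: writes `bird_id,timestamp,wet_count`
#' with ISO-8601 local-clock timestamps (no offset suffix).
#'
#' @param records Tibble of block records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_block_records <- function(records, path) {
  validate_block_records(records)
  out <- tibble::tibble(
    bird_id = records$bird_id,
    timestamp = format(records$block_start, "%Y-%m-%dT%H:%M:%S"),
    wet_count = as.integer(records$wet_count)
  )
  readr::write_csv(out, path)
  invisible(path)
}

parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 3600 + as.numeric(parts[2]) * 60
}

#' Assign blocks to nights
#'
#' Maps a block start time to the calendar date of the evening its night
#' began. With the default 18:00-06:00 window, blocks starting in
#' \[18:00, 24:00) belong to that evening's date, blocks in \[00:00, 06:00)
#' to the previous evening's date, and daytime blocks to `NA`.
#'
#' @param block_start POSIXct vector of block start times (local clock).
#' @param night_window Length-2 character vector `c(start, end)` of clock
#'   times; the window must span midnight (start later than end).
#'
#' @return A `Date` vector, `NA` for blocks outside the night window.
#' @examples
#' ts <- lubridate::ymd_hms("2010-03-05 18:00:00", "2010-03-06 05:50:00",
#'                          "2010-03-06 12:00:00", tz = "Etc/GMT+6")
#' assign_night(ts)
#' @export
assign_night <- function(block_start, night_window = c("18:00", "06:00")) {
  w0 <- parse_clock(night_window[1])
  w1 <- parse_clock(night_window[2])
  if (w0 <= w1) {
    abort("night_window must span midnight (start later than end)")
  }
  secs <- lubridate::hour(block_start) * 3600 +
    lubridate::minute(block_start) * 60 +
    lubridate::second(block_start)
  date <- lubridate::as_date(block_start)
  dplyr::case_when(
    secs >= w0 ~ date,
    secs < w1 ~ date - 1L,
    TRUE ~ lubridate::as_date(NA)
  )
}

#' Aggregate blocks into nightly binomial counts
#'
#' For each bird-night, sums the wet counts of all blocks in the night window
#' into the aggregate count `y` and sets the binomial trial count
#' `n = 200 * n_blocks` (14,400 for a complete 72-block night). Nights with
#' missing blocks are kept with a proportionally smaller trial count; use
#' `min_blocks` to drop sparsely observed nights.
#'
#' @param records Tibble of block records (see [read_block_records()]).
#' @param night_window Passed to [assign_night()].
#' @param min_blocks Minimum observed blocks for a night to be retained.
#'
#' @return A tibble with one row per bird-night: `bird_id`, `night_date`,
#'   `y`, `n`, `n_blocks`, `proportion`.
#' @export
aggregate_nights <- function(records, night_window = c("18:00", "06:00"),
                             min_blocks = 1) {
  validate_block_records(records)
  records$night_date <- assign_night(records$block_start, night_window)
  records |>
    dplyr::filter(!is.na(.data$night_date)) |>
    dplyr::group_by(.data$bird_id, .data$night_date) |>
    dplyr::summarise(
      y = sum(.data$wet_count),
      n_blocks = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_blocks >= min_blocks) |>
    dplyr::mutate(
      n = max_wet_per_block * .data$n_blocks,
      proportion = .data$y / .data$n
    ) |>
    dplyr::select("bird_id", "night_date", "y", "n", "n_blocks", "proportion")
}

#' Count wet bouts in one night's block sequence
#'
#' A wet bout is a maximal run of consecutive blocks each containing at least
#' one wet 3-s sub-period (at least 3 s on the water); its complement, an
#' all-dry block, belongs to a flying bout.
#'
#' @param wet_counts Integer vector of block wet counts, in time order within
#'   one night.
#' @return A one-row tibble with `n_wet_bouts` and `n_flying_blocks`. An
#'   empty sequence yields zeros.
#' @examples
#' detect_wet_bouts(c(0, 5, 10, 0, 0, 3))
#' @export
detect_wet_bouts <- function(wet_counts) {
  if (length(wet_counts) == 0) {
    return(tibble::tibble(n_wet_bouts = 0L, n_flying_blocks = 0L))
  }
  if (any(is.na(wet_counts)) || any(wet_counts < 0)) {
    abort("wet_counts must be non-negative and non-missing")
  }
  r <- rle(wet_counts >= 1)
  tibble::tibble(
    n_wet_bouts = sum(r$values),
    n_flying_blocks = sum(wet_counts == 0)
  )
}

#' Per-night wet-bout summaries for a block stream
#'
#' Applies [detect_wet_bouts()] to each bird-night of a block-record stream,
#' using the same night window as [aggregate_nights()].
#'
#' @inheritParams aggregate_nights
#' @return A tibble with `bird_id`, `night_date`, `n_wet_bouts`,
#'   `n_flying_blocks`.
#' @export
summarize_bouts <- function(records, night_window = c("18:00", "06:00")) {
  validate_block_records(records)
  records$night_date <- assign_night(records$block_start, night_window)
  records |>
    dplyr::filter(!is.na(.data$night_date)) |>
    dplyr::arrange(.data$bird_id, .data$block_start) |>
    dplyr::group_by(.data$bird_id, .data$night_date) |>
    dplyr::reframe(detect_wet_bouts(.data$wet_count))
}

#' Regress nightly wet time on bout count
#'
#' Diagnostic least-squares fit of the nightly aggregate wet count on the
#' number of wet bouts, matched by bird-night. A strong positive slope
#' indicates that nights with more water landings accumulate proportionally
#' more time on the water.
#'
#' @param nights Nightly observations from [aggregate_nights()].
#' @param bouts Bout summaries from [summarize_bouts()].
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n_nights`.
#' @export
proportion_bout_regression <- function(nights, bouts) {
  joined <- dplyr::inner_join(nights, bouts,
                              by = c("bird_id", "night_date"))
  if (nrow(joined) < 3) abort("need at least 3 matched bird-nights")
  if (var(joined$n_wet_bouts) == 0) {
    abort("bout counts have zero variance; regression undefined")
  }
  fit <- lm(y ~ n_wet_bouts, data = joined)
  tss <- sum((joined$y - mean(joined$y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(fit$residuals^2) / tss
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_nights = nrow(joined)
  )
}

#' Export the nightly table
#'
#' Writes one row per bird-night with the aggregate count, trial count,
#' proportion and bout count (`bird_id,night_date,y,n,n_blocks,proportion,
#' n_wet_bouts`).
#'
#' @param nights Output of [aggregate_nights()].
#' @param bouts Output of [summarize_bouts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_night_table <- function(nights, bouts, path) {
  out <- dplyr::left_join(nights, bouts, by = c("bird_id", "night_date")) |>
    dplyr::select("bird_id", "night_date", "y", "n", "n_blocks",
                  "proportion", "n_wet_bouts")
  readr::write_csv(out, path)
  invisible(path)
}
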