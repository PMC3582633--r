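test_that("reader returns validated records in timestamp order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "bird_id,timestamp,wet_count",
    "g1,2010-03-05T18:20:00,5",
    "g1,2010-03-05T18:00:00,0",
    "g1,2010-03-05T18:10:00,200"
  ), path)
  rec <- read_block_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$wet_count, c(0L, 200L, 5L))
  expect_true(!is.unsorted(rec$block_start))
})

test_that("reader rejects invalid rows with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bird_id,timestamp,wet_count",
               "g1,2010-03-05T18:00:00,201"), path)
  expect_error(read_block_records(path), "0\\.\\.200")

  writeLines(c("bird_id,timestamp,wet_count",
               "g1,not-a-time,3"), path)
  expect_error(read_block_records(path), "timestamp")

  writeLines(c("bird_id,timestamp,wet_count",
               "g1,2010-03-05T18:03:00,3"), path)
  expect_error(read_block_records(path), "10-min grid")

  expect_error(read_block_records(file.path(tempdir(), "absent.csv")),
               "no such file")
})

test_that("block records round-trip losslessly through write-then-read", {
  spec <- simulation_spec(n_birds = 2, n_nights = 1, seed = 4)
  sim <- simulate_birds(spec, emit_daytime = TRUE)
  expect_equal(nrow(sim$records), 2 * 144)
  path <- withr::local_tempfile(fileext = ".csv")
  write_block_records(sim$records, path)
  back <- read_block_records(path)
  expect_equal(back$bird_id, sim$records$bird_id)
  expect_equal(back$wet_count, sim$records$wet_count)
  expect_equal(as.numeric(back$block_start),
               as.numeric(sim$records$block_start))
})

test_that("night assignment maps evening, pre-dawn and daytime blocks", {
  ts <- lubridate::ymd_hms(c("2010-03-05 18:00:00", "2010-03-06 05:50:00",
                             "2010-03-06 12:00:00", "2010-03-05 23:50:00",
                             "2010-03-06 06:00:00", "2010-03-06 17:50:00"),
                           tz = "Etc/GMT+6")
  nights <- assign_night(ts)
  expect_equal(nights, lubridate::as_date(c("2010-03-05", "2010-03-05", NA,
                                            "2010-03-05", NA, NA)))
  expect_error(assign_night(ts, night_window = c("06:00", "18:00")),
               "span midnight")
})

test_that("nightly aggregation reproduces saturation, dry and mixed nights", {
  sat <- aggregate_nights(night_blocks(rep(200, 72)))
  expect_equal(sat$y, 14400)
  expect_equal(sat$n, 14400)
  expect_equal(sat$proportion, 1)
  expect_equal(sat$n_blocks, 72)

  dry <- aggregate_nights(night_blocks(rep(0, 72)))
  expect_equal(dry$y, 0)
  expect_equal(dry$proportion, 0)

  alt <- aggregate_nights(night_blocks(rep(c(0, 100), 36)))
  expect_equal(alt$y, sum(rep(c(0, 100), 36)))
  expect_equal(alt$y, 3600)
  expect_equal(alt$proportion, 0.25)
})

test_that("aggregation rejects duplicate blocks and respects min_blocks", {
  rec <- night_blocks(c(5, 7))
  dup <- dplyr::bind_rows(rec, rec[1, ])
  expect_error(aggregate_nights(dup), "duplicate")

  partial <- night_blocks(c(50, 60, 70))
  agg <- aggregate_nights(partial)
  expect_equal(agg$n, 600)
  expect_equal(agg$proportion, 180 / 600)
  expect_equal(nrow(aggregate_nights(partial, min_blocks = 4)), 0)
})

test_that("aggregation is permutation-invariant and additive over subsets", {
  set.seed(42)
  for (rep in 1:5) {
    counts <- sample(0:200, 72, replace = TRUE)
    rec <- night_blocks(counts)
    base <- aggregate_nights(rec)
    shuffled <- rec[sample(nrow(rec)), ]
    expect_equal(aggregate_nights(shuffled), base)
    split <- sample(c(TRUE, FALSE), 72, replace = TRUE)
    y_parts <- sum(aggregate_nights(rec[split, ])$y) +
      sum(aggregate_nights(rec[!split, ])$y)
    expect_equal(y_parts, base$y)
    expect_true(base$y <= 200 * base$n_blocks)
    expect_true(base$proportion >= 0 && base$proportion <= 1)
  }
})

test_that("wet-bout detection matches examples and handles empty input", {
  expect_equal(detect_wet_bouts(c(0, 5, 10, 0, 0, 3))$n_wet_bouts, 2)
  r <- detect_wet_bouts(c(0, 0, 0, 0))
  expect_equal(r$n_wet_bouts, 0)
  expect_equal(r$n_flying_blocks, 4)
  expect_equal(detect_wet_bouts(rep(1, 72))$n_wet_bouts, 1)
  empty <- detect_wet_bouts(integer(0))
  expect_equal(empty$n_wet_bouts, 0)
  expect_equal(empty$n_flying_blocks, 0)
})

test_that("wet-bout detection equals the brute-force run counter", {
  set.seed(99)
  ok <- vapply(1:1000, function(i) {
    len <- sample(1:72, 1)
    x <- sample(0:3, len, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1)) *
      sample(c(1, 50), len, replace = TRUE)
    got <- detect_wet_bouts(x)
    identical(got$n_wet_bouts, brute_bout_count(x)) &&
      identical(got$n_flying_blocks, sum(x == 0)) &&
      got$n_wet_bouts <= ceiling(len / 2)
  }, logical(1))
  expect_identical(sum(ok), 1000L)
})

test_that("bout regression recovers exact and degenerate fits", {
  bouts <- tibble::tibble(
    bird_id = "b1",
    night_date = lubridate::as_date("2010-03-05") + 0:4,
    n_wet_bouts = c(1L, 2L, 3L, 4L, 5L),
    n_flying_blocks = 0L
  )
  nights <- tibble::tibble(
    bird_id = "b1", night_date = bouts$night_date,
    y = 100 * bouts$n_wet_bouts, n = 14400, n_blocks = 72,
    proportion = y / n
  )
  fit <- proportion_bout_regression(nights, bouts)
  expect_equal(fit$slope, 100)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  const <- dplyr::mutate(nights, y = 500)
  expect_equal(proportion_bout_regression(const, bouts)$r_squared, 0)

  flat_bouts <- dplyr::mutate(bouts, n_wet_bouts = 2L)
  expect_error(proportion_bout_regression(nights, flat_bouts),
               "zero variance")
  expect_error(proportion_bout_regression(nights[1:2, ], bouts[1:2, ]),
               "at least 3")
})

test_that("bout regression agrees with the normal-equations oracle", {
  spec <- simulation_spec(n_birds = 4, n_nights = 30, seed = 21)
  sim <- simulate_birds(spec, emit_daytime = FALSE)
  nights <- aggregate_nights(sim$records)
  bouts <- summarize_bouts(sim$records)
  fit <- proportion_bout_regression(nights, bouts)
  joined <- dplyr::inner_join(nights, bouts, by = c("bird_id", "night_date"))
  oracle <- ols_oracle(joined$n_wet_bouts, joined$y)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
})

test_that("night table export carries the documented columns", {
  spec <- simulation_spec(n_birds = 2, n_nights = 3, seed = 5)
  sim <- simulate_birds(spec, emit_daytime = FALSE)
  nights <- aggregate_nights(sim$records)
  bouts <- summarize_bouts(sim$records)
  path <- withr::local_tempfile(fileext = ".csv")
  write_night_table(nights, bouts, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("bird_id", "night_date", "y", "n", "n_blocks",
                       "proportion", "n_wet_bouts"))
  expect_equal(nrow(back), nrow(nights))
})
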