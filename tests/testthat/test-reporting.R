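test_that("per-minute aggregates reproduce box-plot numbers", {
  const <- data.frame(t_s = 0:119, ca_deg = rep(40, 120))
  agg <- aggregate_minutes(const)
  expect_identical(nrow(agg), 2L)
  expect_true(all(agg$n == 60))
  expect_true(all(agg[c("min", "q1", "median", "q3", "max")] == 40))

  ramp <- data.frame(t_s = 0:59, ca_deg = 1:60)
  a <- aggregate_minutes(ramp)
  expect_equal(a$median, 30.5)
  expect_equal(a$q1, 15.75)
  expect_equal(a$q3, 45.25)

  proto <- data.frame(t_s = 0:239, ka_deg = rnorm(240, 30))
  expect_identical(nrow(aggregate_minutes(proto)), 4L)
})

test_that("aggregate quartiles match the sort-based oracle and stay ordered", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(1:60, 1)
    v <- runif(n, 0, 90)
    a <- aggregate_minutes(data.frame(t_s = seq_len(n) - 1, ca_deg = v))
    expect_equal(a$q1, quantile_oracle(v, 0.25))
    expect_equal(a$median, quantile_oracle(v, 0.50))
    expect_equal(a$q3, quantile_oracle(v, 0.75))
    expect_true(a$min <= a$q1 && a$q1 <= a$median &&
                a$median <= a$q3 && a$q3 <= a$max)
  }
})

test_that("missing samples are excluded and empty minutes omitted", {
  s <- data.frame(t_s = 0:179,
                  ca_deg = c(rnorm(60, 40), rep(NA, 60), rnorm(60, 55)))
  a <- aggregate_minutes(s)
  expect_identical(a$minute_index, c(0, 2))
  expect_true(all(a$n == 60))
})

test_that("pearson_with_band matches a from-scratch covariance oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(pearson_with_band(x, y)$r, pearson_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("correlation bands follow the 0.90/0.70/0.50 cutpoints on |r|", {
  x <- 1:10
  expect_identical(pearson_with_band(x, 2 * x + 1)$r_band, "very_high")
  expect_identical(pearson_with_band(x, -x)$r_band, "very_high")
  expect_equal(pearson_with_band(x, -x)$r, -1)
  # banded by magnitude, exercised at each printed cutpoint
  band_of <- function(r) posturekit:::.portney_band(r)
  expect_identical(band_of(0.992), "very_high")
  expect_identical(band_of(0.900), "very_high")
  expect_identical(band_of(0.704), "high")
  expect_identical(band_of(0.607), "moderate")
  expect_identical(band_of(0.500), "moderate")
  expect_identical(band_of(0.499), "low")
  expect_error(pearson_with_band(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_band(1:2, 2:3), "at least 3")
})

test_that("perfect linearity gives a significant very-high correlation", {
  vs <- pearson_with_band(1:10, 2 * (1:10) + 1)
  expect_equal(vs$r, 1.0)
  expect_lt(vs$p_two_tailed, 0.01)
  expect_equal(vs$r_squared_pct, 100)
})

test_that("MAPE matches hand computations and is scale-invariant", {
  expect_equal(mape(c(40, 50), c(40, 50)), 0)
  expect_equal(mape(c(100, 100), c(95, 105)), 0.05)
  expect_equal(mape(40, 44), 0.10)
  set.seed(43)
  ref <- runif(50, 10, 90)
  cand <- ref + rnorm(50)
  k <- 7.3
  expect_equal(mape(k * ref, k * cand), mape(ref, cand), tolerance = 1e-12)
  expect_warning(m <- mape(c(0, 100), c(1, 110)), "zero reference")
  expect_equal(m, 0.10)
  expect_error(mape(c(0, 0), c(1, 1)), "undefined")
})

test_that("validate_series pairs two session tables on one channel", {
  ref <- data.frame(t_s = 0:99, ka_deg = runif(100, 30, 60))
  cand <- ref
  cand$ka_deg <- cand$ka_deg * 1.02
  vs <- validate_series(ref, cand, "ka_deg")
  expect_equal(vs$mape, 0.02, tolerance = 1e-9)
  expect_identical(vs$r_band, "very_high")
  expect_output(print(vs), "MAPE")
})

test_that("export_report writes the full machine-readable bundle", {
  upper <- simulate_accel_stream(25, 240, noise_sd_deg = 0)
  mid <- simulate_accel_stream(20, 240, noise_sd_deg = 0)
  series <- pair_streams(upper, mid)
  dir <- withr::local_tempdir()
  paths <- export_report(series, dir, plots = TRUE)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[["report"]])
  expect_equal(rep$n_samples, 240)
  expect_equal(rep$summary$kyphotic_fraction, 1)
  expect_identical(rep$aggregation$quartile_method,
                   "linear interpolation (type 7)")
  minutes <- utils::read.csv(paths[["minutes"]])
  expect_identical(nrow(minutes[minutes$channel == "ka_deg", ]), 4L)

  # constant series collapse to a single nonzero histogram bin per channel
  h <- angle_histogram(series, "ka_deg")
  expect_identical(nrow(h), 1L)
  expect_equal(h$count, 240L)

  expect_error(export_report(series[0, ], dir), "empty")
})
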