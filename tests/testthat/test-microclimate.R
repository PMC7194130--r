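test_that("daily statistics use the half-range daily average", {
  empty <- data.frame(logger_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      temperature = numeric(0))
  expect_error(daily_stats(empty), "empty")

  d <- daily_stats(hourly_series(rep(8, 24)))
  expect_equal(d$tmin, 8); expect_equal(d$tmax, 8); expect_equal(d$tavg, 8)

  # tavg is forced by min and max alone
  temps <- c(2, 10, runif(22, 2.5, 9.5))
  d2 <- daily_stats(hourly_series(temps))
  expect_equal(d2$tavg, 6)

  # half-range differs from the arithmetic mean by design
  d3 <- daily_stats(hourly_series(c(rep(0, 23), 12)))
  expect_equal(d3$tavg, 6)
  expect_false(isTRUE(all.equal(d3$tavg, mean(c(rep(0, 23), 12)))))
})

test_that("days with too few valid hours are emitted as missing", {
  temps <- c(rep(5, 10), rep(NA, 14), rep(6, 24))  # day 1 has 10 valid hours
  d <- daily_stats(hourly_series(temps))
  expect_true(is.na(d$tavg[1]))
  expect_equal(d$tavg[2], 6)
  expect_equal(d$n_hours, c(10, 24))
  d17 <- daily_stats(hourly_series(temps), min_hours = 10)
  expect_equal(d17$tavg[1], 5)
})

test_that("growing degree days match hand evaluation and edge cases", {
  mk <- function(tavg) data.frame(date = as.Date("2018-06-01") +
                                    seq_along(tavg) - 1, tavg = tavg)
  expect_equal(growing_degree_days(mk(rep(10, 10)))$gdd, 50)
  expect_equal(growing_degree_days(mk(c(5, 4, 2, 5)))$gdd, 0)
  r <- growing_degree_days(mk(c(6, 4, 7)))
  expect_equal(r$gdd, 3)
  expect_equal(r$days_counted, 3)
  expect_equal(r$days_above, 2)
  # missing days are skipped and reflected in days_counted
  r2 <- growing_degree_days(mk(c(6, NA, 7)))
  expect_equal(r2$gdd, 3)
  expect_equal(r2$days_counted, 2)
  expect_error(growing_degree_days(mk(1:3),
                                   window = as.Date(c("2019-01-01",
                                                      "2019-01-02"))),
               "window")
})

test_that("GDD is monotone in daily temperature and in the threshold", {
  set.seed(1)
  for (rep in 1:20) {
    tavg <- runif(30, -2, 12)
    d <- data.frame(date = as.Date("2018-06-01") + 0:29, tavg = tavg)
    g0 <- growing_degree_days(d)$gdd
    # raising any one day never decreases GDD
    i <- sample(30, 1)
    d2 <- d; d2$tavg[i] <- d2$tavg[i] + runif(1, 0, 5)
    expect_gte(growing_degree_days(d2)$gdd, g0)
    # appending a sub-threshold day changes nothing
    d3 <- rbind(d, data.frame(date = as.Date("2018-07-01"), tavg = 4.9))
    expect_equal(growing_degree_days(d3)$gdd, g0)
    # lower threshold accumulates at least as much
    expect_gte(growing_degree_days(d, threshold = 3)$gdd,
               growing_degree_days(d, threshold = 7)$gdd)
  }
})

test_that("strict and inclusive threshold readings differ only at equality", {
  d <- data.frame(date = as.Date("2018-06-01") + 0:2, tavg = c(5, 6, 4))
  strict <- growing_degree_days(d)
  incl <- growing_degree_days(d, inclusive = TRUE)
  expect_equal(strict$gdd, incl$gdd)     # the boundary day contributes 0
  expect_equal(strict$days_above, 1)
  expect_equal(incl$days_above, 2)
})

test_that("gap imputation fills from the prior year and never touches data", {
  su <- data.frame(summit_id = "A", elevation = 3500)
  off <- c(N = 0, S = 0, E = 0, W = 0)
  # identical windows: residual distribution degenerate at 0
  ls <- generate_logger_series(su[, , drop = FALSE], aspect_offsets = off,
                               noise_sd = 0, warming_increment = 0,
                               seed = 1)
  s1 <- ls[ls$logger_id == "A.N" & ls$window == 1, ]
  s2 <- ls[ls$logger_id == "A.N" & ls$window == 2, ]
  miss <- 3000:3023
  truth <- s2$temperature[miss]
  s2$temperature[miss] <- NA
  out <- impute_gaps(s2, s1, seed = 7)
  expect_equal(out$n_filled, 24)
  expect_equal(out$filled$temperature[miss], truth, tolerance = 1e-12)
  expect_true(all(out$imputation_sd$sd == 0))
  # untouched elsewhere
  expect_identical(out$filled$temperature[-miss], s2$temperature[-miss])

  # no gaps: returned unchanged
  out0 <- impute_gaps(s1, s1, seed = 1)
  expect_identical(out0$filled, s1)
  expect_equal(out0$n_filled, 0L)

  # unserviceable slot: reference missing the counterpart
  s1_short <- s1[-(3000:3023), ]
  expect_error(impute_gaps(s2, s1_short, seed = 1), "counterpart")
})

test_that("masking experiment: imputation error is below diurnal amplitude", {
  su <- data.frame(summit_id = "A", elevation = 3500)
  off <- c(N = 0, S = 0, E = 0, W = 0)
  ls <- generate_logger_series(su, aspect_offsets = off, noise_sd = 1,
                               diurnal_amplitude = 2, seed = 21)
  s1 <- ls[ls$logger_id == "A.N" & ls$window == 1, ]
  s2 <- ls[ls$logger_id == "A.N" & ls$window == 2, ]
  miss <- 4000:4479                      # 480-hour mask
  truth <- s2$temperature[miss]
  s2$temperature[miss] <- NA
  outA <- impute_gaps(s2, s1, seed = 5)
  outB <- impute_gaps(s2, s1, seed = 5)
  expect_identical(outA$filled, outB$filled)   # seed-reproducible
  mae <- mean(abs(outA$filled$temperature[miss] - truth))
  expect_lt(mae, 2)
})

test_that("temperature trends recover slope, degeneracy, and warming", {
  tr <- temperature_trend(c(1, 2, 3, 4))
  expect_equal(tr$slope, 1)
  expect_equal(tr$p_value, 0)
  flat <- temperature_trend(rep(2.5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  expect_error(temperature_trend(c(1, 2)), "3 periods")

  # warming recovery against the generator's truth over replicate seeds
  su <- data.frame(summit_id = "A", elevation = 3500)
  off <- c(N = 0, S = 0, E = 0, W = 0)
  deltas <- vapply(1:40, function(s) {
    ls <- generate_logger_series(su, aspect_offsets = off, noise_sd = 1,
                                 warming_increment = 1.5, seed = 900 + s)
    x <- ls[ls$logger_id == "A.N", ]
    mean(x$temperature[x$window == 2]) - mean(x$temperature[x$window == 1])
  }, numeric(1))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 1.5), 3 * se)
})
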