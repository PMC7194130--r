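# Soil-temperature logger processing: daily statistics, growing degree
# days, seasonal-analogue gap imputation, and temperature trends.

#' Read hourly logger series from delimited text
#'
#' @param path CSV with columns `logger_id`, `timestamp` (ISO 8601),
#'   `temperature`, and optionally `summit_id`, `aspect`, `window`.
#' @return data.frame of class `logger_series`.
#' @export
read_logger_series <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("logger_id", "timestamp", "temperature")
  .assert(all(need %in% names(x)),
          "logger file needs columns logger_id, timestamp, temperature")
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC")
  .assert(!anyNA(x$timestamp), "unparseable timestamps in ", path)
  x$temperature <- suppressWarnings(as.numeric(x$temperature))
  if (!"window" %in% names(x)) x$window <- 1L
  class(x) <- c("logger_series", "data.frame")
  x
}

# Check hourly spacing within each logger/window group.
.check_hourly <- function(series) {
  .assert(all(c("logger_id", "timestamp", "temperature") %in% names(series)),
          "series needs columns logger_id, timestamp, temperature")
  grp <- paste(series$logger_id, series$window %||% 1L)
  for (g in split(seq_len(nrow(series)), grp)) {
    ts <- series$timestamp[g]
    .assert(!is.unsorted(ts, strictly = TRUE),
            "timestamps must be strictly increasing per logger")
    d <- diff(as.numeric(ts))
    .assert(all(d == 3600), "timestamps must be hourly (1 h spacing)")
  }
  invisible(TRUE)
}

#' Daily temperature statistics from hourly values
#'
#' Per logger, window, and calendar day: the minimum and maximum of the
#' available hourly values and the daily average defined as the half-range
#' `tavg = 0.5 * (tmin + tmax)` (the convention used when loggers report
#' at fixed intervals; note it differs from the arithmetic mean of the
#' hourly values).  Days with fewer valid hours than `min_hours` are
#' emitted with missing statistics.
#'
#' @param series A `logger_series` (hourly; missing values allowed).
#' @param min_hours Minimum number of non-missing hourly values a day needs
#'   to be summarized (default 18 of 24).
#' @return data.frame with columns `logger_id`, `window`, `date`,
#'   `n_hours`, `tmin`, `tmax`, `tavg`.
#' @export
daily_stats <- function(series, min_hours = 18) {
  .assert(nrow(series) > 0, "empty series")
  .check_hourly(series)
  if (is.null(series$window)) series$window <- 1L
  day <- as.Date(series$timestamp, tz = "UTC")
  key <- data.frame(logger_id = series$logger_id, window = series$window,
                    date = day, stringsAsFactors = FALSE)
  agg <- function(f, v) {
    stats::aggregate(v, key, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < min_hours) NA_real_ else f(z)
    })$x
  }
  out <- unique(key)
  out <- out[order(out$logger_id, out$window, out$date), ]
  o2 <- stats::aggregate(series$temperature, key, function(z) sum(!is.na(z)))
  m <- match(paste(out$logger_id, out$window, out$date),
             paste(o2$logger_id, o2$window, o2$date))
  out$n_hours <- o2$x[m]
  tmin <- stats::aggregate(series$temperature, key, function(z) {
    z <- z[!is.na(z)]; if (length(z) < min_hours) NA_real_ else min(z)
  })
  tmax <- stats::aggregate(series$temperature, key, function(z) {
    z <- z[!is.na(z)]; if (length(z) < min_hours) NA_real_ else max(z)
  })
  m1 <- match(paste(out$logger_id, out$window, out$date),
              paste(tmin$logger_id, tmin$window, tmin$date))
  out$tmin <- tmin$x[m1]
  out$tmax <- tmax$x[m1]
  out$tavg <- 0.5 * (out$tmin + out$tmax)
  rownames(out) <- NULL
  out
}

#' Growing degree days above a threshold
#'
#' Accumulates `tavg - threshold` over the days whose daily average
#' temperature exceeds the threshold (strictly, by default; set
#' `inclusive = TRUE` for "at or above").  The 5 degC default threshold is
#' the biologically motivated choice for alpine soil.
#'
#' @param daily Output of [daily_stats()] (or any data.frame with `date`
#'   and `tavg`), for a single logger/window.
#' @param threshold Base temperature in degC.
#' @param window Optional length-2 `Date` (start, end) restricting the
#'   accumulation window; defaults to the full span of `daily`.
#' @param inclusive If `TRUE`, days with `tavg == threshold` also qualify
#'   (they contribute 0 degree-days either way; the flag matters only for
#'   the qualifying-day count).
#' @return List with `gdd` (degree-days), `days_counted` (days with a
#'   non-missing daily average inside the window), `days_above` (days
#'   qualifying), `window`.
#' @export
#' @examples
#' d <- data.frame(date = as.Date("2018-06-01") + 0:2, tavg = c(6, 4, 7))
#' growing_degree_days(d)$gdd   # 1 + 0 + 2 = 3
growing_degree_days <- function(daily, threshold = 5, window = NULL,
                                inclusive = FALSE) {
  .assert(all(c("date", "tavg") %in% names(daily)),
          "'daily' needs columns date, tavg")
  dates <- as.Date(daily$date)
  if (is.null(window)) window <- range(dates)
  window <- as.Date(window)
  .assert(length(window) == 2L && window[2] >= window[1],
          "invalid (empty) window")
  keep <- dates >= window[1] & dates <= window[2]
  .assert(any(keep), "window contains no days of the series")
  tavg <- daily$tavg[keep]
  ok <- !is.na(tavg)
  qual <- if (inclusive) tavg[ok] >= threshold else tavg[ok] > threshold
  list(gdd = sum(pmax(tavg[ok] - threshold, 0) * qual),
       days_counted = sum(ok),
       days_above = sum(qual),
       window = window)
}

#' Fill logger gaps from the previous year's record (seasonal analogue)
#'
#' Each missing hour is filled with the same calendar slot
#' (month-day-hour) of the reference (previous-year) series plus the mean
#' of `n_imputations` residuals drawn from the empirical distribution of
#' current-minus-reference differences over the non-missing hours of the
#' same calendar month.  Observed values are never altered.  The spread of
#' the residual draws is returned as a per-hour imputation SD.
#'
#' @param series Hourly data.frame (`timestamp`, `temperature`) for one
#'   logger, containing the gaps.
#' @param reference Same-logger hourly data.frame covering the same
#'   calendar slots one year-window earlier.
#' @param n_imputations Number of residual draws averaged per missing hour.
#' @param seed Integer seed for the residual draws.
#' @return List with `filled` (the series with gaps filled),
#'   `imputation_sd` (data.frame `timestamp`, `sd` for each filled hour),
#'   and `n_filled`.
#' @export
impute_gaps <- function(series, reference, n_imputations = 30, seed = 1) {
  .assert(all(c("timestamp", "temperature") %in% names(series)) &&
            all(c("timestamp", "temperature") %in% names(reference)),
          "series and reference need columns timestamp, temperature")
  .assert(.is_count(n_imputations) && n_imputations >= 1,
          "'n_imputations' must be a positive integer")
  slot <- function(ts) format(ts, "%m-%d %H", tz = "UTC")
  miss <- which(is.na(series$temperature))
  if (length(miss) == 0L) {
    return(list(filled = series,
                imputation_sd = data.frame(
                  timestamp = series$timestamp[0], sd = numeric(0)),
                n_filled = 0L))
  }
  ref_slot <- slot(reference$timestamp)
  cur_slot <- slot(series$timestamp)
  ref_at <- reference$temperature[match(cur_slot[miss], ref_slot)]
  bad <- is.na(ref_at)
  .assert(!any(bad),
          "no previous-year counterpart for slot(s): ",
          paste(utils::head(cur_slot[miss][bad], 5L), collapse = ", "))
  # residual pools by calendar month, from hours observed in both series
  obs <- which(!is.na(series$temperature))
  ref_obs <- reference$temperature[match(cur_slot[obs], ref_slot)]
  diffs <- series$temperature[obs] - ref_obs
  pool_month <- format(series$timestamp[obs], "%m", tz = "UTC")
  keep <- !is.na(diffs)
  pools <- split(diffs[keep], pool_month[keep])
  month_miss <- format(series$timestamp[miss], "%m", tz = "UTC")
  all_diffs <- diffs[keep]
  .assert(length(all_diffs) > 0,
          "no overlapping observed hours to build a residual distribution")
  set.seed(as.integer(seed))
  fills <- numeric(length(miss))
  sds <- numeric(length(miss))
  for (i in seq_along(miss)) {
    pool <- pools[[month_miss[i]]]
    if (is.null(pool) || length(pool) == 0L) pool <- all_diffs
    draws <- sample(pool, n_imputations, replace = TRUE)
    fills[i] <- ref_at[i] + mean(draws)
    sds[i] <- if (n_imputations > 1) stats::sd(draws) else 0
  }
  filled <- series
  filled$temperature[miss] <- fills
  list(filled = filled,
       imputation_sd = data.frame(timestamp = series$timestamp[miss],
                                  sd = sds),
       n_filled = length(miss))
}

#' Linear trend of aggregated mean temperatures
#'
#' Ordinary least-squares regression of period means (monthly or annual)
#' on the period index, with the usual t test of the slope.  A series with
#' zero residual variance is handled explicitly: an exactly constant
#' response gives slope 0 with p = 1, an exact nonzero trend gives p = 0.
#'
#' @param means Numeric vector of period mean temperatures, in period
#'   order, or a data.frame with columns `period` and `mean`.
#' @param level Label for the aggregation level ("monthly" or "annual");
#'   metadata only.
#' @return List with `slope` (degC per period), `statistic` (t),
#'   `p_value`, `n`.
#' @export
temperature_trend <- function(means, level = c("annual", "monthly")) {
  level <- match.arg(level)
  if (is.data.frame(means)) {
    .assert(all(c("period", "mean") %in% names(means)),
            "data.frame input needs columns period, mean")
    y <- means$mean[order(means$period)]
  } else {
    y <- as.numeric(means)
  }
  n <- length(y)
  .assert(n >= 3, "need at least 3 periods for a trend")
  x <- seq_len(n)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-24 * max(1, sum(y^2))) {   # numerically exact fit
    return(list(slope = slope,
                statistic = if (abs(slope) < 1e-12) 0 else Inf,
                p_value = if (abs(slope) < 1e-12) 1 else 0,
                n = n, level = level))
  }
  s <- summary(fit)$coefficients
  list(slope = slope, statistic = unname(s[2, "t value"]),
       p_value = unname(s[2, "Pr(>|t|)"]), n = n, level = level)
}

#' Annual and monthly logger summaries
#'
#' Convenience wrapper: daily statistics, per-window annual means, and GDD
#' per logger and window.
#'
#' @param series A `logger_series` covering one or more loggers/windows.
#' @param threshold GDD base temperature (degC).
#' @param min_hours Passed to [daily_stats()].
#' @return data.frame with one row per logger and window: `annual_mean`
#'   (of daily tavg), `gdd`, `days_above`, `days_counted`.
#' @export
microclimate_summary <- function(series, threshold = 5, min_hours = 18) {
  d <- daily_stats(series, min_hours = min_hours)
  grp <- split(d, paste(d$logger_id, d$window, sep = "\r"))
  out <- do.call(rbind, lapply(grp, function(g) {
    gd <- growing_degree_days(g, threshold = threshold)
    data.frame(logger_id = g$logger_id[1], window = g$window[1],
               annual_mean = mean(g$tavg, na.rm = TRUE),
               gdd = gd$gdd, days_above = gd$days_above,
               days_counted = gd$days_counted, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$logger_id, out$window), ]
}
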