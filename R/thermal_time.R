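#' Daily greenhouse temperature series
#'
#' Container for an air-temperature record. Sub-daily logs (POSIXct
#' timestamps) are reduced to daily means on construction; all thermal-time
#' arithmetic downstream works on the daily-mean series, the convention under
#' which cumulative temperature is a running sum of daily mean temperatures
#' (degree-days, base 0 degC).
#'
#' @param timestamp `Date` (one per day) or `POSIXct` (sub-daily) vector,
#'   strictly increasing. Character vectors are parsed as ISO-8601 dates.
#' @param temp_c numeric air temperatures in degC, finite.
#' @return A `temperature_series`: a tibble with columns `date` and `temp_c`
#'   (one row per day, contiguous), carrying class `"temperature_series"`.
#' @examples
#' ts <- temperature_series(seq(as.Date("2022-09-01"), by = 1, length.out = 30),
#'                          rep(20, 30))
#' ts
#' @export
temperature_series <- function(timestamp, temp_c) {
  if (length(timestamp) != length(temp_c)) {
    hc_abort("timestamp and temp_c must have equal length", "hc_schema_error")
  }
  if (length(timestamp) == 0L) {
    hc_abort("temperature series is empty", "hc_domain_error")
  }
  if (!all(is.finite(temp_c))) {
    hc_abort("temperatures must be finite", "hc_domain_error")
  }
  tnum <- time_to_days(as_date_strict(timestamp))
  if (any(diff(tnum) <= 0)) {
    hc_abort("timestamps must be strictly increasing (no duplicates)",
             "hc_schema_error")
  }
  dates <- if (inherits(timestamp, "POSIXt")) {
    as.Date(timestamp, tz = "UTC")
  } else {
    as_date_strict(timestamp)
  }
  day_num <- sort(unique(as.numeric(dates)))
  daily <- vapply(day_num,
                  function(d) mean(temp_c[as.numeric(dates) == d]),
                  numeric(1))
  if (!identical(day_num, seq(day_num[1L], by = 1, length.out = length(day_num)))) {
    hc_abort("temperature series has gaps: one record per day required",
             "hc_coverage_error")
  }
  out <- tibble::tibble(date = as.Date(day_num, origin = "1970-01-01"),
                        temp_c = daily)
  class(out) <- c("temperature_series", class(out))
  out
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d days, %s to %s, mean %.1f degC\n",
              nrow(x), format(x$date[1L]), format(x$date[nrow(x)]),
              mean(x$temp_c)))
  invisible(x)
}

#' Read a temperature log CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `temp_c`. Rejects unsorted or
#' duplicated timestamps.
#'
#' @param path file path.
#' @return A [temperature_series()].
#' @export
read_temperature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df))) {
    hc_abort("temperature CSV needs columns timestamp, temp_c",
             "hc_schema_error")
  }
  temperature_series(df$timestamp, df$temp_c)
}

#' Write a temperature series to CSV
#'
#' @param series a [temperature_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(series, path) {
  df <- data.frame(timestamp = format(series$date), temp_c = series$temp_c)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-flower thermal clock
#'
#' Binds an anthesis date to a temperature series so calendar time can be
#' mapped to physiological time (cumulative degree-days after anthesis).
#'
#' @param anthesis anthesis date (`Date` or ISO-8601 string).
#' @param series a [temperature_series()] spanning the anthesis date.
#' @return A `thermal_clock` object.
#' @export
thermal_clock <- function(anthesis, series) {
  stopifnot(inherits(series, "temperature_series"))
  anthesis <- as_date_strict(anthesis, "anthesis")
  if (length(anthesis) != 1L) {
    hc_abort("anthesis must be a single date", "hc_schema_error")
  }
  if (anthesis < series$date[1L] || anthesis > series$date[nrow(series)]) {
    hc_abort("anthesis outside the span of the temperature series",
             "hc_coverage_error")
  }
  structure(list(anthesis = anthesis, series = series),
            class = "thermal_clock")
}

#' @export
print.thermal_clock <- function(x, ...) {
  cat(sprintf("<thermal_clock> anthesis %s over %d-day series\n",
              format(x$anthesis), nrow(x$series)))
  invisible(x)
}

# cumulative degree-days from anthesis to fractional day `d`
# (days since epoch); vectorised over d
cum_dd_at <- function(clock, d) {
  s <- clock$series
  day0 <- as.numeric(s$date[1L])
  cs <- c(0, cumsum(s$temp_c))   # cs[k+1] = sum of first k daily means
  a <- as.numeric(clock$anthesis)
  full <- floor(d)
  idx_a <- a - day0 + 1L
  idx_t <- full - day0 + 1L
  frac <- d - full
  tau <- (cs[pmin(idx_t, length(cs))] - cs[idx_a])
  # partial trailing day: fraction of that day's mean
  has_frac <- frac > 0
  if (any(has_frac)) {
    tau[has_frac] <- tau[has_frac] + frac[has_frac] * s$temp_c[idx_t[has_frac]]
  }
  tau
}

#' Cumulative temperature after anthesis
#'
#' Thermal time tau(t): the sum of daily mean temperatures (degree-days,
#' base 0 degC) over whole days from anthesis up to, but not including, `t`.
#' A `POSIXct` `t` contributes the final partial day as
#' (fraction of day) x (that day's mean). `tau(anthesis) = 0`.
#'
#' @param clock a [thermal_clock()].
#' @param t query timestamp(s), `Date`, `POSIXct` or ISO-8601 string; must lie
#'   in `[anthesis, series end + 1 day]`.
#' @return numeric vector of thermal times in degC d.
#' @examples
#' ts <- temperature_series(seq(as.Date("2022-09-01"), by = 1, length.out = 30),
#'                          rep(20, 30))
#' ck <- thermal_clock("2022-09-05", ts)
#' cumulative_temperature(ck, as.Date("2022-09-15"))  # 10 days x 20 degC
#' @export
cumulative_temperature <- function(clock, t) {
  stopifnot(inherits(clock, "thermal_clock"))
  d <- time_to_days(t)
  a <- as.numeric(clock$anthesis)
  if (any(d < a)) {
    hc_abort("query time precedes anthesis", "hc_domain_error")
  }
  # series covers through the end of its last day
  if (any(d > as.numeric(clock$series$date[nrow(clock$series)]) + 1)) {
    hc_abort("query time beyond temperature series coverage",
             "hc_coverage_error")
  }
  cum_dd_at(clock, d)
}

#' Invert thermal time to a calendar date
#'
#' Earliest date `t` (a day boundary) with
#' `cumulative_temperature(clock, t) >= target`.
#'
#' @param clock a [thermal_clock()].
#' @param target thermal time in degC d, `>= 0`.
#' @return a `Date`.
#' @export
invert_thermal_time <- function(clock, target) {
  stopifnot(inherits(clock, "thermal_clock"), length(target) == 1L)
  if (target < 0) {
    hc_abort("target thermal time must be non-negative", "hc_domain_error")
  }
  if (target == 0) {
    return(clock$anthesis)
  }
  s <- clock$series
  i0 <- match(clock$anthesis, s$date)
  cs <- cumsum(s$temp_c[i0:nrow(s)])
  k <- which(cs >= target)
  if (length(k) == 0L) {
    hc_abort("target thermal time not reachable within series coverage",
             "hc_coverage_error")
  }
  clock$anthesis + k[1L]
}

#' Mean temperature from anthesis to a date
#'
#' Arithmetic mean of daily mean temperatures over `[anthesis, t_end)`,
#' computed as cumulative temperature divided by elapsed days so that
#' `mean x elapsed = cumulative` holds exactly.
#'
#' @param clock a [thermal_clock()].
#' @param t_end end timestamp, strictly after anthesis.
#' @return mean temperature in degC.
#' @export
mean_temperature <- function(clock, t_end) {
  stopifnot(inherits(clock, "thermal_clock"))
  d <- time_to_days(t_end)
  a <- as.numeric(clock$anthesis)
  if (any(d <= a)) {
    hc_abort("mean_temperature needs a non-empty interval after anthesis",
             "hc_domain_error")
  }
  cumulative_temperature(clock, t_end) / (d - a)
}
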