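#' @keywords internal
"_PACKAGE"

# Canonical weather variable names used throughout the package.
WEATHER_VARS <- c("air_temp", "wind_speed", "wind_dir", "pressure",
                  "rh", "rainfall", "mo_length")

# Seasonal variables derived from the timestamp; resampled jointly with
# weather during normalization. The `time_days` trend variable is never
# resampled.
SEASONAL_VARS <- c("hour", "wday", "yday")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rddair <- function(..., class = "rddair_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert <- function(cond, ...) if (!isTRUE(cond)) stop_rddair(...)

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the master seed and the stage name, so stages can
#' be rerun in isolation and still reproduce a full-run result. Result is
#' kept well below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483587)
}

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  assert(!any(is.na(d)), "invalid ", what, ": ", paste(x, collapse = ", "))
  d
}

# Hourly timestamp sequence, timezone-naive (represented in UTC).
hour_seq <- function(start, end) {
  seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
      as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = "hour")
}

# Timestamp-derived model features. `origin` anchors the trend variable.
time_features <- function(time, origin) {
  lt <- as.POSIXlt(time, tz = "UTC")
  data.frame(
    hour = lt$hour,
    wday = lt$wday,                       # 0 = Sunday
    yday = lt$yday + 1L,
    time_days = as.numeric(difftime(time, as.POSIXct(paste(origin, "00:00:00"),
                                                     tz = "UTC"),
                                    units = "days"))
  )
}

# Stationary AR(1) series: x_t = rho x_{t-1} + e_t, marginal sd = sd.
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  if (rho == 0) return(stats::rnorm(n, 0, sd))
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

pearson_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
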