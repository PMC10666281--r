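# Synthetic monitoring-network generator with known ground truth.
#
# Emulates the statistical structure of an urban air quality network around
# an intervention with a known start date T0: weather- and seasonality-driven
# variation in hourly concentrations, a long-term trend, a site-level
# intervention step of configurable relative size, and spatially structured
# areal impacts driven by known features. Every stochastic component is
# returned in a ground-truth record so downstream stages can be validated.

#' Simulation configuration
#'
#' @param n_sites Number of monitoring sites.
#' @param site_type Character vector (`"roadside"`/`"background"`) recycled to
#'   `n_sites`.
#' @param start,end Period covered by the hourly series (dates). Default span
#'   2016-01-01..2020-12-31.
#' @param T0 Intervention start date; the treatment indicator is 1 from T0 on.
#' @param true_tau Relative intervention effect per site (e.g. -0.10 for a 10%
#'   reduction); recycled to `n_sites`. Must be > -1.
#' @param trend_slope Long-term trend of log-concentration, per year.
#' @param noise_sd Hourly log-scale Gaussian noise sd.
#' @param missing_frac Fraction of hourly concentration values set missing
#'   (encoded as `NA`, never as 0).
#' @param weather_effect_scale,seasonal_scale Multipliers on the
#'   weather-transfer and site-seasonality terms (0 switches them off).
#' @param weather_seasonal_scale,weather_noise_scale Multipliers on the
#'   diurnal/annual amplitudes and AR(1) noise of the weather generator.
#' @param weather_ar AR(1) coefficient shared by the weather noise components.
#' @param ramp_days If > 0, the intervention effect ramps linearly from 0 at
#'   `T0 - ramp_days` to its full size at `T0 + ramp_days` instead of a pure
#'   step (exercises the donut design's anticipation/adaptation window).
#' @param n_areas,n_features Areal layout for the feature-attribution test bed.
#' @param domain_km Side of the square planar domain (km).
#' @param field_range_km,field_sill Exponential-covariance parameters of the
#'   spatially correlated component of areal impacts.
#' @param area_noise_sd iid noise sd on areal impacts.
#' @param area_effect_scale Multiplier on the causal feature coefficients
#'   (0 gives the null model: impact = field + noise).
#' @param seed Integer seed; together with the config it fully determines all
#'   generated output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 6,
                       site_type = c("background", "roadside"),
                       start = "2016-01-01", end = "2020-12-31",
                       T0 = "2020-03-23",
                       true_tau = -0.10,
                       trend_slope = -0.03,
                       noise_sd = 0.15,
                       missing_frac = 0.02,
                       weather_effect_scale = 1,
                       seasonal_scale = 1,
                       weather_seasonal_scale = 1,
                       weather_noise_scale = 1,
                       weather_ar = 0.9,
                       ramp_days = 0,
                       n_areas = 120,
                       n_features = 12,
                       domain_km = 40,
                       field_range_km = 8,
                       field_sill = 0.36,
                       area_noise_sd = 0.25,
                       area_effect_scale = 1,
                       seed = 1L) {
  start <- as_date_strict(start, "start"); end <- as_date_strict(end, "end")
  T0 <- as_date_strict(T0, "T0")
  assert(start < T0 && T0 < end,
         "configuration error: need start < T0 < end, got ",
         start, " / ", T0, " / ", end)
  tau <- rep_len(true_tau, n_sites)
  assert(all(tau > -1), "true_tau must be > -1")
  assert(noise_sd >= 0, "noise_sd must be >= 0")
  assert(missing_frac >= 0 && missing_frac < 1, "missing_frac must be in [0,1)")
  structure(list(
    n_sites = as.integer(n_sites),
    site_type = rep_len(site_type, n_sites),
    start = start, end = end, T0 = T0,
    true_tau = tau, trend_slope = trend_slope, noise_sd = noise_sd,
    missing_frac = missing_frac,
    weather_effect_scale = weather_effect_scale,
    seasonal_scale = seasonal_scale,
    weather_seasonal_scale = weather_seasonal_scale,
    weather_noise_scale = weather_noise_scale,
    weather_ar = weather_ar, ramp_days = ramp_days,
    n_areas = as.integer(n_areas), n_features = as.integer(n_features),
    domain_km = domain_km, field_range_km = field_range_km,
    field_sill = field_sill, area_noise_sd = area_noise_sd,
    area_effect_scale = area_effect_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-variable climatology of the weather generator: mean level, diurnal and
# annual cosine amplitudes (with peak hour / peak day of year), and marginal
# sd of the AR(1) noise. Values are plausible for a temperate coastal city.
weather_climatology <- function() {
  list(
    air_temp  = list(mean = 11,    d_amp = 3,   d_peak = 15, a_amp = 7,  a_peak = 200, sd = 1.8),
    wind_speed= list(mean = 4.5,   d_amp = 0.6, d_peak = 14, a_amp = 0.8,a_peak = 20,  sd = 1.6),
    wind_dir  = list(mean = 210,   d_amp = 0,   d_peak = 0,  a_amp = 25, a_peak = 30,  sd = 45),
    pressure  = list(mean = 1013,  d_amp = 0.5, d_peak = 10, a_amp = 4,  a_peak = 30,  sd = 7),
    rh        = list(mean = 75,    d_amp = 8,   d_peak = 4,  a_amp = 6,  a_peak = 350, sd = 9),
    rainfall  = list(mean = 0.08,  d_amp = 0,   d_peak = 0,  a_amp = 0.05, a_peak = 330, sd = 0.5),
    mo_length = list(mean = 15,    d_amp = 40,  d_peak = 2,  a_amp = 10, a_peak = 10,  sd = 80)
  )
}

#' Generate hourly weather series
#'
#' Seven weather variables (air temperature, wind speed, wind direction,
#' atmospheric pressure, relative humidity, rainfall, Monin-Obukhov length)
#' as diurnal + annual cosine cycles plus stationary AR(1) noise. Wind
#' direction is wrapped to \[0, 360), wind speed and rainfall floored at 0,
#' relative humidity clamped to \[2, 100\].
#'
#' @param config A [sim_config()].
#' @return A data frame with a `time` column (hourly, strictly increasing,
#'   timezone-naive) and one column per weather variable.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "weather"))
  time <- hour_seq(config$start, config$end)
  tf <- time_features(time, config$start)
  n <- length(time)
  clim <- weather_climatology()
  out <- data.frame(time = time)
  for (v in WEATHER_VARS) {
    p <- clim[[v]]
    seasonal <- config$weather_seasonal_scale *
      (p$d_amp * cos(2 * pi * (tf$hour - p$d_peak) / 24) +
       p$a_amp * cos(2 * pi * (tf$yday - p$a_peak) / 365.25))
    x <- p$mean + seasonal +
      ar1_series(n, config$weather_ar, p$sd * config$weather_noise_scale)
    x <- switch(v,
      wind_speed = pmax(x, 0),
      wind_dir   = x %% 360,
      rainfall   = pmax(x, 0),
      rh         = pmin(pmax(x, 2), 100),
      x)
    out[[v]] <- x
  }
  out
}

# Weather-to-log-concentration transfer function: a fixed library of
# documented nonlinear terms (fully known to the tests).
#   - dilution decreasing in wind speed: -0.35 log(1 + ws)
#   - temperature U-shape (heating emissions when cold, photochemistry/
#     boundary-layer growth when warm): quadratic around 12 C
#   - washout by rainfall, concave
#   - source-sector dependence on wind direction (peak at 240 deg)
#   - stagnation under high pressure
#   - atmospheric stability: tanh(50/L) is +1 for shallow stable layers
#     (small positive Monin-Obukhov length) and -1 for strongly convective
weather_transfer <- function(w) {
  -0.35 * log1p(w$wind_speed) +
    0.0012 * (w$air_temp - 12)^2 -
    0.05 * sqrt(w$rainfall) +
    0.15 * cos((w$wind_dir - 240) * pi / 180) +
    0.004 * (w$pressure - 1013) +
    0.002 * (w$rh - 75) +
    0.12 * tanh(50 / ifelse(w$mo_length == 0, 1e-3, w$mo_length))
}

# Site-level traffic/activity seasonality on the log scale.
site_seasonality <- function(tf) {
  0.12 * cos(2 * pi * (tf$hour - 8.5) / 24) +
    0.08 * cos(4 * pi * (tf$hour - 8.5) / 24) -
    0.12 * (tf$wday %in% c(0, 6)) +
    0.06 * cos(2 * pi * (tf$yday - 30) / 365.25)
}

# Fraction of the full intervention effect applied at time offset `days`
# from T0 (0 before, 1 after; linear ramp across +/- ramp_days if set).
effect_fraction <- function(days_from_T0, ramp_days) {
  if (ramp_days > 0) {
    pmin(pmax((days_from_T0 + ramp_days) / (2 * ramp_days), 0), 1)
  } else {
    as.numeric(days_from_T0 >= 0)
  }
}

#' Generate hourly site concentration series with known ground truth
#'
#' Log-concentration is built additively: site baseline + weather transfer +
#' site seasonality (hour-of-day, day-of-week, day-of-year) + linear trend +
#' `log(1 + true_tau)` step from T0 + iid Gaussian noise. All components are
#' stored in the returned ground-truth record.
#'
#' @param config A [sim_config()].
#' @param weather Output of [generate_weather()] (must cover the full period).
#' @return A list with `series` (named list of data frames `time`, `value`),
#'   `meta` (site id, planar km coordinates, type, true tau) and `truth`
#'   (per-site component vectors and the baseline).
#' @export
generate_site_series <- function(config, weather) {
  stopifnot(inherits(config, "sim_config"))
  assert(all(config$true_tau > -1), "true_tau must be > -1")
  time <- hour_seq(config$start, config$end)
  assert(identical(as.numeric(weather$time), as.numeric(time)),
         "weather does not cover the configured period")
  set.seed(stage_seed(config$seed, "sites"))
  tf <- time_features(time, config$start)
  n <- length(time)

  g <- config$weather_effect_scale * weather_transfer(weather)
  s <- config$seasonal_scale * site_seasonality(tf)
  trend <- config$trend_slope * tf$time_days / 365.25
  days_from_T0 <- as.numeric(as.Date(time, tz = "UTC") - config$T0)
  frac <- effect_fraction(days_from_T0, config$ramp_days)

  meta <- data.frame(
    site_id = sprintf("site%02d", seq_len(config$n_sites)),
    x_km = stats::runif(config$n_sites, 0, config$domain_km),
    y_km = stats::runif(config$n_sites, 0, config$domain_km),
    type = config$site_type,
    true_tau = config$true_tau,
    stringsAsFactors = FALSE
  )

  series <- list(); truth <- list()
  for (i in seq_len(config$n_sites)) {
    b0 <- log(ifelse(config$site_type[i] == "roadside", 45, 28)) +
      stats::rnorm(1, 0, 0.1)
    step_log <- log1p(config$true_tau[i]) * frac
    noise <- stats::rnorm(n, 0, config$noise_sd)
    value <- exp(b0 + g + s + trend + step_log + noise)
    if (config$missing_frac > 0) {
      value[stats::runif(n) < config$missing_frac] <- NA_real_
    }
    id <- meta$site_id[i]
    series[[id]] <- data.frame(time = time, value = value)
    truth[[id]] <- list(site_id = id, baseline = b0,
                        true_tau = config$true_tau[i],
                        weather_effect = g, seasonal = s, trend = trend,
                        step_log = step_log, noise = noise)
  }
  list(series = series, meta = meta, truth = truth)
}

# Draw a zero-mean Gaussian field with exponential covariance
# sill * exp(-d / range) at the given coordinates (Cholesky of the dense
# covariance; fine for the areal problem sizes used here).
exp_gaussian_field <- function(x, y, sill, range_km) {
  if (sill == 0) return(numeric(length(x)))
  d <- as.matrix(stats::dist(cbind(x, y)))
  C <- sill * exp(-d / range_km)
  L <- chol(C + diag(1e-10 * sill, nrow(C)))
  as.numeric(crossprod(L, stats::rnorm(length(x))))
}

#' Generate areal features and ground-truth areal impacts
#'
#' Features are correlated Gaussians (corr `0.35^|i-j|`). The true impact is
#' a known sparse function of the first three features plus one interaction,
#' a spatially correlated Gaussian field with exponential covariance, and iid
#' noise:
#' `impact = -4 - 1.5 f01 + 1.0 f02 - 0.8 f03 - 0.4 f01*f02 + field + noise`
#' (coefficients scaled by `area_effect_scale`).
#'
#' @param config A [sim_config()]; needs `n_areas >= 30`.
#' @return A list with `features` (data frame: area_id, x_km, y_km, feature
#'   columns f01..), `impact` (true areal impact vector) and `truth`
#'   (coefficients, causal feature names, field and noise components).
#' @export
generate_area_impacts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  assert(config$n_areas >= 30, "need n_areas >= 30")
  set.seed(stage_seed(config$seed, "areas"))
  n <- config$n_areas; p <- config$n_features
  x <- stats::runif(n, 0, config$domain_km)
  y <- stats::runif(n, 0, config$domain_km)

  rho <- 0.35
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  F <- matrix(stats::rnorm(n * p), n, p) %*% chol(S)
  colnames(F) <- sprintf("f%02d", seq_len(p))

  beta <- c(f01 = -1.5, f02 = 1.0, f03 = -0.8) * config$area_effect_scale
  inter_coef <- -0.4 * config$area_effect_scale
  field <- exp_gaussian_field(x, y, config$field_sill, config$field_range_km)
  noise <- stats::rnorm(n, 0, config$area_noise_sd)
  impact <- -4 +
    as.numeric(F[, names(beta)] %*% beta) +
    inter_coef * F[, "f01"] * F[, "f02"] +
    field + noise

  features <- data.frame(area_id = sprintf("area%03d", seq_len(n)),
                         x_km = x, y_km = y, F, stringsAsFactors = FALSE)
  list(features = features, impact = impact,
       truth = list(intercept = -4, beta = beta, inter_coef = inter_coef,
                    causal_features = c("f01", "f02", "f03"),
                    field = field, noise = noise,
                    field_range_km = config$field_range_km,
                    field_sill = config$field_sill))
}

#' Deterministic spatial covariates at arbitrary planar locations
#'
#' Simple mapping covariates shared by sites and grid cells in synthetic
#' runs: distance to the domain centre and the east coordinate.
#'
#' @param x,y Planar km coordinates.
#' @param config A [sim_config()] (for the domain size).
#' @return Data frame with `dist_center` and `east`.
#' @export
spatial_covariates <- function(x, y, config) {
  cx <- config$domain_km / 2
  data.frame(dist_center = sqrt((x - cx)^2 + (y - cx)^2), east = x)
}

#' Build a regular 1 x 1 km grid over the simulation domain
#'
#' Cells carry the deterministic spatial covariates and are assigned to the
#' nearest area centroid.
#'
#' @param config A [sim_config()].
#' @param areas Output of [generate_area_impacts()].
#' @return Data frame: `x_km`, `y_km`, covariates, `area_id`.
#' @export
make_grid <- function(config, areas) {
  ctr <- seq(0.5, config$domain_km - 0.5, by = 1)
  grid <- expand.grid(x_km = ctr, y_km = ctr)
  cov <- spatial_covariates(grid$x_km, grid$y_km, config)
  ax <- areas$features$x_km; ay <- areas$features$y_km
  nearest <- vapply(seq_len(nrow(grid)), function(i) {
    which.min((ax - grid$x_km[i])^2 + (ay - grid$y_km[i])^2)
  }, integer(1))
  cbind(grid, cov, area_id = areas$features$area_id[nearest])
}
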