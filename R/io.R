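# Plain-text interchange formats: long-format CSV for hourly data, CSV for
# tabular stage outputs, JSON for ground truth and fit reports.

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write hourly series to long-format CSV
#'
#' Columns: `timestamp` (ISO 8601), `site_id`, `variable`, `value`.
#'
#' @param x Either a weather data frame (`time` + variable columns) or a
#'   named list of site data frames (`time`, `value`).
#' @param path Output file.
#' @param variable Variable name used for site concentration series.
#' @export
write_hourly_csv <- function(x, path, variable = "no2") {
  if (is.data.frame(x)) {
    vars <- setdiff(names(x), "time")
    long <- do.call(rbind, lapply(vars, function(v)
      data.frame(timestamp = fmt_time(x$time), site_id = "met",
                 variable = v, value = x[[v]])))
  } else {
    long <- do.call(rbind, lapply(names(x), function(id)
      data.frame(timestamp = fmt_time(x[[id]]$time), site_id = id,
                 variable = variable, value = x[[id]]$value)))
  }
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format hourly CSV
#'
#' @param path File written by [write_hourly_csv()].
#' @return For a single-variable file, a named list of site data frames
#'   (`time`, `value`); for a multi-variable file, a wide data frame.
#' @export
read_hourly_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long$time <- as.POSIXct(long$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC")
  if (length(unique(long$variable)) == 1) {
    out <- lapply(split(long, long$site_id), function(d)
      data.frame(time = d$time, value = d$value))
    return(out[unique(long$site_id)])
  }
  wide <- NULL
  for (v in unique(long$variable)) {
    d <- long[long$variable == v, c("time", "value")]
    names(d)[2] <- v
    wide <- if (is.null(wide)) d else merge(wide, d, by = "time")
  }
  wide[order(wide$time), ]
}

write_daily_csv <- function(daily_list, path) {
  long <- do.call(rbind, lapply(names(daily_list), function(id)
    cbind(site_id = id, daily_list[[id]])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

read_daily_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long$date <- as.Date(long$date)
  lapply(split(long, long$site_id), function(d) {
    d <- d[order(d$date), setdiff(names(d), "site_id"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

write_changepoints_csv <- function(cps_list, path) {
  rows <- do.call(rbind, lapply(names(cps_list), function(id) {
    cp <- cps_list[[id]]$changepoints
    if (!nrow(cp)) return(NULL)
    data.frame(site_id = id, date = cp$date, type = cp$type)
  }))
  if (is.null(rows)) rows <- data.frame(site_id = character(),
                                        date = character(),
                                        type = character())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write the simulation ground-truth record as JSON
#'
#' Bulky per-hour component vectors are summarized (means); the injected
#' effects, baselines and areal coefficients are kept in full.
#'
#' @param sites Output of [generate_site_series()].
#' @param areas Output of [generate_area_impacts()] (optional).
#' @param path Output file.
#' @export
write_truth_json <- function(sites, areas = NULL, path) {
  site_truth <- lapply(sites$truth, function(tr) list(
    site_id = tr$site_id, baseline = tr$baseline, true_tau = tr$true_tau,
    mean_weather_effect = mean(tr$weather_effect),
    mean_seasonal = mean(tr$seasonal)))
  out <- list(sites = site_truth)
  if (!is.null(areas)) {
    out$areas <- list(intercept = areas$truth$intercept,
                      beta = as.list(areas$truth$beta),
                      inter_coef = areas$truth$inter_coef,
                      causal_features = areas$truth$causal_features,
                      field_range_km = areas$truth$field_range_km,
                      field_sill = areas$truth$field_sill)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
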