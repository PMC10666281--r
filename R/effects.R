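# From site-level effect estimates to counterfactual exposure.
#
# Counterfactual (without-intervention) concentrations are obtained by
# scaling observed post-T0 values by 1/(1 + tau_hat), where tau_hat is the
# central effect estimate zeroed for sites that either showed no response or
# whose effect is insignificant at the 10% level. Annual impacts are
# phi = mean(observed) - mean(counterfactual) and
# phi% = phi / mean(counterfactual). Observed (raw) concentrations, not
# normalized ones, feed the annual means: annual exposure is a real-world
# quantity, the normalized series serve only estimation.

#' Adjusted central effect estimates
#'
#' The central estimate passes through only for sites that responded and are
#' significant at the 10% level; all others are set to zero.
#'
#' @param estimates An [effect_estimate()] table (one row per site).
#' @return Named numeric vector of adjusted tau, indexed by `site_id`.
#' @export
adjust_tau <- function(estimates) {
  tau <- ifelse(estimates$response & estimates$sig10, estimates$tau, 0)
  stats::setNames(tau, estimates$site_id)
}

#' Counterfactual (without-intervention) series
#'
#' `counterfactual(t) = observed(t) / (1 + tau_hat)` for `t >= T0`, and the
#' observed value before T0.
#'
#' @param observed Data frame with `value` and either `date` or `time`.
#' @param tau_hat Adjusted relative effect (> -1).
#' @param T0 Intervention date.
#' @return Data frame of the same shape with counterfactual `value`.
#' @export
counterfactual_series <- function(observed, tau_hat, T0) {
  assert(tau_hat > -1, "tau_hat must be > -1, got ", tau_hat)
  T0 <- as_date_strict(T0, "T0")
  when <- if ("date" %in% names(observed)) as.Date(observed$date)
          else as.Date(observed$time, tz = "UTC")
  out <- observed
  post <- !is.na(when) & when >= T0
  out$value[post] <- observed$value[post] / (1 + tau_hat)
  out
}

#' Annual observed vs counterfactual impact
#'
#' @param observed,counterfactual Daily data frames `date`, `value` covering
#'   the same valid dates of `year`.
#' @param year Calendar year of the annual means.
#' @param min_coverage Minimum fraction of the year's days with valid values.
#' @param id Site or area identifier.
#' @return One-row data frame: `id`, `y_obs`, `y_counter`, `phi`
#'   (`y_obs - y_counter`, ug/m3), `phi_pct` (`phi / y_counter`).
#' @export
annual_impact <- function(observed, counterfactual, year,
                          min_coverage = 0.9, id = NA_character_) {
  in_year <- function(d) format(as.Date(d$date)) >= paste0(year, "-01-01") &
    format(as.Date(d$date)) <= paste0(year, "-12-31")
  o <- observed[in_year(observed) & !is.na(observed$value), ]
  cf <- counterfactual[in_year(counterfactual) & !is.na(counterfactual$value), ]
  shared <- intersect(format(o$date), format(cf$date))
  ndays <- if (year %% 4 == 0 && (year %% 100 != 0 || year %% 400 == 0))
    366 else 365
  assert(length(shared) >= min_coverage * ndays,
         "year ", year, " coverage ", length(shared), "/", ndays,
         " days below the configured minimum of ", min_coverage)
  y_obs <- mean(o$value[format(o$date) %in% shared])
  y_counter <- mean(cf$value[format(cf$date) %in% shared])
  assert(y_counter > 0, "counterfactual annual mean must be positive")
  data.frame(id = id, y_obs = y_obs, y_counter = y_counter,
             phi = y_obs - y_counter,
             phi_pct = (y_obs - y_counter) / y_counter,
             stringsAsFactors = FALSE)
}

#' Aggregate site effects by monitoring-location type
#'
#' Group means of tau for roadside and background sites (and, when
#' requested, the responding-only subsets), with percentile bootstrap CI95
#' over sites resampled with replacement.
#'
#' @param estimates An [effect_estimate()] table.
#' @param types Named character vector or data frame mapping `site_id` to
#'   `type`; if `estimates` already carries a `type` column it is used.
#' @param responding_only Also aggregate the responding subset per type.
#' @param n_boot Bootstrap resamples.
#' @param min_sites Groups below this size are skipped with a warning.
#' @param seed Integer seed.
#' @return Data frame: `group`, `subset`, `mean_tau`, `lo95`, `hi95`,
#'   `n_sites`.
#' @export
aggregate_sites <- function(estimates, types = NULL, responding_only = TRUE,
                            n_boot = 10000L, min_sites = 3L, seed = 1L) {
  est <- as.data.frame(estimates)
  if (!"type" %in% names(est)) {
    assert(!is.null(types), "site types required")
    if (is.data.frame(types)) {
      est$type <- types$type[match(est$site_id, types$site_id)]
    } else est$type <- unname(types[est$site_id])
  }
  subsets <- list(all = rep(TRUE, nrow(est)))
  if (responding_only) subsets$responding <- est$response

  set.seed(seed)
  rows <- list()
  for (sub in names(subsets)) {
    for (ty in unique(est$type)) {
      sel <- est$type == ty & subsets[[sub]]
      tau <- est$tau[sel]
      if (length(tau) < min_sites) {
        warning("group ", ty, "/", sub, " has ", length(tau),
                " site(s) (< ", min_sites, "); skipped")
        next
      }
      bm <- vapply(seq_len(n_boot), function(b)
        mean(sample(tau, replace = TRUE)), numeric(1))
      ci <- unname(stats::quantile(bm, c(0.025, 0.975)))
      rows[[length(rows) + 1]] <- data.frame(
        group = ty, subset = sub, mean_tau = mean(tau),
        lo95 = ci[1], hi95 = ci[2], n_sites = length(tau),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
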