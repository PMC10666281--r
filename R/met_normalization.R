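# Meteorological normalization (de-weathering).
#
# A flexible tree-ensemble model predicts hourly concentration from weather,
# seasonal variables (hour-of-day, day-of-week, day-of-year) and a time
# variable carrying the long-term trend and any intervention signal.
# Normalized concentrations are obtained by averaging model predictions over
# covariate rows resampled from the whole observed period while holding the
# time variable fixed, so weather and seasonality variation is integrated
# out but trend and intervention discontinuities are retained.

#' Specification of the concentration model
#'
#' @param predictors Predictor names: the seven weather variables, the three
#'   seasonal variables and the `time_days` trend variable. `time_days` is
#'   always a predictor and is never resampled.
#' @param tune If `TRUE`, `max_depth` and `eta` are tuned by k-fold
#'   cross-validation over `grid` with early stopping; otherwise the fixed
#'   `params`/`nrounds` are used.
#' @param grid Data frame of candidate `max_depth`/`eta` pairs.
#' @param params Fixed booster parameters used when `tune = FALSE` (and as
#'   the base for tuned fits).
#' @param nrounds Maximum boosting rounds.
#' @param early_stopping_rounds,nfold Cross-validation controls.
#' @param holdout_frac Random fraction of hours held out for the fit report.
#' @param min_days Minimum span (days) of joined hourly data.
#' @return A list of class `conc_model_spec`.
#' @export
conc_model_spec <- function(predictors = c(WEATHER_VARS, SEASONAL_VARS, "time_days"),
                            tune = TRUE,
                            grid = expand.grid(max_depth = c(3L, 5L),
                                               eta = c(0.1, 0.3)),
                            params = list(max_depth = 4L, eta = 0.1,
                                          min_child_weight = 5,
                                          subsample = 1, colsample_bytree = 1),
                            nrounds = 300L,
                            early_stopping_rounds = 20L,
                            nfold = 3L,
                            holdout_frac = 0.2,
                            min_days = 365) {
  assert("time_days" %in% predictors,
         "the time variable `time_days` must be a predictor")
  structure(list(predictors = predictors, tune = tune, grid = grid,
                 params = params, nrounds = as.integer(nrounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 nfold = as.integer(nfold), holdout_frac = holdout_frac,
                 min_days = min_days),
            class = "conc_model_spec")
}

# Inner-join concentration and weather on the hour and attach seasonal/time
# features; rows with missing outcome or predictors are dropped (no
# imputation of weather gaps).
join_training_frame <- function(conc, weather, predictors, origin = NULL) {
  d <- merge(conc, weather, by = "time", sort = TRUE)
  origin <- origin %||% as.Date(min(d$time), tz = "UTC")
  tf <- time_features(d$time, origin)
  d <- cbind(d, tf)
  keep_cols <- intersect(predictors, names(d))
  ok <- stats::complete.cases(d[, c("value", keep_cols)])
  list(data = d[ok, , drop = FALSE], origin = origin)
}

xgb_fit <- function(X, y, params, nrounds, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = c(list(objective = "reg:squarederror", nthread = 1,
                    tree_method = "hist", seed = seed), params),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Fit the hourly concentration model
#'
#' @param conc Data frame `time`, `value` (hourly concentrations, ug/m3).
#' @param weather Data frame `time` + weather variables ([generate_weather()]
#'   layout).
#' @param spec A [conc_model_spec()].
#' @param seed Integer seed (holdout split, CV folds, booster).
#' @return Object of class `conc_model`: the booster, the joined training
#'   frame, the trend-variable origin, chosen hyperparameters, and a fit
#'   report with held-out R2 and RMSE.
#' @export
fit_concentration_model <- function(conc, weather, spec = conc_model_spec(),
                                    seed = 1L) {
  jf <- join_training_frame(conc, weather, spec$predictors)
  d <- jf$data
  span <- as.numeric(difftime(max(d$time), min(d$time), units = "days"))
  assert(nrow(d) > 0 && span >= spec$min_days,
         "insufficient data: need >= ", spec$min_days,
         " days of joined hourly data, have ", round(span, 1))

  X <- as.matrix(d[, spec$predictors, drop = FALSE])
  y <- d$value
  n <- nrow(X)

  set.seed(stage_seed(seed, "holdout"))
  hold <- sample.int(n, size = max(1L, round(spec$holdout_frac * n)))
  tr <- setdiff(seq_len(n), hold)

  params <- spec$params
  nrounds <- spec$nrounds
  cv_table <- NULL
  if (isTRUE(spec$tune)) {
    cv_table <- spec$grid
    cv_table$rmse <- NA_real_; cv_table$best_iter <- NA_integer_
    for (k in seq_len(nrow(spec$grid))) {
      p <- utils::modifyList(params, as.list(spec$grid[k, , drop = FALSE]))
      set.seed(stage_seed(seed, paste0("cv", k)))
      cv <- xgboost::xgb.cv(
        params = c(list(objective = "reg:squarederror", nthread = 1,
                        tree_method = "hist", seed = seed), p),
        data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr]),
        nrounds = spec$nrounds, nfold = spec$nfold,
        early_stopping_rounds = spec$early_stopping_rounds, verbose = 0)
      cv_table$best_iter[k] <- cv$early_stop$best_iteration
      cv_table$rmse[k] <-
        cv$evaluation_log$test_rmse_mean[cv$early_stop$best_iteration]
    }
    best <- which.min(cv_table$rmse)
    params <- utils::modifyList(params,
                                as.list(spec$grid[best, , drop = FALSE]))
    nrounds <- cv_table$best_iter[best]
  }

  fit_holdout <- xgb_fit(X[tr, , drop = FALSE], y[tr], params, nrounds,
                         stage_seed(seed, "fit"))
  pred_hold <- stats::predict(fit_holdout, X[hold, , drop = FALSE])
  ss_res <- sum((y[hold] - pred_hold)^2)
  ss_tot <- sum((y[hold] - mean(y[hold]))^2)
  report <- list(r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(mean((y[hold] - pred_hold)^2)),
                 n_train = length(tr), n_holdout = length(hold),
                 params = params, nrounds = nrounds, cv = cv_table)

  booster <- xgb_fit(X, y, params, nrounds, stage_seed(seed, "fit"))
  structure(list(booster = booster, params = params, nrounds = nrounds,
                 predictors = spec$predictors, origin = jf$origin,
                 time = d$time, X = X, y = y,
                 pred_obs = stats::predict(booster, X),
                 report = report, spec = spec, seed = seed),
            class = "conc_model")
}

#' @export
print.conc_model <- function(x, ...) {
  cat("Hourly concentration model (gradient-boosted trees)\n",
      "  rows: ", nrow(x$X), "  predictors: ", length(x$predictors), "\n",
      "  held-out R2: ", round(x$report$r2, 3),
      "  RMSE: ", round(x$report$rmse, 3), "\n", sep = "")
  invisible(x)
}

#' Weather/seasonality-normalize an hourly series
#'
#' For each timestamp, `n_resamples` complete covariate rows (weather and
#' seasonal variables jointly) are drawn uniformly with replacement from the
#' observed period while the time variable keeps its value at that timestamp;
#' the normalized value is the mean model prediction over the draws, plus —
#' when `add_residual` — the observed-minus-fitted residual, which preserves
#' abrupt deviations that the time variable under-fits.
#'
#' @param model A fitted [fit_concentration_model()] object.
#' @param n_resamples Number of covariate draws per timestamp (>= 1).
#' @param seed Integer seed.
#' @param add_residual Add back the observed-minus-fitted residual
#'   (default `TRUE`).
#' @return Data frame `time`, `value` (normalized ug/m3), with attributes
#'   `mc_se` (per-hour Monte Carlo standard error of the resampling mean)
#'   and `resample_mean` (the mean-prediction component alone).
#' @export
normalize_series <- function(model, n_resamples = 200L, seed = 1L,
                             add_residual = TRUE) {
  stopifnot(inherits(model, "conc_model"))
  assert(n_resamples >= 1, "n_resamples must be >= 1")
  X <- model$X
  n <- nrow(X)
  cov_cols <- setdiff(model$predictors, "time_days")
  time_col <- X[, "time_days"]

  set.seed(seed)
  acc <- numeric(n); acc2 <- numeric(n)
  Xj <- X
  for (j in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xj[, cov_cols] <- X[idx, cov_cols]
    # the trend variable is never resampled
    stopifnot(identical(Xj[, "time_days"], time_col))
    pj <- stats::predict(model$booster, Xj)
    acc <- acc + pj
    acc2 <- acc2 + pj^2
  }
  m <- acc / n_resamples
  mc_var <- pmax(acc2 / n_resamples - m^2, 0) / max(n_resamples - 1, 1)
  out <- data.frame(time = model$time, value = m)
  if (add_residual) out$value <- out$value + (model$y - model$pred_obs)
  attr(out, "mc_se") <- sqrt(mc_var)
  attr(out, "resample_mean") <- m
  out
}

#' Daily averages of an hourly series
#'
#' @param hourly Data frame `time`, `value`.
#' @param min_hours Minimum number of valid (non-missing) hours for a day to
#'   be emitted.
#' @return Data frame `date`, `value`, `n_hours`; days failing `min_hours`
#'   are dropped.
#' @export
daily_average <- function(hourly, min_hours = 18L) {
  if (nrow(hourly) == 0 || all(is.na(hourly$value))) {
    warning("empty input: no valid hours to average")
    return(data.frame(date = as.Date(character()), value = numeric(),
                      n_hours = integer()))
  }
  ok <- !is.na(hourly$value)
  key <- format(as.Date(hourly$time[ok], tz = "UTC"))  # ISO sorts chronologically
  v <- hourly$value[ok]
  means <- tapply(v, key, mean)
  agg <- data.frame(
    date = as.Date(names(means)),
    value = as.numeric(means),
    n_hours = as.integer(tapply(v, key, length))
  )
  rownames(agg) <- NULL
  agg[agg$n_hours >= min_hours, , drop = FALSE]
}

#' Normalization uncertainty by bootstrap refitting
#'
#' Refits the concentration model on bootstrap resamples of the training
#' hours, normalizes under each refit, and summarizes the per-day spread as
#' a percentile band. Downstream, effect estimates whose sign is not stable
#' across refits can be flagged.
#'
#' @param conc,weather,spec,seed As [fit_concentration_model()].
#' @param n_boot Number of bootstrap refits (>= 2).
#' @param n_resamples Covariate draws per refit.
#' @param level Band level (default 0.95).
#' @param min_hours Daily validity threshold.
#' @return List: `dates`, `lower`, `upper`, `level` and the `boot` matrix
#'   (day x refit) of normalized daily values.
#' @export
normalization_uncertainty <- function(conc, weather, spec = conc_model_spec(),
                                      n_boot = 20L, n_resamples = 50L,
                                      level = 0.95, min_hours = 18L,
                                      seed = 1L) {
  assert(n_boot >= 2, "n_boot must be >= 2")
  base <- fit_concentration_model(conc, weather, spec, seed = seed)
  n <- nrow(base$X)
  cols <- list()
  for (b in seq_len(n_boot)) {
    set.seed(stage_seed(seed, paste0("boot", b)))
    idx <- sort(sample.int(n, n, replace = TRUE))
    fit_b <- base
    fit_b$booster <- xgb_fit(base$X[idx, , drop = FALSE], base$y[idx],
                             base$params, base$nrounds,
                             stage_seed(seed, paste0("bfit", b)))
    fit_b$pred_obs <- stats::predict(fit_b$booster, base$X)
    norm_b <- normalize_series(fit_b, n_resamples = n_resamples,
                               seed = stage_seed(seed, paste0("bnorm", b)))
    cols[[b]] <- daily_average(norm_b, min_hours)
  }
  dates <- cols[[1]]$date
  M <- vapply(cols, function(d) d$value[match(dates, d$date)],
              numeric(length(dates)))
  a <- (1 - level) / 2
  list(dates = dates,
       lower = apply(M, 1, stats::quantile, probs = a, na.rm = TRUE),
       upper = apply(M, 1, stats::quantile, probs = 1 - a, na.rm = TRUE),
       level = level, boot = M)
}
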