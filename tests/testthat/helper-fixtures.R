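# Shared fixtures: all synthetic, generated at test time.

# Two-year single-site configuration used throughout the suite.
study_sim <- function(seed, true_tau = -0.10, ...) {
  args <- utils::modifyList(
    list(n_sites = 1, start = "2019-01-01", end = "2020-12-31",
         T0 = "2020-03-23", true_tau = true_tau, seed = seed),
    list(...))
  do.call(sim_config, args)
}

T0_STUDY <- as.Date("2020-03-23")

# One fully generated site: weather + concentration series + truth.
gen_site <- function(seed, true_tau = -0.10, ...) {
  cfg <- study_sim(seed, true_tau, ...)
  w <- generate_weather(cfg)
  s <- generate_site_series(cfg, w)
  list(cfg = cfg, weather = w, conc = s$series$site01,
       truth = s$truth$site01, meta = s$meta)
}

# Small untuned model spec for unit tests.
fast_spec <- function(nrounds = 100L, eta = 0.3) {
  conc_model_spec(tune = FALSE,
                  params = list(max_depth = 4L, eta = eta,
                                min_child_weight = 5, subsample = 1,
                                colsample_bytree = 1),
                  nrounds = nrounds)
}

# Daily series builder (values on consecutive dates).
make_daily <- function(values, start = "2020-01-01") {
  data.frame(date = as.Date(start) + seq_along(values) - 1, value = values)
}

# Exhaustive minimum of the penalized piecewise-linear segmentation cost:
# enumerates every admissible segmentation recursively. Independent of the
# dynamic program it validates.
brute_force_segmentation_cost <- function(series, penalty, min_seg_len) {
  y <- series$value
  t <- as.numeric(series$date - series$date[1])
  t <- t - mean(t); y <- y - mean(y)
  seg_rss <- function(a, b) {
    idx <- a:b
    sum(stats::lm.fit(cbind(1, t[idx]), y[idx])$residuals^2)
  }
  n <- length(y)
  best <- function(j) {
    if (j == 0) return(-penalty)
    out <- Inf
    for (i in c(0, seq_len(j - min_seg_len))) {
      if (i != 0 && i < min_seg_len) next
      if (j - i < min_seg_len) next
      out <- min(out, best(i) + seg_rss(i + 1, j) + penalty)
    }
    out
  }
  best(n)
}

# Build a minimal impact_model around a hand-fit booster (for stump and
# oracle tests that need full control of the trees).
manual_impact_model <- function(X, y, max_depth, nrounds, eta = 1,
                                seed = 1L) {
  booster <- rddair:::xgb_fit(
    X, y, list(max_depth = max_depth, eta = eta, min_child_weight = 1,
               subsample = 1, colsample_bytree = 1),
    nrounds, seed)
  structure(list(booster = booster, X = X, feature_names = colnames(X),
                 target = y, params = list(), nrounds = nrounds,
                 dropped = character(0), cv_report = list()),
            class = "impact_model")
}

# Small but complete end-to-end pipeline configuration.
small_pipeline_config <- function(out_dir, master_seed = 1L, n_sites = 6L) {
  taus <- rep(c(-0.25, -0.10, 0), length.out = n_sites)
  pipeline_config(
    out_dir = out_dir,
    sim = sim_config(n_sites = n_sites,
                     site_type = if (n_sites >= 6)
                       rep(c("background", "roadside"),
                           each = ceiling(n_sites / 2),
                           length.out = n_sites)
                     else "background",
                     start = "2019-01-01", end = "2020-12-31",
                     true_tau = taus,
                     n_areas = 60, domain_km = 20, seed = 1),
    appraise = appraise_config_study(n_draws = 2000L, n_norm_boot = 4L),
    n_boot = 2000L,
    tuning = attribution_tuning(grid = expand.grid(max_depth = 2L,
                                                   eta = 0.1),
                                nrounds = 80, nfold = 3),
    master_seed = master_seed)
}
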