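# End-to-end orchestration: simulate -> normalize -> changepoint -> rdd ->
# effects -> mapping -> attribution, with stage-derived seeds, persisted CSV
# outputs per stage and a JSON run manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param sim A [sim_config()] (defines the synthetic inputs, the
#'   intervention date T0 and the master period).
#' @param appraise An [appraise_config()] (normalization, change-point, RDD
#'   and Monte Carlo settings; the margin half-width `hw` is per-pollutant
#'   in multi-pollutant use).
#' @param pollutant Label carried through the outputs.
#' @param n_boot Bootstrap resamples for site aggregation.
#' @param tuning An [attribution_tuning()].
#' @param master_seed Master seed; every stochastic stage derives its own
#'   seed from it via [stage_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("rddair_run_"),
                            sim = sim_config(),
                            appraise = appraise_config(),
                            pollutant = "no2",
                            n_boot = 10000L,
                            tuning = attribution_tuning(),
                            master_seed = 1L) {
  assert(inherits(sim, "sim_config"), "sim must be a sim_config",
         class = "rddair_config_error")
  assert(inherits(appraise, "appraise_config"),
         "appraise must be an appraise_config",
         class = "rddair_config_error")
  structure(list(out_dir = out_dir, sim = sim, appraise = appraise,
                 pollutant = pollutant, n_boot = as.integer(n_boot),
                 tuning = tuning, master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `out_dir`, `pollutant`, `n_boot`, `master_seed` plus
#' nested `sim`, `appraise` and `tuning` blocks holding the arguments of
#' [sim_config()], [appraise_config()] and [attribution_tuning()]. Unknown
#' keys are a configuration error.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "pollutant", "n_boot", "master_seed",
             "sim", "appraise", "tuning")
  bad <- setdiff(names(y), known)
  assert(!length(bad), "unknown configuration keys: ",
         paste(bad, collapse = ", "), class = "rddair_config_error")
  args <- y[intersect(names(y), c("out_dir", "pollutant", "n_boot",
                                  "master_seed"))]
  check_args <- function(given, fn, block) {
    bad <- setdiff(names(given), names(formals(fn)))
    assert(!length(bad), "unknown ", block, " keys: ",
           paste(bad, collapse = ", "), class = "rddair_config_error")
    given
  }
  if (!is.null(y$sim))
    args$sim <- do.call(sim_config, check_args(y$sim, sim_config, "sim"))
  if (!is.null(y$appraise))
    args$appraise <- do.call(appraise_config,
                             check_args(y$appraise, appraise_config,
                                        "appraise"))
  if (!is.null(y$tuning))
    args$tuning <- do.call(attribution_tuning,
                           check_args(y$tuning, attribution_tuning,
                                      "tuning"))
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  stripped <- unclass(config)
  stripped$out_dir <- NULL
  saveRDS(stripped, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes all seven stages on synthetic inputs, writes every stage output
#' as CSV/JSON under `config$out_dir`, and returns the in-memory results
#' plus a manifest (config hash, stage seeds and timings).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `estimates`, `aggregates`, `annual`,
#'   `mapping`, `attribution`, `manifest` and the per-site appraisal
#'   details.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stages <- character(0); timings <- numeric(0)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- with_stage(name, expr)
    stages <<- c(stages, name)
    timings <<- c(timings, proc.time()[["elapsed"]] - t0)
    say("stage ", name, " done")
    out
  }
  ms <- config$master_seed
  T0 <- config$sim$T0
  outfile <- function(name) file.path(config$out_dir, name)

  sim <- timed("simulate", {
    sc <- config$sim
    sc$seed <- stage_seed(ms, "simulate")
    weather <- generate_weather(sc)
    sites <- generate_site_series(sc, weather)
    areas <- generate_area_impacts(sc)
    grid <- make_grid(sc, areas)
    write_hourly_csv(weather, outfile("weather_hourly.csv"))
    write_hourly_csv(sites$series, outfile("conc_hourly.csv"),
                     variable = config$pollutant)
    write_table_csv(sites$meta, outfile("site_meta.csv"))
    write_table_csv(areas$features, outfile("area_features.csv"))
    write_truth_json(sites, areas, outfile("ground_truth.json"))
    list(weather = weather, sites = sites, areas = areas, grid = grid,
         sc = sc)
  })

  appr <- timed("normalize", {
    out <- list()
    for (id in sim$sites$meta$site_id) {
      out[[id]] <- appraise_site(
        sim$sites$series[[id]], sim$weather, T0, config$appraise,
        seed = stage_seed(ms, paste0("site_", id)),
        site_id = id, pollutant = config$pollutant)
    }
    write_daily_csv(lapply(out, `[[`, "daily"),
                    outfile("normalized_daily.csv"))
    out
  })

  timed("changepoint", {
    write_changepoints_csv(lapply(appr, `[[`, "changepoints"),
                           outfile("changepoints.csv"))
    rp <- do.call(rbind, lapply(names(appr), function(id) {
      w <- appr[[id]]$research_period
      if (is.null(w)) return(NULL)
      data.frame(site_id = id, start = w$start, end = w$end)
    }))
    if (is.null(rp)) rp <- data.frame(site_id = character(),
                                      start = character(),
                                      end = character())
    write_table_csv(rp, outfile("research_periods.csv"))
  })

  estimates <- timed("rdd", {
    est <- do.call(rbind, lapply(appr, `[[`, "estimate"))
    rownames(est) <- NULL
    write_table_csv(est, outfile("effect_estimates.csv"))
    est
  })

  eff <- timed("effects", {
    tau_hat <- adjust_tau(estimates)
    year <- as.integer(format(T0, "%Y"))
    daily_obs <- lapply(sim$sites$series, daily_average,
                        min_hours = config$appraise$min_hours)
    annual <- do.call(rbind, lapply(names(daily_obs), function(id) {
      cf <- counterfactual_series(daily_obs[[id]], tau_hat[[id]], T0)
      annual_impact(daily_obs[[id]], cf, year, id = id)
    }))
    agg <- aggregate_sites(estimates, types = sim$sites$meta,
                           n_boot = config$n_boot,
                           seed = stage_seed(ms, "aggregate"))
    write_table_csv(annual, outfile("annual_impacts.csv"))
    write_table_csv(agg, outfile("aggregate_effects.csv"))
    list(annual = annual, aggregates = agg, tau_hat = tau_hat)
  })

  mapping <- timed("mapping", {
    meta <- sim$sites$meta
    si <- eff$annual[match(meta$site_id, eff$annual$id), ]
    site_impacts <- data.frame(site_id = meta$site_id,
                               x_km = meta$x_km, y_km = meta$y_km,
                               phi = si$phi, phi_pct = si$phi_pct)
    # a single mapping covariate keeps the regression well-posed for
    # small monitoring networks (>= p + 5 sites required)
    site_cov <- spatial_covariates(meta$x_km, meta$y_km,
                                   sim$sc)[, "dist_center", drop = FALSE]
    m <- map_impacts(site_impacts, site_cov, sim$grid,
                     expected_areas = sim$areas$features$area_id)
    write_table_csv(m$grid, outfile("impact_grid.csv"))
    write_table_csv(m$areal, outfile("impact_areal.csv"))
    m
  })

  attribution <- timed("attribution", {
    feats <- sim$areas$features
    areal <- mapping$areal[match(feats$area_id, mapping$areal$area_id), ]
    out <- list()
    for (target in c("phi", "phi_pct")) {
      model <- fit_impact_model(feats, areal[[target]], config$tuning,
                                seed = stage_seed(ms, paste0("gbdt_",
                                                             target)))
      expl <- shap_values(model)
      imp <- global_importance(expl)
      gain <- total_gain_importance(model, imp)
      tab <- imp$table
      tab$total_gain <- gain$table$total_gain[match(tab$feature,
                                                    gain$table$feature)]
      write_table_csv(cbind(area_id = feats$area_id,
                            as.data.frame(expl$phi)),
                      outfile(paste0("shap_", target, ".csv")))
      write_table_csv(tab, outfile(paste0("importance_", target, ".csv")))
      out[[target]] <- list(model = model, explanation = expl,
                            importance = imp, gain = gain)
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rddair")),
    config_hash = config_hash(config),
    master_seed = ms,
    stages = stages,
    stage_seconds = as.list(stats::setNames(round(timings, 2), stages)),
    n_sites = config$sim$n_sites,
    T0 = format(T0)
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(estimates = estimates, aggregates = eff$aggregates,
                 annual = eff$annual, tau_hat = eff$tau_hat,
                 mapping = mapping, attribution = attribution,
                 appraisals = appr, manifest = manifest,
                 out_dir = config$out_dir))
}
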