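# Residual kriging: interpolation of site-level impacts as a linear
# regression on spatial covariates plus ordinary kriging of its residuals.
# Coordinates are planar kilometres throughout; no geodesy.

#' Linear mapping regression
#'
#' @param impacts Numeric site-level impact values.
#' @param covariates Data frame of spatial covariates at the sites.
#' @return List: `fit` (lm), `residuals`, `coef`.
#' @export
fit_mapping_regression <- function(impacts, covariates) {
  p <- ncol(covariates)
  assert(length(impacts) >= p + 5,
         "need at least p + 5 = ", p + 5, " sites for ", p, " covariates")
  d <- cbind(y = impacts, covariates)
  fit <- stats::lm(y ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_rddair("rank-deficient mapping design; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  list(fit = fit, residuals = unname(stats::residuals(fit)),
       coef = stats::coef(fit))
}

vgm_curve <- function(h, nugget, psill, range_km, model) {
  g <- switch(model,
    exponential = 1 - exp(-h / range_km),
    spherical = ifelse(h >= range_km, 1,
                       1.5 * h / range_km - 0.5 * (h / range_km)^3),
    stop_rddair("unknown variogram model: ", model))
  out <- nugget + psill * g
  out[h == 0] <- 0   # semivariance is 0 at zero lag by convention
  out
}

#' Fit a variogram model to residuals
#'
#' Method-of-moments empirical semivariogram on distance bins, then a
#' weighted least-squares fit of the chosen family with weights equal to
#' the pair counts.
#'
#' @param residuals Numeric residuals at the sites.
#' @param coords Two-column matrix/data frame of planar km coordinates.
#' @param model `"exponential"` (default) or `"spherical"`;
#'   `gamma(h) = nugget + psill * (1 - exp(-h/range))` for the exponential.
#' @param n_bins Number of distance bins.
#' @param max_dist Maximum pair distance used (default: a third of the
#'   maximum pairwise distance, where exponential structure is
#'   identifiable; long lags mostly add trend leakage).
#' @return Object of class `variogram_model`: `nugget`, `psill`, `range_km`,
#'   `model`, `empirical` (bin table), `sill`.
#' @export
fit_variogram <- function(residuals, coords, model = "exponential",
                          n_bins = 15L, max_dist = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  assert(n >= 10, "need >= 10 points to fit a variogram, have ", n)
  D <- as.matrix(stats::dist(coords))
  dv <- D[lower.tri(D)]
  assert(stats::sd(dv) > 0 || length(unique(dv)) > 1,
         "all pairwise distances identical; variogram undefined")
  G <- outer(residuals, residuals, function(a, b) (a - b)^2) / 2
  gv <- G[lower.tri(G)]
  max_dist <- max_dist %||% (max(dv) / 3)
  use <- dv <= max_dist & dv > 0
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dv[use], breaks, include.lowest = TRUE)
  emp <- data.frame(
    dist = as.numeric(tapply(dv[use], bin, mean)),
    gamma = as.numeric(tapply(gv[use], bin, mean)),
    n_pairs = as.integer(table(bin))
  )
  emp <- emp[emp$n_pairs > 0 & !is.na(emp$dist), ]

  s2 <- stats::var(residuals)
  if (s2 == 0) {
    return(structure(list(nugget = 0, psill = 0,
                          range_km = max_dist / 3, model = model,
                          empirical = emp, sill = 0),
                     class = "variogram_model"))
  }
  obj <- function(par) {
    g <- vgm_curve(emp$dist, par[1], par[2], par[3], model)
    sum(emp$n_pairs * (emp$gamma - g)^2)
  }
  starts <- list(c(0.1 * s2, 0.9 * s2, max_dist / 4),
                 c(0.5 * s2, 0.5 * s2, max_dist / 10),
                 c(0.9 * s2, 0.1 * s2, max_dist / 2))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "L-BFGS-B",
                      lower = c(0, 0, 1e-3),
                      upper = c(3 * s2, 3 * s2, 1.5 * max_dist))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(nugget = best$par[1], psill = best$par[2],
                 range_km = best$par[3], model = model, empirical = emp,
                 sill = best$par[1] + best$par[2]),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(x$model, "variogram: nugget", signif(x$nugget, 4),
      " partial sill", signif(x$psill, 4),
      " range", signif(x$range_km, 4), "km\n")
  invisible(x)
}

#' Ordinary kriging of residuals
#'
#' Solves the ordinary-kriging system (unit-sum weights enforced with a
#' Lagrange multiplier) per target; exact at data locations when the nugget
#' is zero.
#'
#' @param residuals Residual values at the data sites.
#' @param coords Data-site coordinates (planar km, two columns).
#' @param vgm A [fit_variogram()] model.
#' @param targets Target coordinates (two columns).
#' @return List: `pred`, `var` (kriging variance, >= 0), `weights`
#'   (target x site matrix).
#' @export
krige <- function(residuals, coords, vgm, targets) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  if (any(D[lower.tri(D)] < 1e-9)) {
    idx <- which(D < 1e-9 & lower.tri(D), arr.ind = TRUE)[1, ]
    stop_rddair("duplicate coordinates make the kriging matrix singular ",
                "(sites ", idx[2], " and ", idx[1], ")")
  }
  if ((vgm$nugget + vgm$psill) <= 1e-12) {
    # degenerate variogram (constant residuals): every site is equally
    # informative and the surface is flat
    m <- nrow(targets)
    return(list(pred = rep(mean(residuals), m), var = rep(0, m),
                weights = matrix(1 / n, m, n)))
  }
  G <- vgm_curve(D, vgm$nugget, vgm$psill, vgm$range_km, vgm$model)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ai <- solve(A)

  dx <- outer(targets[, 1], coords[, 1], "-")
  dy <- outer(targets[, 2], coords[, 2], "-")
  H <- sqrt(dx^2 + dy^2)
  G0 <- vgm_curve(H, vgm$nugget, vgm$psill, vgm$range_km, vgm$model)
  B <- cbind(G0, 1)                 # targets x (n + 1)
  sol <- B %*% t(Ai)                # weights + multiplier per target
  W <- sol[, seq_len(n), drop = FALSE]
  mu <- sol[, n + 1]
  pred <- as.numeric(W %*% residuals)
  v <- pmax(rowSums(W * G0) + mu, 0)
  list(pred = pred, var = as.numeric(v), weights = W)
}

#' Map site impacts to a grid and areal units
#'
#' Cell prediction = mapping-regression prediction + ordinary-kriged
#' residual; areal value = unweighted mean over the cells assigned to the
#' area. `phi` and `phi_pct` are mapped independently.
#'
#' @param site_impacts Data frame `site_id`, `x_km`, `y_km` plus impact
#'   columns (default `phi`, `phi_pct`).
#' @param site_covariates Data frame of covariates at the sites (same row
#'   order).
#' @param grid Data frame `x_km`, `y_km`, the same covariate columns, and
#'   `area_id`.
#' @param impact_cols Impact columns to map.
#' @param vgm_args Extra arguments for [fit_variogram()].
#' @param expected_areas Optional vector of area ids that must all receive
#'   at least one grid cell.
#' @return List: `grid` (cell predictions and kriging variances per impact),
#'   `areal` (area means), `models` (per-impact regression + variogram).
#' @export
map_impacts <- function(site_impacts, site_covariates, grid,
                        impact_cols = c("phi", "phi_pct"),
                        vgm_args = list(), expected_areas = NULL) {
  assert(all(c("x_km", "y_km", "area_id") %in% names(grid)),
         "grid needs x_km, y_km and area_id columns")
  if (!is.null(expected_areas)) {
    missing_areas <- setdiff(expected_areas, grid$area_id)
    assert(!length(missing_areas), "area with zero assigned cells: ",
           paste(utils::head(missing_areas, 5), collapse = ", "))
  }
  cov_cols <- names(site_covariates)
  assert(all(cov_cols %in% names(grid)),
         "grid lacks covariate columns: ",
         paste(setdiff(cov_cols, names(grid)), collapse = ", "))
  coords <- as.matrix(site_impacts[, c("x_km", "y_km")])
  targets <- as.matrix(grid[, c("x_km", "y_km")])

  out_grid <- grid[, c("x_km", "y_km", "area_id")]
  models <- list()
  for (col in impact_cols) {
    reg <- fit_mapping_regression(site_impacts[[col]], site_covariates)
    trend <- stats::predict(reg$fit,
                            newdata = grid[, cov_cols, drop = FALSE])
    if (nrow(coords) < 10) {
      # too few sites to estimate spatial structure: pure-nugget model,
      # i.e. the kriged residual surface is the global residual mean
      vgm <- structure(list(nugget = stats::var(reg$residuals), psill = 0,
                            range_km = 1, model = "exponential",
                            empirical = NULL,
                            sill = stats::var(reg$residuals),
                            note = "fewer than 10 sites: pure-nugget model"),
                       class = "variogram_model")
    } else {
      vgm <- do.call(fit_variogram,
                     c(list(reg$residuals, coords), vgm_args))
    }
    kr <- krige(reg$residuals, coords, vgm, targets)
    out_grid[[col]] <- as.numeric(trend) + kr$pred
    out_grid[[paste0(col, "_var")]] <- kr$var
    models[[col]] <- list(regression = reg, variogram = vgm)
  }
  areal <- do.call(rbind, lapply(split(out_grid, out_grid$area_id),
    function(g) {
      row <- data.frame(area_id = g$area_id[1], n_cells = nrow(g))
      for (col in impact_cols) row[[col]] <- mean(g[[col]])
      row
    }))
  rownames(areal) <- NULL
  list(grid = out_grid, areal = areal, models = models)
}
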