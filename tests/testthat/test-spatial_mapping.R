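test_that("mapping regression reproduces hand-solved normal equations", {
  set.seed(61)
  x <- rnorm(8)
  y <- 2 - 1.5 * x + rnorm(8, 0, 0.3)
  reg <- fit_mapping_regression(y, data.frame(cov = x))
  X <- cbind(1, x)
  beta_hand <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(reg$coef), as.numeric(beta_hand), tolerance = 1e-10)

  # exactly linear impacts leave zero residuals
  reg2 <- fit_mapping_regression(2 + 3 * x, data.frame(cov = x))
  expect_equal(reg2$residuals, rep(0, 8), tolerance = 1e-10)

  # intercept-only model centres the impacts
  reg3 <- fit_mapping_regression(y, data.frame(one = rep(1, 8))[, 0,
                                                               drop = FALSE])
  expect_equal(reg3$residuals, unname(y - mean(y)), tolerance = 1e-10)

  expect_error(fit_mapping_regression(y[1:5], data.frame(cov = x[1:5])),
               "p \\+ 5")
  expect_error(fit_mapping_regression(y, data.frame(a = x, b = 2 * x)),
               "collinear")
})

test_that("variograms separate nugget noise from structured fields", {
  set.seed(62)
  n <- 500
  xy <- cbind(runif(n, 0, 40), runif(n, 0, 40))

  # iid residuals: essentially pure nugget
  v_iid <- fit_variogram(rnorm(n), xy)
  expect_gt(v_iid$nugget / v_iid$sill, 0.6)

  # constant residuals: zero sill
  v_const <- fit_variogram(rep(1.3, 12), xy[1:12, ])
  expect_equal(v_const$sill, 0)

  expect_error(fit_variogram(rnorm(5), xy[1:5, ]), ">= 10")
})

test_that("known exponential-field range is recovered within factor 2", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_areas = 500, field_range_km = 8, field_sill = 1,
                      area_noise_sd = 0, area_effect_scale = 0, seed = seed)
    ar <- generate_area_impacts(cfg)
    v <- fit_variogram(ar$truth$field,
                       ar$features[, c("x_km", "y_km")])
    if (v$range_km > 4 && v$range_km < 16) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("ordinary kriging weights equal the direct augmented solve", {
  coords <- cbind(c(0, 3, 5, 7, 10), c(0, 4, 1, 8, 2))
  z <- c(1.2, 0.4, -0.8, 2.1, 0.3)
  vgm <- structure(list(nugget = 0.1, psill = 1.2, range_km = 4,
                        model = "exponential", sill = 1.3),
                   class = "variogram_model")
  targets <- cbind(c(2, 6, 9), c(2, 5, 5))
  kr <- krige(z, coords, vgm, targets)

  gam <- function(h) ifelse(h == 0, 0, 0.1 + 1.2 * (1 - exp(-h / 4)))
  D <- as.matrix(dist(coords))
  A <- rbind(cbind(gam(D), 1), c(rep(1, 5), 0))
  for (k in 1:3) {
    h0 <- sqrt(colSums((t(coords) - targets[k, ])^2))
    sol <- unname(solve(A, c(gam(h0), 1)))
    expect_equal(unname(kr$weights[k, ]), sol[1:5], tolerance = 1e-10)
    expect_equal(kr$pred[k], sum(sol[1:5] * z), tolerance = 1e-10)
    expect_equal(kr$var[k], sum(sol[1:5] * gam(h0)) + sol[6],
                 tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(kr$weights)), rep(1, 3), tolerance = 1e-10)
})

test_that("kriging is exact at data sites and rejects duplicates", {
  coords <- cbind(c(0, 3, 5, 7, 10), c(0, 4, 1, 8, 2))
  z <- c(1.2, 0.4, -0.8, 2.1, 0.3)
  vgm <- structure(list(nugget = 0, psill = 1, range_km = 5,
                        model = "exponential", sill = 1),
                   class = "variogram_model")
  kr <- krige(z, coords, vgm, coords)
  expect_equal(kr$pred, z, tolerance = 1e-8)
  expect_equal(kr$var, rep(0, 5), tolerance = 1e-8)

  # on a 1-D transect between two sites, variance grows monotonically
  # with distance to the nearest site
  c2 <- cbind(c(0, 20), c(0, 0))
  tr <- cbind(seq(0, 10, by = 0.5), 0)
  kr2 <- krige(z[1:2], c2, vgm, tr)
  expect_true(all(diff(kr2$var) >= -1e-9))
  expect_equal(kr2$var[1], 0, tolerance = 1e-8)

  expect_error(krige(z, rbind(coords[1:4, ], coords[1, ]), vgm,
                     cbind(1, 1)), "duplicate")
})

test_that("mapped surfaces decompose into trend plus kriged residual", {
  set.seed(64)
  cfg <- sim_config(n_areas = 40, seed = 64, domain_km = 20)
  ar <- generate_area_impacts(cfg)
  grid <- make_grid(cfg, ar)
  n_sites <- 25
  sx <- runif(n_sites, 0, 20); sy <- runif(n_sites, 0, 20)
  cov_s <- spatial_covariates(sx, sy, cfg)
  si <- data.frame(site_id = paste0("s", 1:n_sites), x_km = sx, y_km = sy,
                   phi = -3 + 0.1 * cov_s$dist_center +
                     0.05 * cov_s$east + rnorm(n_sites, 0, 0.3),
                   phi_pct = -0.1 + 0.004 * cov_s$dist_center +
                     rnorm(n_sites, 0, 0.01))
  m <- map_impacts(si, cov_s, grid)

  trend <- predict(m$models$phi$regression$fit,
                   newdata = grid[, c("dist_center", "east")])
  kr <- krige(m$models$phi$regression$residuals, cbind(sx, sy),
              m$models$phi$variogram, as.matrix(grid[, c("x_km", "y_km")]))
  expect_equal(m$grid$phi, as.numeric(trend) + kr$pred, tolerance = 1e-10)

  # areal values are unweighted cell means; one area over all cells
  # collapses to the grid mean
  a1 <- m$areal[m$areal$area_id == m$areal$area_id[1], ]
  cells <- m$grid[m$grid$area_id == a1$area_id, ]
  expect_equal(a1$phi, mean(cells$phi), tolerance = 1e-12)
  g2 <- grid; g2$area_id <- "all"
  m2 <- map_impacts(si, cov_s, g2)
  expect_equal(m2$areal$phi, mean(m2$grid$phi), tolerance = 1e-12)

  # constant site impacts map to a constant surface
  si3 <- si; si3$phi <- -2; si3$phi_pct <- -0.05
  m3 <- map_impacts(si3, cov_s, grid)
  expect_equal(unique(round(m3$grid$phi, 9)), -2)
})

test_that("residual kriging beats regression-only mapping on structured fields", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    cfg <- sim_config(n_areas = 60, seed = seed, domain_km = 30,
                      field_range_km = 8, field_sill = 1)
    ar <- generate_area_impacts(cfg)
    grid <- make_grid(cfg, ar)

    # truth on sites and cells: linear trend in covariates + one shared
    # smooth exponential field evaluated at both supports
    n_sites <- 40
    sx <- runif(n_sites, 0, 30); sy <- runif(n_sites, 0, 30)
    all_x <- c(sx, grid$x_km); all_y <- c(sy, grid$y_km)
    fld <- rddair:::exp_gaussian_field(all_x, all_y, 1, 8)
    cov_s <- spatial_covariates(sx, sy, cfg)
    truth_sites <- -3 + 0.15 * cov_s$dist_center + fld[1:n_sites]
    truth_cells <- -3 + 0.15 * grid$dist_center +
      fld[(n_sites + 1):length(fld)]

    si <- data.frame(site_id = paste0("s", 1:n_sites), x_km = sx,
                     y_km = sy, phi = truth_sites)
    m <- map_impacts(si, cov_s, grid, impact_cols = "phi")
    reg_only <- predict(m$models$phi$regression$fit,
                        newdata = grid[, c("dist_center", "east")])
    rmse <- function(v) sqrt(mean((v - truth_cells)^2))
    if (rmse(m$grid$phi) < rmse(as.numeric(reg_only))) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("areas with zero assigned cells are an error", {
  cfg <- sim_config(n_areas = 30, seed = 3, domain_km = 10)
  ar <- generate_area_impacts(cfg)
  grid <- make_grid(cfg, ar)
  si <- data.frame(site_id = paste0("s", 1:8),
                   x_km = runif(8, 0, 10), y_km = runif(8, 0, 10),
                   phi = rnorm(8), phi_pct = rnorm(8, 0, 0.05))
  cov_s <- spatial_covariates(si$x_km, si$y_km, cfg)
  bad <- grid[grid$area_id != grid$area_id[1], ]
  expect_error(map_impacts(si, cov_s, bad,
                           expected_areas = ar$features$area_id),
               "zero assigned cells")
})
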