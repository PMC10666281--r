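test_that("impact model fitting validates inputs and filters features", {
  cfg <- sim_config(n_areas = 60, seed = 71)
  ar <- generate_area_impacts(cfg)
  feats <- ar$features
  feats$constant <- 5
  feats$mostly_na <- NA_real_
  tun <- attribution_tuning(grid = expand.grid(max_depth = 2L, eta = 0.1),
                            nrounds = 40, nfold = 3)
  m <- fit_impact_model(feats, ar$impact, tun, seed = 1)
  expect_setequal(m$dropped, c("constant", "mostly_na"))
  expect_false("x_km" %in% m$feature_names)

  bad <- ar$impact; bad[3] <- NA
  expect_error(fit_impact_model(feats, bad, tun), "non-finite target")
  expect_error(fit_impact_model(feats[1:20, ], ar$impact[1:20], tun),
               ">= 50 areas")
})

test_that("learnable targets are learned and noise targets are not", {
  cfg <- sim_config(n_areas = 150, seed = 72)
  ar <- generate_area_impacts(cfg)
  tun <- attribution_tuning(nfold = 3)
  # single-feature step function
  step_target <- ifelse(ar$features$f01 > 0, 2, -2)
  m1 <- fit_impact_model(ar$features, step_target, tun, seed = 2)
  expect_gte(m1$cv_report$r2, 0.9)
  # pure noise
  set.seed(9)
  m2 <- fit_impact_model(ar$features, rnorm(150), tun, seed = 2)
  expect_lte(m2$cv_report$r2, 0.1)
  # determinism
  m3 <- fit_impact_model(ar$features, step_target, tun, seed = 2)
  expect_identical(predict(m1$booster, m1$X), predict(m3$booster, m3$X))
})

test_that("a single stump attributes everything to its split feature", {
  set.seed(73)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(X[, 2] > 0, 3, -1)
  m <- manual_impact_model(X, y, max_depth = 1, nrounds = 1)
  expl <- shap_values(m)
  expect_equal(unname(colSums(abs(expl$phi[, c(1, 3, 4)]))), rep(0, 3))
  expect_equal(expl$phi[, 2], expl$pred - expl$base, tolerance = 1e-10)

  gain <- total_gain_importance(m)
  expect_equal(gain$table$total_gain[gain$table$feature == "f2"], 1)
  expect_equal(sum(gain$table$total_gain), 1)
})

test_that("tree SHAP equals brute-force Shapley enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- X[, 1] * 2 + X[, 2] * X[, 3] + rnorm(60, 0, 0.3)
    m <- manual_impact_model(X, y, max_depth = 3, nrounds = 25, eta = 0.3,
                             seed = seed)
    expl <- shap_values(m)
    bf <- shap_values_brute(m)
    expect_lt(max(abs(expl$phi - bf)), 1e-8)
  }
})

test_that("local accuracy and the base value hold on every area", {
  cfg <- sim_config(n_areas = 80, seed = 74)
  ar <- generate_area_impacts(cfg)
  tun <- attribution_tuning(grid = expand.grid(max_depth = 3L, eta = 0.1),
                            nrounds = 80, nfold = 3)
  m <- fit_impact_model(ar$features, ar$impact, tun, seed = 3)
  expl <- shap_values(m)
  expect_lt(max(abs(expl$base + rowSums(expl$phi) - expl$pred)), 1e-6)
  # efficiency: base value equals the mean training prediction
  expect_lt(abs(expl$base - mean(expl$pred)), 1e-6)
  # the reimplemented predictions agree with the booster (float32 noise)
  expect_lt(max(abs(expl$pred - predict(m$booster, m$X))), 1e-4)
})

test_that("features unused by any tree get exactly zero SHAP values", {
  set.seed(75)
  X <- matrix(rnorm(300), 75, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * X[, 1]   # only f1 matters
  m <- manual_impact_model(X, y, max_depth = 2, nrounds = 10, eta = 0.5)
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = m$booster))
  used <- unique(dt$Feature[dt$Feature != "Leaf"])
  expl <- shap_values(m)
  for (f in setdiff(colnames(X), used)) {
    expect_identical(unname(expl$phi[, f]), rep(0, nrow(X)))
  }
})

test_that("symmetric trees give identical attributions to twin features", {
  # hand-built ensemble: two stumps with the same split value and leaves,
  # one on each twin feature; exact Shapley symmetry then forces equal
  # attributions when the twin columns are byte-identical
  tree_on <- function(f) list(feature = c(f, NA, NA), split = c(0, NA, NA),
                              yes = c(2L, NA, NA), no = c(3L, NA, NA),
                              missing = c(3L, NA, NA),
                              value = c(NA, -1, 1), cover = c(100, 50, 50))
  x <- c(f1 = 0.7, f2 = 0.7)
  phi <- rddair:::treeshap_one(tree_on(1L), x, 2) +
    rddair:::treeshap_one(tree_on(2L), x, 2)
  expect_equal(phi[1], phi[2], tolerance = 1e-12)
})

test_that("global importance ranks causal features with correct signs", {
  cfg <- sim_config(n_areas = 200, seed = 76)
  ar <- generate_area_impacts(cfg)
  tun <- attribution_tuning(nfold = 3)
  m <- fit_impact_model(ar$features, ar$impact, tun, seed = 4)
  expl <- shap_values(m)
  gi <- global_importance(expl)
  top3 <- gi$table$feature[1:3]
  expect_setequal(top3, c("f01", "f02", "f03"))
  r <- stats::setNames(gi$table$pearson_r, gi$table$feature)
  expect_lt(r[["f01"]], 0)
  expect_gt(r[["f02"]], 0)
  expect_lt(r[["f03"]], 0)
  expect_equal(sort(gi$table$rank), seq_len(nrow(gi$table)))

  dep <- dependence_summary(expl, "f01")
  expect_equal(dep$pearson_r,
               cor(expl$X[, "f01"], expl$phi[, "f01"]), tolerance = 1e-12)
  expect_error(dependence_summary(expl, "nope"), "unknown feature")

  tg <- total_gain_importance(m, gi, top_k = 5)
  expect_gte(tg$top_k_jaccard, 0.25)
})

test_that("degenerate SHAP columns report undefined correlation", {
  set.seed(77)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- manual_impact_model(X, 2 * X[, 1], max_depth = 1, nrounds = 1)
  expl <- shap_values(m)
  dep <- dependence_summary(expl, "f4")
  expect_true(dep$degenerate)
  expect_true(is.na(dep$pearson_r))
  gi <- global_importance(expl)
  expect_true(is.na(gi$table$pearson_r[gi$table$feature == "f4"]))
})
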