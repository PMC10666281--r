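# Feature attribution of areal impacts.
#
# A gradient-boosted decision-tree model predicts areal impacts from spatial
# features; Shapley additive explanations (SHAP values) attribute each
# prediction to the features. SHAP values are computed with the polynomial
# path-dependent tree algorithm implemented here on the parsed tree dump
# (double precision); a brute-force subset-enumeration oracle with the same
# cover-weighted tree-traversal value function is provided for validation.

#' Tuning configuration for the impact model
#'
#' @param grid Candidate `max_depth` / `eta` pairs.
#' @param nrounds Maximum boosting rounds (early-stopped in CV).
#' @param early_stopping_rounds,nfold Cross-validation controls.
#' @param min_areas Minimum number of areas.
#' @param max_missing Features missing in more than this fraction of areas
#'   are dropped before modelling (as are zero-variance features).
#' @return A list of class `attribution_tuning`.
#' @export
attribution_tuning <- function(grid = expand.grid(max_depth = c(2L, 3L),
                                                  eta = c(0.05, 0.1)),
                               nrounds = 300L, early_stopping_rounds = 30L,
                               nfold = 5L, min_areas = 50L,
                               max_missing = 0.2) {
  structure(as.list(environment()), class = "attribution_tuning")
}

# Drop identifier/coordinate columns and apply the feature quality filter.
prepare_feature_matrix <- function(features, max_missing) {
  drop <- intersect(c("area_id", "x_km", "y_km"), names(features))
  X <- features[, setdiff(names(features), drop), drop = FALSE]
  miss <- vapply(X, function(v) mean(is.na(v)), numeric(1))
  keep <- miss <= max_missing
  X <- X[, keep, drop = FALSE]
  nonconst <- vapply(X, function(v) stats::sd(v, na.rm = TRUE) > 0,
                     logical(1))
  dropped <- c(names(miss)[!keep], names(nonconst)[!nonconst])
  X <- X[, nonconst, drop = FALSE]
  list(X = as.matrix(X), dropped = dropped)
}

#' Fit the gradient-boosted impact model
#'
#' @param features Areal feature table (data frame; `area_id`/coordinate
#'   columns are ignored as predictors).
#' @param target Areal impact per row (absolute ug/m3 or relative).
#' @param tuning An [attribution_tuning()]; `max_depth`/`eta` and the number
#'   of rounds are chosen by k-fold CV RMSE.
#' @param seed Integer seed (CV folds and booster).
#' @return Object of class `impact_model`: booster, feature matrix and
#'   names, chosen parameters, CV report, dropped features.
#' @export
fit_impact_model <- function(features, target,
                             tuning = attribution_tuning(), seed = 1L) {
  assert(nrow(features) >= tuning$min_areas,
         "need >= ", tuning$min_areas, " areas, have ", nrow(features))
  if (any(!is.finite(target))) {
    ids <- if ("area_id" %in% names(features))
      features$area_id[!is.finite(target)] else which(!is.finite(target))
    stop_rddair("non-finite target for areas: ",
                paste(utils::head(ids, 5), collapse = ", "))
  }
  pf <- prepare_feature_matrix(features, tuning$max_missing)
  X <- pf$X

  cv_table <- tuning$grid
  cv_table$rmse <- NA_real_; cv_table$best_iter <- NA_integer_
  for (k in seq_len(nrow(tuning$grid))) {
    p <- list(objective = "reg:squarederror", nthread = 1,
              tree_method = "hist", seed = seed,
              max_depth = tuning$grid$max_depth[k],
              eta = tuning$grid$eta[k],
              subsample = 1, colsample_bytree = 1, min_child_weight = 3)
    set.seed(stage_seed(seed, paste0("acv", k)))
    cv <- xgboost::xgb.cv(params = p,
                          data = xgboost::xgb.DMatrix(X, label = target),
                          nrounds = tuning$nrounds, nfold = tuning$nfold,
                          early_stopping_rounds = tuning$early_stopping_rounds,
                          verbose = 0)
    cv_table$best_iter[k] <- cv$early_stop$best_iteration
    cv_table$rmse[k] <- cv$evaluation_log$test_rmse_mean[cv$early_stop$best_iteration]
  }
  best <- which.min(cv_table$rmse)
  params <- list(max_depth = tuning$grid$max_depth[best],
                 eta = tuning$grid$eta[best],
                 subsample = 1, colsample_bytree = 1, min_child_weight = 3)
  booster <- xgb_fit(X, target, params, cv_table$best_iter[best],
                     stage_seed(seed, "afit"))
  r2 <- 1 - min(cv_table$rmse)^2 / stats::var(target)
  structure(list(booster = booster, X = X,
                 feature_names = colnames(X), target = target,
                 params = params, nrounds = cv_table$best_iter[best],
                 dropped = pf$dropped,
                 cv_report = list(table = cv_table, rmse = min(cv_table$rmse),
                                  r2 = r2)),
            class = "impact_model")
}

#' @export
print.impact_model <- function(x, ...) {
  cat("Areal impact model (GBDT):", nrow(x$X), "areas,",
      ncol(x$X), "features,", x$nrounds, "trees\n  CV RMSE:",
      signif(x$cv_report$rmse, 4), " CV R2:",
      signif(x$cv_report$r2, 3), "\n")
  invisible(x)
}

# ---- parsed tree representation ------------------------------------------

# Round doubles to float32 precision. xgboost stores split thresholds and
# compares feature values in single precision; replicating that here keeps
# boundary cases (splits located exactly at data values under the histogram
# method) routed identically.
round_f32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

# Parse an xgboost booster into per-tree vectors (1-based child indices;
# `feature` is an index into feature_names, NA at leaves; `value` holds leaf
# weights; `cover` the training cover of each node).
parse_trees <- function(booster, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  node_of <- function(id) as.integer(sub("^\\d+-", "", id)) + 1L
  cfg <- xgboost::xgb.config(booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  trees <- lapply(split(dt, dt$Tree), function(d) {
    d <- d[order(d$Node), ]
    leaf <- d$Feature == "Leaf"
    list(
      feature = ifelse(leaf, NA_integer_,
                       match(d$Feature, feature_names)),
      split = round_f32(d$Split),  # dumps are float32 printed as text
      yes = ifelse(leaf, NA_integer_, node_of(d$Yes)),
      no = ifelse(leaf, NA_integer_, node_of(d$No)),
      missing = ifelse(leaf, NA_integer_, node_of(d$Missing)),
      value = ifelse(leaf, d$Gain, NA_real_),
      cover = d$Cover
    )
  })
  list(trees = unname(trees), base_score = base_score,
       feature_names = feature_names)
}

# Deterministic single-tree prediction for a feature vector.
tree_predict <- function(tr, x) {
  j <- 1L
  while (is.na(tr$feature[j]) == FALSE) {
    xv <- x[tr$feature[j]]
    j <- if (is.na(xv)) tr$missing[j]
         else if (xv < tr$split[j]) tr$yes[j] else tr$no[j]
  }
  tr$value[j]
}

# Cover-weighted conditional expectation of a tree given the features in S:
# splits on features in S follow x, others descend into both children
# weighted by their cover share. This is the value function of the
# path-dependent tree Shapley semantics.
tree_expectation <- function(tr, x, S) {
  rec <- function(j) {
    f <- tr$feature[j]
    if (is.na(f)) return(tr$value[j])
    if (f %in% S) {
      xv <- x[f]
      k <- if (is.na(xv)) tr$missing[j]
           else if (xv < tr$split[j]) tr$yes[j] else tr$no[j]
      return(rec(k))
    }
    (tr$cover[tr$yes[j]] * rec(tr$yes[j]) +
       tr$cover[tr$no[j]] * rec(tr$no[j])) / tr$cover[j]
  }
  rec(1L)
}

#' Predictions from the parsed tree ensemble
#'
#' Double-precision reimplementation of the booster's prediction used as the
#' reference output that SHAP values must reassemble exactly.
#'
#' @param parsed Output of the internal tree parser (see [shap_values()]).
#' @param X Feature matrix.
#' @return Numeric predictions.
#' @keywords internal
parsed_predict <- function(parsed, X) {
  vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    parsed$base_score +
      sum(vapply(parsed$trees, tree_predict, numeric(1), x = x))
  }, numeric(1))
}

# Path-dependent TreeSHAP for one instance and one tree. The path is kept
# in plain vectors (d: feature, z: covering fraction when excluded, o:
# fraction when included, w: permutation weights); copy-on-recurse keeps the
# bookkeeping simple at the shallow depths used here.
treeshap_one <- function(tr, x, n_features) {
  phi <- numeric(n_features)

  extend <- function(path, pz, po, pi) {
    l <- length(path$d)
    path$d <- c(path$d, pi); path$z <- c(path$z, pz); path$o <- c(path$o, po)
    path$w <- c(path$w, if (l == 0) 1 else 0)
    if (l > 0) for (i in l:1) {
      path$w[i + 1] <- path$w[i + 1] + po * path$w[i] * i / (l + 1)
      path$w[i] <- pz * path$w[i] * (l + 1 - i) / (l + 1)
    }
    path
  }

  unwind <- function(path, i) {
    l <- length(path$d)
    n <- path$w[l]
    if (l > 1) for (j in (l - 1):1) {
      if (path$o[i] != 0) {
        t <- path$w[j]
        path$w[j] <- n * l / (j * path$o[i])
        n <- t - path$w[j] * path$z[i] * (l - j) / l
      } else {
        path$w[j] <- path$w[j] * l / (path$z[i] * (l - j))
      }
    }
    keep <- setdiff(seq_len(l), i)
    list(d = path$d[keep], z = path$z[keep], o = path$o[keep],
         w = path$w[seq_len(l - 1)])
  }

  unwound_sum <- function(path, i) {
    l <- length(path$d)
    total <- 0
    n <- path$w[l]
    if (l > 1) for (j in (l - 1):1) {
      if (path$o[i] != 0) {
        t <- n * l / (j * path$o[i])
        total <- total + t
        n <- path$w[j] - t * path$z[i] * (l - j) / l
      } else {
        total <- total + path$w[j] * l / (path$z[i] * (l - j))
      }
    }
    total
  }

  recurse <- function(j, path, pz, po, pi) {
    path <- extend(path, pz, po, pi)
    f <- tr$feature[j]
    if (is.na(f)) {
      l <- length(path$d)
      if (l >= 2) for (i in 2:l) {
        s <- unwound_sum(path, i)
        phi[path$d[i]] <<- phi[path$d[i]] +
          s * (path$o[i] - path$z[i]) * tr$value[j]
      }
      return(invisible())
    }
    xv <- x[f]
    hot <- if (is.na(xv)) tr$missing[j]
           else if (xv < tr$split[j]) tr$yes[j] else tr$no[j]
    cold <- if (hot == tr$yes[j]) tr$no[j] else tr$yes[j]
    iz <- 1; io <- 1
    k <- which(path$d == f)[1]
    if (!is.na(k)) {
      iz <- path$z[k]; io <- path$o[k]
      path <- unwind(path, k)
    }
    recurse(hot, path, iz * tr$cover[hot] / tr$cover[j], io, f)
    recurse(cold, path, iz * tr$cover[cold] / tr$cover[j], 0, f)
  }

  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0L)
  phi
}

#' SHAP values for an impact model
#'
#' Exact path-dependent tree Shapley values computed per area: additive
#' per-feature contributions in model-output units whose sum plus the base
#' value (the cover-weighted expected model output) reassembles the model
#' prediction (local accuracy).
#'
#' @param model An [fit_impact_model()] object.
#' @param features Feature table to explain (default: the training table);
#'   must carry the training feature columns.
#' @return Object of class `shap_explanation`: `phi` (area x feature
#'   matrix), `base`, `pred`, `X`, `feature_names`.
#' @export
shap_values <- function(model, features = NULL) {
  stopifnot(inherits(model, "impact_model"))
  X <- if (is.null(features)) model$X else {
    assert(all(model$feature_names %in% names(features)),
           "feature columns mismatch the training columns: missing ",
           paste(setdiff(model$feature_names, names(features)),
                 collapse = ", "))
    as.matrix(features[, model$feature_names, drop = FALSE])
  }
  X <- matrix(round_f32(X), nrow(X), ncol(X),
              dimnames = dimnames(X))
  parsed <- parse_trees(model$booster, model$feature_names)
  p <- length(model$feature_names)
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, model$feature_names))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    for (tr in parsed$trees) phi[i, ] <- phi[i, ] + treeshap_one(tr, x, p)
  }
  base <- parsed$base_score +
    sum(vapply(parsed$trees, tree_expectation, numeric(1),
               x = X[1, ], S = integer(0)))
  structure(list(phi = phi, base = base,
                 pred = parsed_predict(parsed, X),
                 X = X, feature_names = model$feature_names,
                 parsed = parsed),
            class = "shap_explanation")
}

#' Brute-force Shapley values (reference oracle)
#'
#' Enumerates all feature subsets with the cover-weighted tree-traversal
#' conditional expectation as the value function; feasible for small
#' feature counts only. Matches [shap_values()] up to numerical error.
#'
#' @param model An [fit_impact_model()] object.
#' @param max_features Guard on `2^p` enumeration.
#' @return Matrix of Shapley values (area x feature).
#' @export
shap_values_brute <- function(model, max_features = 15L) {
  p <- length(model$feature_names)
  assert(p <= max_features, "brute-force enumeration limited to ",
         max_features, " features, model has ", p)
  parsed <- parse_trees(model$booster, model$feature_names)
  X <- matrix(round_f32(model$X), nrow(model$X), ncol(model$X),
              dimnames = dimnames(model$X))
  subsets <- lapply(0:(2^p - 1), function(mask)
    which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  wgt <- function(s) factorial(s) * factorial(p - s - 1) / factorial(p)

  ens_value <- function(x, S) {
    parsed$base_score +
      sum(vapply(parsed$trees, tree_expectation, numeric(1), x = x, S = S))
  }
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, model$feature_names))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    vals <- vapply(subsets, ens_value, numeric(1), x = x)
    names(vals) <- vapply(subsets, function(S)
      paste(S, collapse = ","), character(1))
    for (f in seq_len(p)) {
      for (k in seq_along(subsets)) {
        S <- subsets[[k]]
        if (f %in% S) next
        key <- paste(sort(c(S, f)), collapse = ",")
        phi[i, f] <- phi[i, f] +
          wgt(length(S)) * (vals[[key]] - vals[[k]])
      }
    }
  }
  phi
}

#' Global feature importance from SHAP values
#'
#' Mean absolute SHAP value per feature plus the Pearson correlation between
#' feature values and SHAP values (a sign diagnostic), ranked descending.
#'
#' @param expl A [shap_values()] explanation.
#' @param top_k Rows retained in the `top` table.
#' @return Object of class `global_importance`: data frame `feature`,
#'   `mean_abs_shap`, `pearson_r` (`NA` when the SHAP column has zero
#'   variance), `rank`; plus `top`.
#' @export
global_importance <- function(expl, top_k = 20L) {
  imp <- data.frame(
    feature = expl$feature_names,
    mean_abs_shap = colMeans(abs(expl$phi)),
    pearson_r = vapply(seq_along(expl$feature_names), function(j)
      pearson_or_na(expl$X[, j], expl$phi[, j]), numeric(1)),
    stringsAsFactors = FALSE
  )
  imp <- imp[order(-imp$mean_abs_shap), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(table = imp, top = utils::head(imp, top_k)),
            class = "global_importance")
}

#' @export
print.global_importance <- function(x, ...) {
  cat("Global SHAP importance (top features):\n")
  print(utils::head(x$table, 10), digits = 3)
  invisible(x)
}

#' Total-gain feature importance
#'
#' Per-feature sum of split-gain (squared-error reduction) over all splits
#' using the feature, with the Jaccard overlap of the top-k sets against a
#' SHAP ranking when one is supplied.
#'
#' @param model An [fit_impact_model()] object.
#' @param shap_importance Optional [global_importance()] for the overlap.
#' @param top_k Size of the compared top sets.
#' @return List: `table` (feature, total_gain, rank; unused features have
#'   gain 0), `top_k_jaccard` (or `NA`).
#' @export
total_gain_importance <- function(model, shap_importance = NULL,
                                  top_k = 5L) {
  imp <- xgboost::xgb.importance(model = model$booster)
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  gain[imp$Feature] <- imp$Gain
  tab <- data.frame(feature = names(gain), total_gain = unname(gain),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$total_gain), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  jac <- NA_real_
  if (!is.null(shap_importance)) {
    a <- utils::head(tab$feature, top_k)
    b <- utils::head(shap_importance$table$feature, top_k)
    jac <- length(intersect(a, b)) / length(union(a, b))
  }
  list(table = tab, top_k_jaccard = jac)
}

#' SHAP dependence summary for one feature
#'
#' @param expl A [shap_values()] explanation.
#' @param feature_name Feature to summarize.
#' @return List: `data` (feature value, SHAP value per area), `pearson_r`
#'   (`NA` with `degenerate = TRUE` when the SHAP column is constant).
#' @export
dependence_summary <- function(expl, feature_name) {
  j <- match(feature_name, expl$feature_names)
  assert(!is.na(j), "unknown feature: ", feature_name)
  r <- pearson_or_na(expl$X[, j], expl$phi[, j])
  list(data = data.frame(value = expl$X[, j], shap = expl$phi[, j]),
       pearson_r = r, degenerate = is.na(r), feature = feature_name)
}
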