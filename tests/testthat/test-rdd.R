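T0 <- as.Date("2020-03-23")

# Noise-free log-linear series with a pure step at T0.
step_series <- function(a = 3.4, b = 0.001, step = log(0.9), n_pre = 180,
                        n_post = 180) {
  dates <- seq(T0 - n_pre, T0 + n_post - 1, by = "day")
  t <- as.numeric(dates - T0)
  make_step <- a + b * t + step * (t >= 0)
  data.frame(date = dates, value = exp(make_step))
}

test_that("a constructed log-step is recovered to machine precision", {
  s <- step_series()
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 0L)
  expect_equal(unname(fit$coef["treat"]), log(0.9), tolerance = 1e-10)
  expect_equal(total_effect(fit)$tau, -0.10, tolerance = 1e-10)
})

test_that("a flat series has a zero treatment coefficient", {
  s <- step_series(b = 0, step = 0)
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 0L)
  expect_equal(unname(fit$coef["treat"]), 0, tolerance = 1e-10)
})

test_that("dynamic AR(1) outcome model is identified exactly without noise", {
  rho <- 0.5; beta <- -0.05; c0 <- 1.7
  dates <- seq(T0 - 300, T0 + 250, by = "day")
  t <- as.numeric(dates - T0)
  x <- numeric(length(t))
  x[1] <- c0 / (1 - rho)
  for (i in 2:length(t)) x[i] <- c0 + rho * x[i - 1] + beta * (t[i] >= 0)
  s <- data.frame(date = dates, value = exp(x))
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 1L)
  expect_equal(unname(fit$coef["treat"]), beta, tolerance = 1e-8)
  expect_equal(unname(fit$coef["lag1"]), rho, tolerance = 1e-8)
  te <- total_effect(fit)
  expect_equal(te$delta, beta / (1 - rho), tolerance = 1e-8)
})

test_that("total effect matches the forward-simulated step response", {
  # oracle: iterate the fitted dynamic model with and without treatment;
  # the stationary difference of the two paths is the total log effect
  forward_delta <- function(beta, rhos) {
    n <- 3000
    d <- numeric(n + length(rhos))
    for (i in seq_len(n)) {
      k <- i + length(rhos)
      d[k] <- beta + sum(rhos * d[k - seq_along(rhos)])
    }
    d[length(d)]
  }
  set.seed(41)
  for (L in 0:3) {
    rhos <- if (L > 0) runif(L, -0.1, 0.25) else numeric(0)
    beta <- -0.07
    fit <- structure(list(coef = c(treat = beta,
                                   stats::setNames(rhos, if (L > 0)
                                     paste0("lag", seq_len(L)) else NULL)),
                          treat_name = "treat",
                          lag_names = if (L > 0) paste0("lag", seq_len(L))
                                      else character(0)),
                     class = "rdd_fit")
    expect_equal(total_effect(fit)$delta, forward_delta(beta, rhos),
                 tolerance = 1e-8)
  }
})

test_that("total effect is undefined for non-stationary dynamics", {
  fit <- structure(list(coef = c(treat = -0.05, lag1 = 0.7, lag2 = 0.35),
                        treat_name = "treat",
                        lag_names = c("lag1", "lag2")), class = "rdd_fit")
  expect_error(total_effect(fit), "non-stationary")
})

test_that("Monte Carlo intervals collapse to the point under zero variance", {
  s <- step_series()
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 0L)
  fit$vcov <- fit$vcov * 0
  est <- mc_interval(fit, n_draws = 500, seed = 1)
  expect_equal(est$lo95, est$tau, tolerance = 1e-9)
  expect_equal(est$hi95, est$tau, tolerance = 1e-9)
})

test_that("lag-free percentile intervals match closed-form quantiles", {
  # tau = exp(beta) - 1 with beta ~ Normal: quantiles transform directly
  s <- step_series()
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 0L)
  k <- match("treat", names(fit$coef))
  V <- fit$vcov * 0
  V[k, k] <- 0.02^2
  fit$vcov <- V
  est <- mc_interval(fit, n_draws = 100000, seed = 2)
  mu <- unname(fit$coef["treat"])
  want <- function(p) expm1(qnorm(p, mu, 0.02))
  expect_equal(est$lo95, want(0.025), tolerance = 1e-3)
  expect_equal(est$hi95, want(0.975), tolerance = 1e-3)
  expect_equal(est$lo90, want(0.05), tolerance = 1e-3)
  # nesting of the interval levels
  expect_true(est$lo99 <= est$lo95 && est$lo95 <= est$lo90)
  expect_true(est$hi90 <= est$hi95 && est$hi95 <= est$hi99)
})

test_that("estimation rows never fall inside the donut and sides are guarded", {
  s <- step_series()
  fit <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 2L)
  expect_true(all(abs(as.numeric(fit$dates - T0)) > 7))
  short <- s[s$date <= T0 + 12, ]
  expect_error(fit_donut_rdd(short, NULL, T0, margin_period(7),
                             lag_order = 0L), "post-donut")
  s2 <- s; s2$value[5] <- -1
  expect_error(fit_donut_rdd(s2, NULL, T0, margin_period(7),
                             lag_order = 0L), "non-positive")
})

test_that("tau is invariant to rescaling the series", {
  s <- step_series(b = 0.0005)
  f1 <- fit_donut_rdd(s, NULL, T0, margin_period(7), lag_order = 0L)
  s2 <- s; s2$value <- s2$value * 37.5
  f2 <- fit_donut_rdd(s2, NULL, T0, margin_period(7), lag_order = 0L)
  expect_equal(total_effect(f1)$tau, total_effect(f2)$tau,
               tolerance = 1e-10)
})

test_that("site appraisal is deterministic and carries stage errors", {
  g <- gen_site(45, true_tau = -0.20)
  cfg <- appraise_config_study(n_norm_boot = 2L, n_draws = 1000L)
  a1 <- appraise_site(g$conc, g$weather, T0, cfg, seed = 77,
                      site_id = "site01")
  a2 <- appraise_site(g$conc, g$weather, T0, cfg, seed = 77,
                      site_id = "site01")
  expect_identical(a1$estimate, a2$estimate)
  expect_true(a1$estimate$response)
  err <- tryCatch(
    appraise_site(g$conc[1:100, ], g$weather, T0, cfg, seed = 1),
    error = conditionMessage)
  expect_match(err, "stage normalize")
})
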