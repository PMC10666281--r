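# Change-point detection on normalized daily series.
#
# Structural changes are either a change in the slope of the linear trend or
# an abrupt level discontinuity. Both are captured by penalized piecewise-
# linear segmentation: each segment gets its own least-squares line (so both
# slope and level may change at a breakpoint) and the globally optimal
# segmentation for a fixed per-breakpoint penalty is found by exact dynamic
# programming (optimal partitioning, O(n^2) with O(1) segment costs).

# Prefix-sum machinery for O(1) least-squares segment costs. t and y are
# centered globally before the sums are formed to limit cancellation error.
segment_cost_env <- function(t, y) {
  t <- t - mean(t); y <- y - mean(y)
  list(
    St  = c(0, cumsum(t)),   Sy  = c(0, cumsum(y)),
    Stt = c(0, cumsum(t^2)), Sty = c(0, cumsum(t * y)),
    Syy = c(0, cumsum(y^2))
  )
}

# RSS of a per-segment linear fit on points a..b (1-based, inclusive);
# vectorized over `a`.
segment_cost <- function(ps, a, b) {
  n <- b - a + 1
  St  <- ps$St[b + 1]  - ps$St[a]
  Sy  <- ps$Sy[b + 1]  - ps$Sy[a]
  Stt <- ps$Stt[b + 1] - ps$Stt[a]
  Sty <- ps$Sty[b + 1] - ps$Sty[a]
  Syy <- ps$Syy[b + 1] - ps$Syy[a]
  syy <- Syy - Sy^2 / n
  stt <- Stt - St^2 / n
  sty <- Sty - St * Sy / n
  rss <- ifelse(stt > 1e-12, syy - sty^2 / stt, syy)
  pmax(rss, 0)
}

#' Detect change points in a daily series
#'
#' Finds the global optimum of a penalized piecewise-linear segmentation by
#' exact dynamic programming. The default per-breakpoint penalty is
#' `penalty_const * sigma2 * log(n)` with `sigma2` estimated robustly from
#' first differences (`mad(diff(y))^2 / 2`).
#'
#' Each breakpoint is labelled post hoc: `"level"` when the fitted
#' discontinuity at the breakpoint exceeds the fitted-value change that the
#' slope difference would accumulate over `min_seg_len` days, else
#' `"slope"`.
#'
#' @param series Data frame `date`, `value` (a normalized daily series).
#' @param penalty Per-breakpoint penalty; `NULL` for the default above.
#' @param min_seg_len Minimum segment length in observations (>= 2).
#' @param penalty_const Constant `c` of the default penalty (default 5:
#'   a BIC-style charge for the ~3 parameters a breakpoint adds).
#' @return Object of class `changepoint_set`: `changepoints` (data frame
#'   `index`, `date`, `type`; the date is the first observation of the new
#'   segment), `fitted` piecewise-linear values, `segments`, `penalty`,
#'   `cost` (total RSS + penalty * breakpoints), `sigma2`.
#' @export
detect_change_points <- function(series, penalty = NULL, min_seg_len = 14L,
                                 penalty_const = 5) {
  n <- nrow(series)
  min_seg_len <- max(as.integer(min_seg_len), 2L)
  assert(n >= 2 * min_seg_len,
         "series too short: need at least 2*min_seg_len = ",
         2 * min_seg_len, " days, have ", n)
  y <- series$value
  t <- as.numeric(series$date - series$date[1])
  sigma2 <- (stats::mad(diff(y))^2) / 2
  if (is.null(penalty)) {
    penalty <- penalty_const * max(sigma2, 1e-12) * log(n)
  }

  ps <- segment_cost_env(t, y)
  # F[j+1] = optimal cost of points 1..j (+ penalty per breakpoint);
  # F[1] corresponds to the empty prefix.
  F <- rep(Inf, n + 1)
  F[1] <- -penalty
  prev <- integer(n + 1)
  for (j in min_seg_len:n) {
    i <- c(0L, seq_len(max(j - min_seg_len, 0)))
    i <- i[i == 0L | i >= min_seg_len]
    i <- i[j - i >= min_seg_len]
    if (!length(i)) next
    cand <- F[i + 1] + segment_cost(ps, i + 1, j) + penalty
    k <- which.min(cand)
    F[j + 1] <- cand[k]
    prev[j + 1] <- i[k]
  }
  assert(is.finite(F[n + 1]), "no feasible segmentation")

  # backtrack segment boundaries
  ends <- integer(0); j <- n
  while (j > 0) { ends <- c(j, ends); j <- prev[j + 1] }
  starts <- c(1L, utils::head(ends, -1) + 1L)

  fitted <- numeric(n)
  seg <- data.frame(start = starts, end = ends, intercept = NA_real_,
                    slope = NA_real_)
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    seg$intercept[k] <- fit$coefficients[1]
    seg$slope[k] <- ifelse(is.na(fit$coefficients[2]), 0,
                           fit$coefficients[2])
    fitted[idx] <- seg$intercept[k] + seg$slope[k] * t[idx]
  }

  cp_idx <- starts[-1]
  type <- character(0)
  if (length(cp_idx)) {
    day_scale <- min_seg_len * stats::median(diff(t))
    type <- vapply(seq_along(cp_idx), function(k) {
      tb <- t[cp_idx[k]]
      left <- seg$intercept[k] + seg$slope[k] * tb
      right <- seg$intercept[k + 1] + seg$slope[k + 1] * tb
      jump <- abs(right - left)
      drift <- abs(seg$slope[k + 1] - seg$slope[k]) * day_scale
      if (jump >= drift) "level" else "slope"
    }, character(1))
  }

  structure(list(
    changepoints = data.frame(index = cp_idx,
                              date = series$date[cp_idx],
                              type = type, stringsAsFactors = FALSE),
    fitted = fitted, segments = seg, penalty = penalty,
    min_seg_len = min_seg_len, sigma2 = sigma2,
    cost = F[n + 1]
  ), class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat("Piecewise-linear segmentation:", nrow(x$changepoints),
      "change point(s), penalty", signif(x$penalty, 4), "\n")
  if (nrow(x$changepoints)) print(x$changepoints)
  invisible(x)
}

#' Margin period around the intervention start
#'
#' A symmetric window `[T0 - hw, T0 + hw]` used both to classify a response
#' (a change point inside it) and as the donut hole of the RDD.
#'
#' @param half_width_days Half-width in days (>= 1).
#' @return Object of class `margin_period`.
#' @export
margin_period <- function(half_width_days = 7L) {
  assert(half_width_days >= 1, "margin-period half-width must be >= 1 day")
  structure(list(hw = as.integer(half_width_days)), class = "margin_period")
}

mp_hw <- function(mp) if (inherits(mp, "margin_period")) mp$hw else as.integer(mp)

#' Did the site respond to the intervention?
#'
#' `TRUE` iff at least one detected change date lies in the closed margin
#' window `[T0 - hw, T0 + hw]`.
#'
#' @param cps A `changepoint_set`.
#' @param mp A [margin_period()] (or half-width in days).
#' @param T0 Intervention date.
#' @return Logical flag.
#' @export
classify_response <- function(cps, mp, T0) {
  hw <- mp_hw(mp); T0 <- as_date_strict(T0, "T0")
  d <- cps$changepoints$date
  any(d >= T0 - hw & d <= T0 + hw)
}

#' Select the RDD research period
#'
#' The research window runs between the latest change date before
#' `T0 - hw` and the earliest change date after `T0 + hw` (both exclusive),
#' clipped to the series extent: change points inside the margin period
#' never clip the window.
#'
#' @param cps A `changepoint_set`.
#' @param mp A [margin_period()].
#' @param T0 Intervention date.
#' @param series The daily series the change points were detected on.
#' @param min_side_days Minimum usable days required on each side of the
#'   margin period.
#' @return List `start`, `end` (class `research_period`).
#' @export
select_research_period <- function(cps, mp, T0, series, min_side_days = 30L) {
  hw <- mp_hw(mp); T0 <- as_date_strict(T0, "T0")
  assert(classify_response(cps, mp, T0),
         "site shows no response: no change point inside the margin period")
  d <- cps$changepoints$date
  # Walk outward past change points whose segment would leave fewer than
  # min_side_days usable days next to the margin period: such micro-segments
  # reflect transition dynamics that the donut hole is there to absorb.
  starts <- c(sort(d[d < T0 - hw] + 1, decreasing = TRUE), min(series$date))
  ends <- c(sort(d[d > T0 + hw] - 1), max(series$date))
  usable_pre <- function(s) sum(series$date >= s & series$date < T0 - hw)
  usable_post <- function(e) sum(series$date > T0 + hw & series$date <= e)
  start <- starts[which(vapply(starts, usable_pre, 0) >= min_side_days)[1]]
  end <- ends[which(vapply(ends, usable_post, 0) >= min_side_days)[1]]
  assert(!is.na(start) && !is.na(end),
         "research period too short (", usable_pre(min(series$date)),
         " pre / ", usable_post(max(series$date)),
         " post usable days, need ", min_side_days,
         " per side); consider adjusting the change-point penalty")
  start <- as.Date(start, origin = "1970-01-01")
  end <- as.Date(end, origin = "1970-01-01")
  structure(list(start = start, end = end), class = "research_period")
}
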