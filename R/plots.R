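# Figure helpers (ggplot2, suggested dependency). Each returns a ggplot
# object; callers decide on devices and files.

need_ggplot <- function() {
  assert(requireNamespace("ggplot2", quietly = TRUE),
         "ggplot2 is required for plotting")
}

#' Normalized daily series with change points and margin period
#'
#' @param daily Data frame `date`, `value`.
#' @param cps A `changepoint_set` (optional).
#' @param T0 Intervention date.
#' @param mp A [margin_period()].
#' @return A ggplot object.
#' @export
plot_normalized_series <- function(daily, cps = NULL, T0, mp = margin_period()) {
  need_ggplot()
  T0 <- as_date_strict(T0, "T0"); hw <- mp_hw(mp)
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = date, y = value)) +
    ggplot2::annotate("rect", xmin = T0 - hw, xmax = T0 + hw,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_vline(xintercept = T0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "normalized concentration (µg/m³)")
  if (!is.null(cps) && nrow(cps$changepoints)) {
    p <- p + ggplot2::geom_vline(xintercept = cps$changepoints$date,
                                 color = "red", alpha = 0.6) +
      ggplot2::geom_line(data = data.frame(date = daily$date,
                                           value = cps$fitted),
                         color = "blue")
  }
  p
}

#' Site-level effect estimates with interval bars
#'
#' @param estimates An [effect_estimate()] table.
#' @return A ggplot object.
#' @export
plot_effect_estimates <- function(estimates) {
  need_ggplot()
  d <- as.data.frame(estimates)
  d$site_id <- stats::reorder(d$site_id, d$tau)
  ggplot2::ggplot(d, ggplot2::aes(x = site_id, y = tau)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo95, ymax = hi95),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(color = response)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "total effect τ (95% interval)")
}

#' Global SHAP importance bar chart
#'
#' @param imp A [global_importance()].
#' @param top_k Features shown.
#' @return A ggplot object.
#' @export
plot_shap_importance <- function(imp, top_k = 20L) {
  need_ggplot()
  d <- utils::head(imp$table, top_k)
  d$feature <- stats::reorder(d$feature, d$mean_abs_shap)
  ggplot2::ggplot(d, ggplot2::aes(x = feature, y = mean_abs_shap)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |SHAP| (model-output units)")
}

#' SHAP dependence scatter for one feature
#'
#' @param dep A [dependence_summary()].
#' @return A ggplot object.
#' @export
plot_shap_dependence <- function(dep) {
  need_ggplot()
  ggplot2::ggplot(dep$data, ggplot2::aes(x = value, y = shap)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = dep$feature, y = "SHAP value",
                  subtitle = paste0("Pearson R = ",
                                    ifelse(is.na(dep$pearson_r), "undefined",
                                           round(dep$pearson_r, 2))))
}
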