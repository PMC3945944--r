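# ggplot2 displays for the main result types.

#' Plot a segmented dive profile
#'
#' Depth trace with the descent/bottom/ascent boundaries of the selected
#' dives marked.
#'
#' @param series Corrected depth tibble.
#' @param dives Dive metrics tibble.
#' @param dive_ids Dives to show (default: all).
#' @return A ggplot.
#' @export
plot_dive_profile <- function(series, dives, dive_ids = dives$dive_id) {
  d <- dives[dives$dive_id %in% dive_ids, ]
  lo <- min(d$start_s); hi <- max(d$end_s)
  sub <- series[series$time_s >= lo - 30 & series$time_s <= hi + 30, ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$time_s, y = .data$depth_m)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = stats::na.omit(d$descent_end_s),
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = stats::na.omit(d$ascent_start_s),
                        linetype = "dashed", colour = "darkorange3") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "depth (m)",
                  title = "Dive profile with phase boundaries") +
    ggplot2::theme_minimal()
}

#' @rdname model_average
#' @export
autoplot.fs_avg <- function(object, ...) {
  cf <- object$coefficients[object$coefficients$term != "(Intercept)", ]
  cf$term <- factor(cf$term, levels = rev(cf$term))
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - .data$std_error,
      xmax = .data$estimate + .data$std_error,
      alpha = .data$importance)) +
    ggplot2::scale_alpha(range = c(0.25, 1), limits = c(0, 1)) +
    ggplot2::labs(x = "averaged coefficient (link scale, standardized)",
                  y = NULL, alpha = "importance",
                  title = sprintf("Model-averaged coefficients (%s scale)",
                                  object$scale %||% "?")) +
    ggplot2::theme_minimal()
}

#' @rdname loocv
#' @export
autoplot.fs_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed,
                               colour = .data$individual_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "predicted prey capture attempts",
                  y = "observed prey capture attempts",
                  colour = "individual",
                  title = sprintf("Held-out predictions (pooled C = %.2f, %s)",
                                  object$c_index_pooled, object$label)) +
    ggplot2::theme_minimal()
}
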