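#' Plot a digitized Kaplan-Meier curve
#'
#' Shows the digitized coordinate pairs together with the step function they
#' imply, the way the curve would appear restored on the original plot.
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  pts <- tibble::tibble(time = object$time, survival = object$survival)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Follow-up (months)", y = "Survival probability",
      title = sprintf("Digitized curve: %s", attr(object, "arm_label"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-arm RMST comparison
#'
#' Restricted survival curves for both arms with the area under each curve
#' up to the milestone shaded — the two areas whose difference is the RMST
#' gain — plus a vertical line at the milestone.
#'
#' @param object An `rmst_comparison` from [compare_arms()] or the
#'   `comparison` element of an [run_analysis()] report.
#' @param treated,control The `km_curve` objects that were compared (needed
#'   because the comparison object stores summaries, not the curves).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmst_comparison <- function(object, treated, control, ...) {
  t_star <- object$gain$milestone
  curve_df <- function(curve) {
    tr <- truncate_curve(curve, t_star)
    tibble::tibble(arm = attr(curve, "arm_label"), time = tr$time,
                   survival = tr$survival)
  }
  df <- dplyr::bind_rows(curve_df(treated), curve_df(control))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_area(alpha = 0.15, position = "identity") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = t_star, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Follow-up (months)", y = "Survival probability",
      title = sprintf("RMST gain %.2f mo at t* = %.1f mo",
                      object$gain$rmst_gain, t_star)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap distribution of the RMST gain
#'
#' Histogram of the bootstrap gain draws with the point estimate and the
#' percentile interval marked.
#'
#' @param comparison An `rmst_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gain_bootstrap <- function(comparison, ...) {
  stopifnot(inherits(comparison, "rmst_comparison"))
  g <- comparison$gain
  ggplot2::ggplot(comparison$boot, ggplot2::aes(x = .data$gain)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = g$rmst_gain, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(g$gain_ci_low, g$gain_ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Bootstrap RMST gain (months)", y = "Resamples",
                  title = sprintf("Gain %.2f mo (%.2f to %.2f)",
                                  g$rmst_gain, g$gain_ci_low, g$gain_ci_high)) +
    ggplot2::theme_minimal()
}
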