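# ggplot2 views of trajectories, sensitivity scans, calibration fits and
# tau fields.

#' Plot a kinetic trajectory
#'
#' Transformed percentage X(t) over time, with the saturation bound drawn as
#' a dashed reference line.
#'
#' @param traj A [kjma_trajectory()] tibble.
#' @param alpha Saturation bound to mark; default 0.35.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, alpha = 0.35) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_days, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Time post injury (days)", y = "Tau burden X(t) (AT%)",
      title = "Homogeneous Avrami tau kinetics"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a one-factor-at-a-time sensitivity scan
#'
#' One panel per perturbed parameter, one curve per multiplicative factor.
#'
#' @param scan An [ofat_scan()] tibble.
#' @param alpha Saturation bound to mark.
#' @return A ggplot object.
#' @export
plot_ofat <- function(scan, alpha = 0.35) {
  ggplot2::ggplot(
    scan,
    ggplot2::aes(x = .data$time_days, y = .data$x,
                 colour = factor(.data$factor), group = .data$factor)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(
      x = "Time post injury (days)", y = "Tau burden X(t) (AT%)",
      colour = "Factor", title = "One-factor-at-a-time sensitivity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname calibrate
#' @param object A `tau_calibration` object.
#' @param times Curve evaluation grid for the fitted trajectory.
#' @method autoplot tau_calibration
#' @export
autoplot.tau_calibration <- function(object, times = NULL, ...) {
  obs <- object$predicted
  times <- times %||% seq(0, max(obs$time_days) * 1.2, length.out = 200)
  curve <- kjma_trajectory(times, object$params, object$alpha)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$time_days, y = .data$x)
    ) +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$time_days, y = .data$tau_at_percent),
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = "Time post injury (days)", y = "Tau burden (AT%)",
      title = "Calibrated Avrami curve vs observations",
      subtitle = sprintf("RMSE %.3g, R² %.5f", object$rmse, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tau_map
#' @param object A `tau_field` object.
#' @method autoplot tau_field
#' @export
autoplot.tau_field <- function(object, ...) {
  long <- tidy(object)
  qs <- dplyr::summarise(
    dplyr::group_by(long, .data$time_days),
    q10 = stats::quantile(.data$tau, 0.1),
    q90 = stats::quantile(.data$tau, 0.9),
    mean_tau = mean(.data$tau),
    max_tau = max(.data$tau),
    .groups = "drop"
  )
  ggplot2::ggplot(qs, ggplot2::aes(x = .data$time_days)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_tau), colour = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$max_tau), colour = "firebrick", linetype = "dotted"
    ) +
    ggplot2::labs(
      x = "Time post injury (days)", y = "Nodal tau (AT%)",
      title = "Spatial tau field over time",
      subtitle = "Mean (solid, equals homogeneous X), 10-90% band, nodal max (dotted)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot remaining tissue volume under atrophy
#'
#' @param volume_series A [remaining_volume()] tibble.
#' @return A ggplot object.
#' @export
plot_remaining_volume <- function(volume_series) {
  ggplot2::ggplot(
    volume_series,
    ggplot2::aes(x = .data$time_days, y = .data$volume_mm3)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Time post injury (days)", y = "Remaining tissue volume (mm³)",
      title = "Atrophy surrogate: tissue volume over time"
    ) +
    ggplot2::theme_minimal()
}
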