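#' Plot a reach simulation
#'
#' Position and velocity of each joint against time, with the planned
#' minimum-jerk trajectory dashed. Angles in degrees.
#'
#' @param object A [simulate_reach()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reach_sim <- function(object, ...) {
  long <- tidy(object)
  keep <- c(q = "actual", qd = "planned", qdot = "actual", qd_dot = "planned")
  d <- dplyr::filter(long, .data$signal %in% names(keep))
  d$panel <- ifelse(d$signal %in% c("q", "qd"), "position (deg)",
                    "velocity (deg/s)")
  d$series <- keep[d$signal]
  d$value <- rad2deg(d$value)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value,
                                  colour = factor(.data$joint),
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::scale_linetype_manual(values = c(actual = "solid",
                                              planned = "dashed")) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "joint",
                  linetype = NULL,
                  title = sprintf("%s controller", object$controller$type)) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Two-axis sweeps (TDE gain x stiffness) render as an RMSE heatmap;
#' one-axis sweeps (delay estimate) as a point-line profile.
#'
#' @param object A `reach_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reach_sweep <- function(object, ...) {
  axes <- attr(object, "axes")
  if (length(axes) == 2L) {
    ggplot2::ggplot(object, ggplot2::aes(factor(.data$beta_bar),
                                         factor(.data$kp),
                                         fill = .data$rmse_deg)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(na.value = "grey30") +
      ggplot2::labs(x = "TDE gain (kg m²)", y = "Kp (1/s²)",
                    fill = "RMSE (deg)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[axes]],
                                         .data$endpoint_error_deg)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = axes, y = "endpoint error (deg)") +
      ggplot2::theme_minimal()
  }
}

#' Hand-path plot for a two-joint reach
#'
#' The simulated Cartesian hand path with the planned straight line.
#'
#' @param sim A two-joint Cartesian-task [simulate_reach()] result.
#' @return A ggplot object.
#' @export
plot_hand_path <- function(sim) {
  stopifnot(inherits(sim, "reach_sim"), sim$task$space == "cartesian")
  qs <- cbind(sim$signals$q_1, sim$signals$q_2)
  hand <- t(apply(qs, 1L, forward_kinematics, params = sim$plant))
  d <- tibble::tibble(x = hand[, 1], y = hand[, 2])
  line <- tibble::tibble(x = c(sim$task$from[1], sim$task$to[1]),
                         y = c(sim$task$from[2], sim$task$to[2]))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_line(data = line, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
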