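#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reach simulation
#'
#' Pivots the tick-indexed signal table to long form: one row per time,
#' signal and joint.
#'
#' @param x A [simulate_reach()] result.
#' @param ... Unused.
#' @return A tibble with columns `time`, `signal`, `joint`, `value`.
#' @export
tidy.reach_sim <- function(x, ...) {
  tidyr::pivot_longer(x$signals, -"time",
                      names_to = c("signal", "joint"),
                      names_pattern = "^(.*)_([0-9]+)$",
                      names_transform = list(joint = as.integer))
}

#' One-row summary of a reach simulation
#'
#' @param x A [simulate_reach()] result.
#' @param ... Unused.
#' @return A one-row tibble: controller type, joint count, divergence flag,
#'   final joint angle(s) in degrees and, for single-joint runs, the
#'   endpoint error relative to the task target.
#' @export
glance.reach_sim <- function(x, ...) {
  n <- n_joints(x$plant)
  last <- x$signals[nrow(x$signals), ]
  out <- tibble::tibble(
    controller = x$controller$type,
    n_joints = n,
    diverged = x$diverged,
    horizon_s = x$config$horizon,
    dt_s = x$config$dt,
    td_ms = 1000 * x$config$td
  )
  for (j in seq_len(n)) {
    out[[paste0("final_q", j, "_deg")]] <- rad2deg(last[[paste0("q_", j)]])
  }
  if (n == 1L && x$task$space == "joint" && !x$diverged) {
    out$endpoint_error_deg <- rad2deg(abs(last$q_1 - x$task$to[1]))
  }
  out
}
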