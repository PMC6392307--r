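#' Delay line for sensed and estimated signals
#'
#' A time-indexed record of vector samples with an initial-value pre-history:
#' queries at or before time zero return the initial value (the quiescent
#' state held before movement onset), queries between stored samples are
#' linearly interpolated, and queries beyond the newest stored sample are a
#' contract violation (a delay line never extrapolates into the future).
#'
#' @param init Initial-value vector returned for `t <= 0`.
#' @param times Strictly increasing numeric vector of sample times (may be
#'   empty).
#' @param samples Matrix with `length(times)` rows of samples, or a vector
#'   for a scalar signal.
#' @return An object of class `delay_line`.
#' @examples
#' dl <- delay_line(0, times = c(0.1, 0.2), samples = c(0.2, 0.4)) # f(t) = 2t
#' delay_query(dl, 0.15) # 0.3
#' @export
delay_line <- function(init, times = numeric(0), samples = NULL) {
  init <- as.numeric(init)
  if (length(times)) {
    if (is.null(dim(samples))) samples <- matrix(samples, ncol = length(init))
    stopifnot(nrow(samples) == length(times), ncol(samples) == length(init))
    if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  } else {
    samples <- matrix(numeric(0), 0L, length(init))
  }
  structure(list(init = init, times = as.numeric(times), samples = samples),
            class = "delay_line")
}

#' @rdname delay_line
#' @param line A `delay_line`.
#' @param t Sample time to append (must exceed the newest stored time) or to
#'   query.
#' @param x Sample vector to append.
#' @export
delay_push <- function(line, t, x) {
  stopifnot(inherits(line, "delay_line"))
  if (length(line$times) && t <= line$times[length(line$times)]) {
    stop("samples must be pushed in strictly increasing time order", call. = FALSE)
  }
  line$times <- c(line$times, t)
  line$samples <- rbind(line$samples, as.numeric(x))
  line
}

#' @rdname delay_line
#' @export
delay_query <- function(line, t) {
  stopifnot(inherits(line, "delay_line"))
  newest <- if (length(line$times)) line$times[length(line$times)] else 0
  if (t > newest + 1e-12) {
    stop(sprintf("delay line queried at t = %g but newest sample is at t = %g",
                 t, newest), call. = FALSE)
  }
  if (t <= 0 || !length(line$times)) return(line$init)
  i <- findInterval(t, line$times)
  if (i == 0L) {
    # between the pre-history (value init, up to t = 0) and the first sample
    t0 <- 0; x0 <- line$init
  } else {
    t0 <- line$times[i]; x0 <- line$samples[i, ]
  }
  if (i == length(line$times) || abs(t - t0) < 1e-12) return(x0)
  t1 <- line$times[i + 1L]; x1 <- line$samples[i + 1L, ]
  w <- (t - t0) / (t1 - t0)
  (1 - w) * x0 + w * x1
}

# Fast uniform-grid history query used by the simulation engine. `mat` holds
# one sample per controller tick (row r is time (r-1)*dt), `kfill` rows are
# valid. Pre-history (t <= 0) returns `init`; queries beyond the newest
# filled row clamp to it (used only for the acceleration history, whose
# newest sample lags the state histories by one tick).
grid_query <- function(mat, kfill, tq, dt, init) {
  if (tq <= 0 || kfill == 0L) return(init)
  idx <- tq / dt + 1
  if (idx >= kfill) return(mat[kfill, ])
  i0 <- floor(idx)
  frac <- idx - i0
  if (frac < 1e-9) return(mat[i0, ])
  (1 - frac) * mat[i0, ] + frac * mat[i0 + 1L, ]
}
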