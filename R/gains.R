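#' Gains of the TDC-family controllers
#'
#' Diagonal gain set shared by plain time-delay control and the
#' Smith-architecture controller: the TDE estimation gain `beta_bar`
#' (kg m^2 scale; plays the role of an assumed inertia), the velocity gain
#' `Kv` (1/s) and the position gain `Kp` (1/s^2) of the desired error
#' dynamics \eqn{\ddot e + K_v \dot e + K_p e = 0}. All entries must be
#' positive. Stability of the TDE loop additionally requires each
#' `beta_bar` entry to be below twice the corresponding plant inertia; that
#' is a run-time property checked by [stability_margin()], not enforced
#' here.
#'
#' @param beta_bar,kv,kp Numeric vectors of diagonal entries (length 1 or 2,
#'   recycled to a common length).
#' @return An object of class `tdc_gains`.
#' @examples
#' tdc_gains(beta_bar = 0.01, kv = 200, kp = 500)
#' @export
tdc_gains <- function(beta_bar, kv, kp) {
  n <- max(length(beta_bar), length(kv), length(kp))
  beta_bar <- rep_len(as.numeric(beta_bar), n)
  kv <- rep_len(as.numeric(kv), n)
  kp <- rep_len(as.numeric(kp), n)
  if (any(c(beta_bar, kv, kp) <= 0)) {
    stop("all tdc_gains entries must be strictly positive", call. = FALSE)
  }
  structure(list(beta_bar = beta_bar, kv = kv, kp = kp), class = "tdc_gains")
}

#' Gains of the delayed equilibrium-point controller
#'
#' Proportional (`p`, position loop) and derivative (`d`, velocity loop)
#' feedback acting on delayed sensory signals, each loop with its own delay.
#'
#' @param p,d Feedback gains (>= 0).
#' @param t_dp,t_dv Position- and velocity-loop delays in seconds (>= 0).
#' @return An object of class `ep_gains`.
#' @export
ep_gains <- function(p = 0, d = 0.76, t_dp = 0.065, t_dv = 0.025) {
  if (any(c(p, d) < 0)) stop("gains must be >= 0", call. = FALSE)
  if (any(c(t_dp, t_dv) < 0)) stop("delays must be >= 0", call. = FALSE)
  structure(list(p = p, d = d, t_dp = t_dp, t_dv = t_dv), class = "ep_gains")
}

#' Steady-state LQ feedback gain
#'
#' Solves the continuous-time infinite-horizon linear-quadratic problem
#' \eqn{\min \int e^T Q e + u^T R u \, dt} for the pair `(A, B)` via the
#' stabilizing solution of the algebraic Riccati equation, computed with the
#' Hamiltonian-eigenvector method. Returns `K = R^-1 B^T P`.
#'
#' @param A,B State and input matrices.
#' @param Q State-weighting matrix (positive semidefinite).
#' @param R Input-weighting matrix (positive definite).
#' @return List with the gain matrix `K`, the Riccati solution `P` and the
#'   Frobenius norm of the Riccati residual (`residual`).
#' @examples
#' # double integrator, Q = I, R = 1: K = c(1, sqrt(3))
#' lqr_gain(matrix(c(0, 0, 1, 0), 2), matrix(c(0, 1)), diag(2), 1)$K
#' @export
lqr_gain <- function(A, B, Q, R) {
  A <- as.matrix(A); B <- as.matrix(B)
  Q <- as.matrix(Q); R <- as.matrix(R)
  n <- nrow(A)
  Rinv <- solve(R)
  if (all(Q == 0)) {
    # zero state cost: P = 0 solves the Riccati equation and K = 0
    return(list(K = matrix(0, ncol(B), n), P = matrix(0, n, n), residual = 0))
  }
  H <- rbind(cbind(A, -B %*% Rinv %*% t(B)),
             cbind(-Q, -t(A)))
  eg <- eigen(H)
  stable <- which(Re(eg$values) < 0)
  if (length(stable) != n) {
    stop("no stabilizing Riccati solution: (A, B) may not be stabilizable",
         call. = FALSE)
  }
  V <- eg$vectors[, stable, drop = FALSE]
  X <- V[seq_len(n), , drop = FALSE]
  Y <- V[n + seq_len(n), , drop = FALSE]
  P <- Re(Y %*% solve(X))
  P <- (P + t(P)) / 2
  K <- Rinv %*% t(B) %*% P
  res <- t(A) %*% P + P %*% A - P %*% B %*% Rinv %*% t(B) %*% P + Q
  list(K = K, P = P, residual = sqrt(sum(res^2)))
}

#' LQ optimal-control setup for the single-joint limb
#'
#' Builds the state-space limb model \eqn{A_s = [0, 1; 0, 0]},
#' \eqn{B_s = [0; 1/J]} (viscoelasticity neglected) together with the
#' steady-state LQ feedback gain for the error state
#' `(qd - qhat, qd_dot - qhat_dot)`. The inertia `J` here is the model the
#' controller *believes*; experiments on unexpected load changes run it
#' against a plant with a different inertia.
#'
#' @param Q State-weighting matrix, or a scalar/length-2 vector taken as the
#'   diagonal.
#' @param R Input weight (scalar).
#' @param J Modelled limb inertia (kg m^2).
#' @return Object of class `lq_setup` with fields `As`, `Bs`, `Q`, `R`, `K`,
#'   `J`, `riccati_residual`.
#' @export
lq_setup <- function(Q = diag(c(10, 10)), R = 2, J = 0.0188) {
  if (!is.matrix(Q)) Q <- diag(rep_len(as.numeric(Q), 2L), 2L)
  As <- matrix(c(0, 0, 1, 0), 2L, 2L)
  Bs <- matrix(c(0, 1 / J), 2L, 1L)
  sol <- lqr_gain(As, Bs, Q, R)
  if (sol$residual >= 1e-8) {
    stop("Riccati residual too large; LQ solution unreliable", call. = FALSE)
  }
  structure(list(As = As, Bs = Bs, Q = Q, R = R, J = J,
                 K = sol$K, riccati_residual = sol$residual),
            class = "lq_setup")
}
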