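#' Generalized forces along a trajectory
#'
#' Evaluates the Euler--Lagrange left-hand side
#' \eqn{\frac{d}{dt}\frac{\partial L}{\partial\dot\theta_i} -
#' \frac{\partial L}{\partial\theta_i}} for the point-mass chain Lagrangian
#' \eqn{L = E_{kinetic} - E_{position}} along a trajectory, in closed form.
#' For a chain of point masses the left-hand side collapses to the
#' Jacobian-transpose form
#' \deqn{Q_i = \sum_k m_k\Big(\ddot x_k \frac{\partial x_k}{\partial\theta_i}
#'  + (\ddot y_k + g)\frac{\partial y_k}{\partial\theta_i}\Big),}
#' which is what is assembled here (mass-matrix, centrifugal and gravity
#' terms all included through the analytic centroid accelerations). At a
#' frozen configuration \eqn{Q_i} reduces to the gravitational term
#' \eqn{\partial E_{position}/\partial\theta_i}.
#'
#' @param chain A \code{\link{build_chain}} result.
#' @param theta,dtheta,ddtheta Coordinate series (samples x coordinates
#'   matrices, or vectors for one sample): angles (rad), angular velocities
#'   (rad/s) and accelerations (rad/s^2).
#' @return Matrix of generalized forces, samples x coordinates (N m).
#' @export
generalized_forces <- function(chain, theta, dtheta, ddtheta) {
  stopifnot(inherits(chain, "lagrangian_chain"))
  k <- length(chain$coords)
  theta <- as_theta_matrix(theta, k)
  dtheta <- as_theta_matrix(dtheta, k)
  ddtheta <- as_theta_matrix(ddtheta, k)
  stopifnot(all(dim(dtheta) == dim(theta)), all(dim(ddtheta) == dim(theta)))
  sn <- sin(theta); cs <- cos(theta)
  Q <- matrix(0, nrow(theta), k, dimnames = list(NULL, chain$coords))
  for (ki in seq_along(chain$m)) {
    a <- chain$A[ki, ]; cc <- chain$C[ki, ]
    xdd <- (cs * ddtheta - sn * dtheta^2) %*% a
    ydd <- -(sn * ddtheta + cs * dtheta^2) %*% cc
    # dx_k/dtheta_i = A[k,i] cos(theta_i); dy_k/dtheta_i = -C[k,i] sin(theta_i)
    Q <- Q + chain$m[ki] *
      (drop(xdd) * sweep(cs, 2, a, `*`) -
         drop(ydd + chain$g) * sweep(sn, 2, cc, `*`))
  }
  Q
}

# wrap Q with moment bookkeeping into a moment_series data frame
moment_frame <- function(times, cols, body_mass) {
  df <- data.frame(time = times, cols, check.names = FALSE)
  attr(df, "body_mass") <- body_mass
  class(df) <- c("moment_series", "data.frame")
  df
}

#' Joint moments in single support
#'
#' Solves the triangular moment chain of the three-link model: the swing-knee
#' moment equals the shank-coordinate generalized force, the swing-hip moment
#' follows from the thigh coordinate, and the stance-ankle moment from the
#' stance-rod coordinate:
#' \deqn{M_k = Q_3,\quad M_{h2} = M_k - Q_2,\quad M_a = M_{h2} - Q_1.}
#'
#' @param chain The \code{"single_support"} chain from \code{\link{build_chain}}.
#' @param states Matching \code{"segment_states"} from
#'   \code{\link{chain_states_single}}.
#' @return A \code{"moment_series"} data frame: \code{time},
#'   \code{stance_ankle}, \code{swing_hip}, \code{swing_knee} (N m) and
#'   body-mass-normalised \code{_nmkg} copies.
#' @export
single_support_moments <- function(chain, states) {
  check_chain_states(chain, states, "single_support")
  Q <- generalized_forces(chain, states$theta, states$dtheta, states$ddtheta)
  M_k <- Q[, 3]
  M_h2 <- M_k - Q[, 2]
  M_a <- M_h2 - Q[, 1]
  bm <- chain$segments$body_mass
  moment_frame(states$times,
               data.frame(stance_ankle = M_a, swing_hip = M_h2,
                          swing_knee = M_k,
                          stance_ankle_nmkg = M_a / bm,
                          swing_hip_nmkg = M_h2 / bm,
                          swing_knee_nmkg = M_k / bm),
               bm)
}

#' Joint moments in double support
#'
#' Solves the two-link moment chain: the leading-leg ankle moment equals the
#' leading-rod generalized force and the trailing-leg hip moment follows from
#' the trailing-rod coordinate:
#' \deqn{M_a^{leading} = Q_{2d},\quad M_h^{trailing} = M_a^{leading} - Q_{1d}.}
#'
#' @param chain The \code{"double_support"} chain from \code{\link{build_chain}}.
#' @param states Matching \code{"segment_states"} from
#'   \code{\link{chain_states_double}}.
#' @return A \code{"moment_series"} data frame: \code{time},
#'   \code{leading_ankle}, \code{trailing_hip} (N m) and \code{_nmkg} copies.
#' @export
double_support_moments <- function(chain, states) {
  check_chain_states(chain, states, "double_support")
  Q <- generalized_forces(chain, states$theta, states$dtheta, states$ddtheta)
  M_a_lead <- Q[, 2]
  M_h_trail <- M_a_lead - Q[, 1]
  bm <- chain$segments$body_mass
  moment_frame(states$times,
               data.frame(leading_ankle = M_a_lead, trailing_hip = M_h_trail,
                          leading_ankle_nmkg = M_a_lead / bm,
                          trailing_hip_nmkg = M_h_trail / bm),
               bm)
}

check_chain_states <- function(chain, states, phase) {
  stopifnot(inherits(chain, "lagrangian_chain"),
            inherits(states, "segment_states"))
  if (chain$phase != phase || states$phase != phase)
    stop("chain and states must both be for the ", phase, " phase")
  invisible(TRUE)
}

#' Stance-knee moment from ankle and hip moments
#'
#' The stance leg is modelled as one rigid rod, so its knee moment is not a
#' free coordinate; it is recovered from the stance ankle and hip moments by
#' the lever-arm decomposition
#' \deqn{M_k^{stand} = M_a^{stand}\,\frac{l_3}{l_1} +
#'   M_h^{stand}\,\frac{l_2}{l_1},}
#' applied identically in the single- and double-support stance sub-phases.
#'
#' @param ankle Stance-ankle moment series (N m).
#' @param hip Stance-hip moment series (N m), same length.
#' @param segments A \code{\link{build_segment_set}} result (supplies the
#'   segment lengths).
#' @return Numeric vector of stance-knee moments (N m).
#' @export
stance_knee_moment <- function(ankle, hip, segments) {
  stopifnot(inherits(segments, "segment_set"),
            is.numeric(ankle), is.numeric(hip),
            length(ankle) == length(hip))
  ankle * segments$l_3 / segments$l_1 + hip * segments$l_2 / segments$l_1
}
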