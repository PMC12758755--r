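#' Absolute segment angles from joint angles
#'
#' Maps hip and knee joint-angle series to absolute segment angles measured
#' from the vertical. With zero pelvic tilt the thigh angle equals the hip
#' angle, and the shank angle is the thigh angle minus the knee flexion
#' angle. All angles follow one convention: measured from the vertical,
#' positive when the distal end of the segment lies anterior to its proximal
#' end.
#'
#' @param hip Hip joint angle series (radians), or a list with elements
#'   \code{th}, \code{d1}, \code{d2} to propagate derivatives.
#' @param knee Knee joint angle series, same form and length as \code{hip}.
#' @return A list with elements \code{thigh} and \code{shank}; each is a
#'   numeric vector, or a list of \code{th}/\code{d1}/\code{d2} vectors when
#'   derivative series were supplied.
#' @examples
#' segment_angles_from_joints(hip = 0.3, knee = 0.5)
#' @export
segment_angles_from_joints <- function(hip, knee) {
  if (is.list(hip) || is.list(knee)) {
    stopifnot(is.list(hip), is.list(knee),
              all(c("th", "d1", "d2") %in% names(hip)),
              all(c("th", "d1", "d2") %in% names(knee)))
    if (length(hip$th) != length(knee$th))
      stop("hip and knee series must share a time grid")
    return(list(
      thigh = hip,
      shank = list(th = hip$th - knee$th,
                   d1 = hip$d1 - knee$d1,
                   d2 = hip$d2 - knee$d2)))
  }
  stopifnot(is.numeric(hip), is.numeric(knee))
  if (length(hip) != length(knee))
    stop("hip and knee series must share a time grid")
  list(thigh = hip, shank = hip - knee)
}

# ---------------------------------------------------------------------------
# Generic planar point-mass chain.
#
# Every point mass k in both phase models has coordinates of the form
#   x_k = sum_i A[k, i] * sin(theta_i),   y_k = sum_i C[k, i] * cos(theta_i)
# for constant coefficient matrices A and C determined by the segment
# lengths and centroid offsets. The A/C representation makes positions,
# velocities, accelerations, configuration Jacobians and chain energies all
# one-liners, shared between the single- and double-support models.
# ---------------------------------------------------------------------------

#' Build the Lagrangian point-mass chain for a support phase
#'
#' Constructs the planar chain of point masses used by both the ground
#' reaction force and the inverse-dynamics computations. Single support is a
#' three-coordinate chain (stance rod, swing thigh, swing shank) carrying
#' four point masses: the lumped stance-leg mass at its rod centroid, the
#' trunk-head-arms mass at the hip (the rod tip), and the swing thigh and
#' shank masses at their centroids. Double support is a two-coordinate chain
#' (trailing rod, leading rod) with three point masses: trailing-leg mass,
#' trunk mass at the hip, and leading-leg mass at distance \code{p_2d} from
#' the hip. Kinetic energy is the point-mass sum
#' \eqn{\frac12 \sum m_k (\dot x_k^2 + \dot y_k^2)}; potential energy is
#' \eqn{\sum m_k g y_k} with the ground contact as the zero level. Segments
#' carry no rotational inertia about their own centroids.
#'
#' @param phase \code{"single_support"} or \code{"double_support"}.
#' @param segments A \code{\link{build_segment_set}} result.
#' @return An object of class \code{"lagrangian_chain"}: a list with the
#'   phase, coordinate names, point-mass vector \code{m}, coefficient
#'   matrices \code{A} and \code{C}, and \code{g}.
#' @export
build_chain <- function(phase, segments) {
  phase <- match.arg(phase, c("single_support", "double_support"))
  stopifnot(inherits(segments, "segment_set"))
  s <- segments
  m_leg <- s$m_t + s$m_s
  if (phase == "single_support") {
    # coords: theta_1 (stance rod), theta_2 (swing thigh), theta_3 (swing shank)
    masses <- c(stance_leg = m_leg, trunk = s$m,
                swing_thigh = s$m_t, swing_shank = s$m_s)
    A <- rbind(stance_leg  = c(s$p_1, 0, 0),
               trunk       = c(s$l_1, 0, 0),
               swing_thigh = c(s$l_1, s$p_2, 0),
               swing_shank = c(s$l_1, s$l_2, s$p_3))
    C <- rbind(stance_leg  = c(s$p_1, 0, 0),
               trunk       = c(s$l_1, 0, 0),
               swing_thigh = c(s$l_1, -s$p_2, 0),
               swing_shank = c(s$l_1, -s$l_2, -s$p_3))
    coords <- c("theta_1", "theta_2", "theta_3")
  } else {
    # coords: theta_1d (trailing rod), theta_2d (leading rod)
    masses <- c(trailing_leg = m_leg, trunk = s$m, leading_leg = m_leg)
    A <- rbind(trailing_leg = c(s$p_1, 0),
               trunk        = c(s$l_1, 0),
               leading_leg  = c(s$l_1, s$p_2d))
    C <- rbind(trailing_leg = c(s$p_1, 0),
               trunk        = c(s$l_1, 0),
               leading_leg  = c(s$l_1, -s$p_2d))
    coords <- c("theta_1d", "theta_2d")
  }
  structure(list(phase = phase, coords = coords, m = masses,
                 A = A, C = C, g = s$g, segments = s),
            class = "lagrangian_chain")
}

# Coerce theta input (vector for 1 sample, or n x k matrix) to a matrix.
as_theta_matrix <- function(theta, k) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = k)
  if (ncol(theta) != k)
    stop("expected ", k, " coordinate columns, got ", ncol(theta))
  theta
}

#' Chain energies
#'
#' Evaluate kinetic and potential energy of a chain at given configurations.
#' Exposed so energy-based cross-checks can be run against the inverse
#' dynamics without touching its internals.
#'
#' @param chain A \code{\link{build_chain}} result.
#' @param theta,dtheta Configuration and angular-velocity matrices
#'   (samples x coordinates), or vectors for a single sample.
#' @return A list with numeric vectors \code{kinetic} and \code{position}
#'   (joules per sample).
#' @export
chain_energy <- function(chain, theta, dtheta) {
  stopifnot(inherits(chain, "lagrangian_chain"))
  k <- length(chain$coords)
  theta <- as_theta_matrix(theta, k)
  dtheta <- as_theta_matrix(dtheta, k)
  n <- nrow(theta)
  kin <- numeric(n)
  pos <- numeric(n)
  for (ki in seq_along(chain$m)) {
    xd <- (cos(theta) * dtheta) %*% chain$A[ki, ]
    yd <- -(sin(theta) * dtheta) %*% chain$C[ki, ]
    y <- cos(theta) %*% chain$C[ki, ]
    kin <- kin + 0.5 * chain$m[ki] * (xd^2 + yd^2)
    pos <- pos + chain$m[ki] * chain$g * y
  }
  list(kinetic = drop(kin), position = drop(pos))
}

# Core state builder: positions/velocities/accelerations of every point mass.
chain_states <- function(chain, times, theta, dtheta, ddtheta) {
  k <- length(chain$coords)
  theta <- as_theta_matrix(theta, k)
  dtheta <- as_theta_matrix(dtheta, k)
  ddtheta <- as_theta_matrix(ddtheta, k)
  stopifnot(nrow(theta) == length(times),
            all(dim(dtheta) == dim(theta)), all(dim(ddtheta) == dim(theta)))
  sn <- sin(theta); cs <- cos(theta)
  K <- length(chain$m)
  mk_mat <- function() matrix(0, nrow(theta), K,
                              dimnames = list(NULL, names(chain$m)))
  x <- mk_mat(); y <- mk_mat(); xd <- mk_mat(); yd <- mk_mat()
  xdd <- mk_mat(); ydd <- mk_mat()
  for (ki in seq_len(K)) {
    a <- chain$A[ki, ]; cc <- chain$C[ki, ]
    x[, ki] <- sn %*% a
    y[, ki] <- cs %*% cc
    xd[, ki] <- (cs * dtheta) %*% a
    yd[, ki] <- -(sn * dtheta) %*% cc
    xdd[, ki] <- (cs * ddtheta - sn * dtheta^2) %*% a
    ydd[, ki] <- -(sn * ddtheta + cs * dtheta^2) %*% cc
  }
  structure(list(phase = chain$phase, times = times,
                 theta = theta, dtheta = dtheta, ddtheta = ddtheta,
                 x = x, y = y, xd = xd, yd = yd, xdd = xdd, ydd = ydd,
                 chain = chain),
            class = "segment_states")
}

#' Point-mass states of the single-support chain
#'
#' Computes centroid positions, velocities and accelerations of every point
#' mass of the three-link single-support model on a common time grid, with
#' the stance-foot contact as origin (x anterior, y up). Velocities and
#' accelerations are analytic derivatives of the position map, never numeric
#' differences.
#'
#' @param times Time grid (s).
#' @param theta1,theta2,theta3 Angle series for the stance rod, swing thigh
#'   and swing shank: each a list with elements \code{th}, \code{d1},
#'   \code{d2} (rad, rad/s, rad/s^2), or a plain numeric vector (derivatives
#'   then taken as zero, a static configuration).
#' @param segments A \code{\link{build_segment_set}} result.
#' @return An object of class \code{"segment_states"}: matrices \code{x},
#'   \code{y}, \code{xd}, \code{yd}, \code{xdd}, \code{ydd} with one column
#'   per point mass (\code{stance_leg}, \code{trunk}, \code{swing_thigh},
#'   \code{swing_shank}), plus the coordinate series.
#' @export
chain_states_single <- function(times, theta1, theta2, theta3, segments) {
  ang <- normalise_angle_inputs(list(theta1, theta2, theta3), length(times))
  chain <- build_chain("single_support", segments)
  chain_states(chain, times, ang$th, ang$d1, ang$d2)
}

#' Point-mass states of the double-support chain
#'
#' As \code{\link{chain_states_single}} for the two-link double-support
#' model: trailing rod anchored at its ground contact (the origin), trunk at
#' the rod tip (hip), leading-leg centroid at \code{p_2d} from the hip along
#' the leading rod. Point-mass columns are \code{trailing_leg}, \code{trunk},
#' \code{leading_leg}.
#'
#' @param times Time grid (s).
#' @param theta1d,theta2d Trailing- and leading-rod angle series (same forms
#'   as in \code{\link{chain_states_single}}).
#' @param segments A \code{\link{build_segment_set}} result.
#' @return A \code{"segment_states"} object.
#' @export
chain_states_double <- function(times, theta1d, theta2d, segments) {
  ang <- normalise_angle_inputs(list(theta1d, theta2d), length(times))
  chain <- build_chain("double_support", segments)
  chain_states(chain, times, ang$th, ang$d1, ang$d2)
}

normalise_angle_inputs <- function(lst, n) {
  one <- function(a) {
    if (is.list(a)) {
      stopifnot(all(c("th", "d1", "d2") %in% names(a)))
      a
    } else {
      list(th = a, d1 = numeric(length(a)), d2 = numeric(length(a)))
    }
  }
  lst <- lapply(lst, one)
  lens <- unlist(lapply(lst, function(a) lengths(a[c("th", "d1", "d2")])))
  if (any(lens != n))
    stop("angle series must all match the time grid length (", n, ")")
  list(th = do.call(cbind, lapply(lst, `[[`, "th")),
       d1 = do.call(cbind, lapply(lst, `[[`, "d1")),
       d2 = do.call(cbind, lapply(lst, `[[`, "d2")))
}

#' @export
print.segment_states <- function(x, ...) {
  cat(sprintf("Segment states: %s, %d samples, masses: %s\n",
              x$phase, length(x$times), paste(colnames(x$x), collapse = ", ")))
  invisible(x)
}

#' Export segment states as a long data frame
#'
#' @param x A \code{"segment_states"} object.
#' @param row.names,optional Unused, for the generic.
#' @param ... Unused.
#' @return Long data frame: \code{time}, \code{phase}, \code{segment},
#'   \code{quantity} (x, y, xd, yd, xdd, ydd), \code{value}.
#' @export
as.data.frame.segment_states <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  qs <- c("x", "y", "xd", "yd", "xdd", "ydd")
  out <- do.call(rbind, lapply(qs, function(q) {
    m <- x[[q]]
    data.frame(time = rep(x$times, ncol(m)),
               phase = x$phase,
               segment = rep(colnames(m), each = nrow(m)),
               quantity = q,
               value = as.vector(m))
  }))
  rownames(out) <- NULL
  out
}
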