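# Shared fixtures and independent numerical oracles.
#
# Every oracle here works only from first principles (finite differences,
# closed forms, normal equations) and never calls the production code path
# it is used to check.

toy_table <- function(...) {
  args <- list(thigh_mass_fraction = 0.10,
               shank_mass_fraction = 0.05,
               thigh_length_fraction = 0.53,
               thigh_centroid_fraction = 0.45,
               shank_centroid_fraction = 0.40)
  over <- list(...)
  args[names(over)] <- over
  do.call(anthropometric_table, args)
}

toy_subject <- function(leg_length = 1, body_mass = 60, cadence = 1) {
  subject_params(leg_length, body_mass, cadence)
}

toy_segments <- function(subject = toy_subject(), table = toy_table()) {
  build_segment_set(subject, table)
}

# random Fourier coefficient set of plausible gait-like magnitude
rand_model <- function(joint = "hip", n = 3) {
  fourier_angle_model(joint,
                      B = c(stats::runif(1, -0.2, 0.5),
                            stats::runif(n, -0.4, 0.4)),
                      phi = stats::runif(n, -pi / 2, pi / 2))
}

# angle state triple from a model (th, d1, d2 at times t)
model_state <- function(model, subject, t, side = "left") {
  d <- angle_derivatives(model, subject, t, side)
  list(th = evaluate_angle(model, subject, t, side), d1 = d$d1, d2 = d$d2)
}

# --- finite-difference trajectory oracles ----------------------------------

# positions of all point masses at times t, for theta given by model list
states_at <- function(phase, t, models, subject, segments, side = "left") {
  sts <- lapply(models, model_state, subject = subject, t = t, side = side)
  if (phase == "single_support") {
    chain_states_single(t, sts[[1]], sts[[2]], sts[[3]], segments)
  } else {
    chain_states_double(t, sts[[1]], sts[[2]], segments)
  }
}

# central finite differences of position matrices: velocity and acceleration.
# The second difference uses a larger step (default 100*h): with h ~ 1e-6*T
# the rounding error eps/h^2 would swamp the 1e-5 tolerance, while the
# truncation error at 1e-4*T stays ~1e-8 relative.
fd_states <- function(phase, t, models, subject, segments, h, h2 = 100 * h) {
  sp <- states_at(phase, t + h, models, subject, segments)
  sm <- states_at(phase, t - h, models, subject, segments)
  s0 <- states_at(phase, t, models, subject, segments)
  sp2 <- states_at(phase, t + h2, models, subject, segments)
  sm2 <- states_at(phase, t - h2, models, subject, segments)
  list(xd = (sp$x - sm$x) / (2 * h), yd = (sp$y - sm$y) / (2 * h),
       xdd = (sp2$x - 2 * s0$x + sm2$x) / h2^2,
       ydd = (sp2$y - 2 * s0$y + sm2$y) / h2^2)
}

# --- energy-only Euler-Lagrange oracle -------------------------------------
# Uses nothing but chain_energy: L(theta, dtheta) = E_kin - E_pos;
# Q_i = d/dt (dL/dthetadot_i) - dL/dtheta_i, every derivative numeric.
el_oracle <- function(chain, theta_fun, dtheta_fun, t, h = 1e-5) {
  k <- length(chain$coords)
  L <- function(th, dth) {
    e <- chain_energy(chain, th, dth)
    e$kinetic - e$position
  }
  dL_ddth <- function(tt) {
    th <- theta_fun(tt); dth <- dtheta_fun(tt)
    vapply(seq_len(k), function(i) {
      e <- rep(0, k); e[i] <- h
      (L(th, dth + e) - L(th, dth - e)) / (2 * h)
    }, numeric(1))
  }
  dL_dth <- function(tt) {
    th <- theta_fun(tt); dth <- dtheta_fun(tt)
    vapply(seq_len(k), function(i) {
      e <- rep(0, k); e[i] <- h
      (L(th + e, dth) - L(th - e, dth)) / (2 * h)
    }, numeric(1))
  }
  (dL_ddth(t + h) - dL_ddth(t - h)) / (2 * h) - dL_dth(t)
}

# --- forward dynamics (for the energy-conservation property) ---------------
# Unforced motion: solve Q(theta, dtheta, ddtheta) = 0 for ddtheta using the
# linearity of Q in ddtheta.
free_acceleration <- function(chain, theta, dtheta) {
  k <- length(chain$coords)
  h0 <- drop(generalized_forces(chain, theta, dtheta, rep(0, k)))
  Mm <- vapply(seq_len(k), function(j) {
    e <- rep(0, k); e[j] <- 1
    drop(generalized_forces(chain, theta, dtheta, e)) - h0
  }, numeric(k))
  solve(Mm, -h0)
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(expected), 1e-8)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
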