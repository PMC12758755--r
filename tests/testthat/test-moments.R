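test_that("chain energies have the required structure", {
  seg <- toy_segments()
  ch <- build_chain("single_support", seg)
  th <- c(0.2, -0.1, 0.3)
  e0 <- chain_energy(ch, th, c(0, 0, 0))
  expect_equal(e0$kinetic, 0)
  # potential at the stacked vertical configuration, by hand
  ev <- chain_energy(ch, c(0, 0, 0), c(0, 0, 0))
  expect_equal(ev$position,
               seg$g * ((seg$m_t + seg$m_s) * seg$p_1 + seg$m * seg$l_1 +
                          seg$m_t * (seg$l_1 - seg$p_2) +
                          seg$m_s * (seg$l_1 - seg$l_2 - seg$p_3)))
  # kinetic energy is quadratic in the angular velocities
  dth <- c(1.1, -0.7, 0.4)
  e1 <- chain_energy(ch, th, dth)
  e2 <- chain_energy(ch, th, 2 * dth)
  expect_equal(e2$kinetic, 4 * e1$kinetic)
  expect_equal(e2$position, e1$position)
  expect_gte(e1$kinetic, 0)
})

test_that("static generalized forces equal the gravity-torque gradient", {
  seg <- toy_segments()
  for (phase in c("single_support", "double_support")) {
    ch <- build_chain(phase, seg)
    k <- length(ch$coords)
    th <- stats::runif(k, -0.4, 0.4)
    Q <- generalized_forces(ch, th, rep(0, k), rep(0, k))
    # oracle: numeric gradient of the potential energy
    h <- 1e-7
    grad <- vapply(seq_len(k), function(i) {
      e <- rep(0, k); e[i] <- h
      (chain_energy(ch, th + e, rep(0, k))$position -
         chain_energy(ch, th - e, rep(0, k))$position) / (2 * h)
    }, numeric(1))
    expect_equal(drop(Q), grad, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a hanging single pendulum reproduces its closed-form dynamics", {
  # one-mass chain built directly: leading leg of a double chain with the
  # trailing coordinate frozen at zero contributes m p^2 thdd + m g p sin(th)
  sub <- toy_subject(1, 60, 1)
  seg <- toy_segments(sub)
  ch <- build_chain("double_support", seg)
  m_leg <- seg$m_t + seg$m_s
  th <- 0.37; dth <- 1.3; ddth <- -2.1
  Q <- generalized_forces(ch, c(0, th), c(0, dth), c(0, ddth))
  closed <- m_leg * seg$p_2d^2 * ddth + m_leg * seg$g * seg$p_2d * sin(th)
  expect_equal(Q[1, 2], closed, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("analytic generalized forces match the energy-only oracle", {
  set.seed(314)
  sub <- toy_subject(0.9, 60, 1)
  seg <- toy_segments(sub)
  for (phase in c("single_support", "double_support")) {
    ch <- build_chain(phase, seg)
    k <- length(ch$coords)
    for (rep in 1:50) {
      models <- replicate(k, rand_model(n = 2), simplify = FALSE)
      theta_fun <- function(t) vapply(models, function(m)
        evaluate_angle(m, sub, t), numeric(1))
      dtheta_fun <- function(t) vapply(models, function(m)
        angle_derivatives(m, sub, t)$d1, numeric(1))
      t0 <- stats::runif(1, 0, sub$period)
      th <- theta_fun(t0)
      dth <- dtheta_fun(t0)
      ddth <- vapply(models, function(m)
        angle_derivatives(m, sub, t0)$d2, numeric(1))
      Q <- drop(generalized_forces(ch, th, dth, ddth))
      Q_fd <- el_oracle(ch, theta_fun, dtheta_fun, t0)
      expect_rel_equal(Q, Q_fd, 1e-4, scale = max(abs(Q_fd), 1))
    }
  }
})

test_that("single-support moments solve the triangular chain", {
  set.seed(21)
  sub <- toy_subject(0.9, 60, 1)
  seg <- toy_segments(sub)
  ch <- build_chain("single_support", seg)
  models3 <- list(rand_model(), rand_model(), rand_model())
  tt <- seq(0, 0.3, length.out = 7)
  st <- states_at("single_support", tt, models3, sub, seg)
  mom <- single_support_moments(ch, st)
  Q <- generalized_forces(ch, st$theta, st$dtheta, st$ddtheta)
  expect_equal(mom$swing_knee, unname(Q[, 3]))
  expect_equal(mom$swing_knee - mom$swing_hip, unname(Q[, 2]))
  expect_equal(mom$swing_hip - mom$stance_ankle, unname(Q[, 1]))
  expect_equal(mom$swing_knee_nmkg, mom$swing_knee / 60)
})

test_that("fully vertical static chain needs no moments", {
  seg <- toy_segments()
  ch <- build_chain("single_support", seg)
  st <- chain_states_single(0, 0, 0, 0, segments = seg)
  mom <- single_support_moments(ch, st)
  expect_equal(mom$stance_ankle, 0)
  expect_equal(mom$swing_hip, 0)
  expect_equal(mom$swing_knee, 0)
})

test_that("static tilted swing shank needs its gravity torque at the knee", {
  seg <- toy_segments()
  ch <- build_chain("single_support", seg)
  th3 <- 0.25
  st <- chain_states_single(0, 0, 0, th3, segments = seg)
  mom <- single_support_moments(ch, st)
  expect_equal(mom$swing_knee, seg$m_s * seg$g * seg$p_3 * sin(th3),
               tolerance = 1e-12)
})

test_that("double-support moments solve the two-link chain and its statics", {
  seg <- toy_segments()
  ch <- build_chain("double_support", seg)
  th1 <- -0.2; th2 <- 0.3
  st <- chain_states_double(0, th1, th2, segments = seg)
  mom <- double_support_moments(ch, st)
  m_leg <- seg$m_t + seg$m_s
  # closed-form gravity torques of the two-rod system
  Q2 <- m_leg * seg$g * seg$p_2d * sin(th2)
  Q1 <- -(m_leg * seg$p_1 + seg$m * seg$l_1 + m_leg * seg$l_1) *
    seg$g * sin(th1)
  expect_equal(mom$leading_ankle, Q2, tolerance = 1e-12)
  expect_equal(mom$trailing_hip, Q2 - Q1, tolerance = 1e-12)

  st_up <- chain_states_double(0, 0, 0, segments = seg)
  mom_up <- double_support_moments(ch, st_up)
  expect_equal(mom_up$leading_ankle, 0)
  expect_equal(mom_up$trailing_hip, 0)
})

test_that("moment reconstruction round-trips through the oracle differences", {
  set.seed(77)
  sub <- toy_subject(0.9, 60, 1)
  seg <- toy_segments(sub)
  ch <- build_chain("single_support", seg)
  models3 <- list(rand_model(), rand_model(), rand_model())
  theta_fun <- function(t) vapply(models3, function(m)
    evaluate_angle(m, sub, t), numeric(1))
  dtheta_fun <- function(t) vapply(models3, function(m)
    angle_derivatives(m, sub, t)$d1, numeric(1))
  t0 <- 0.23
  st <- states_at("single_support", t0, models3, sub, seg)
  mom <- single_support_moments(ch, st)
  Q_fd <- el_oracle(ch, theta_fun, dtheta_fun, t0)
  expect_rel_equal(c(mom$swing_knee,
                     mom$swing_knee - mom$swing_hip,
                     mom$swing_hip - mom$stance_ankle),
                   Q_fd[c(3, 2, 1)], 1e-4, scale = max(abs(Q_fd), 1))
})

test_that("stance-knee decomposition is the lever-arm combination", {
  seg <- toy_segments(toy_subject(1, 60, 1))
  expect_equal(stance_knee_moment(0, 0, seg), 0)
  # equal lever arms average the two inputs
  tab_eq <- toy_table(thigh_length_fraction = 0.5)
  seg_eq <- build_segment_set(toy_subject(1, 60, 1), tab_eq)
  expect_equal(stance_knee_moment(1, 1, seg_eq), 1)
  # exact linearity with the documented coefficients
  a <- c(1.5, -2, 0); h <- c(0.5, 1, -1)
  expect_equal(stance_knee_moment(a, h, seg),
               a * seg$l_3 / seg$l_1 + h * seg$l_2 / seg$l_1)
})

test_that("unforced free fall conserves total chain energy", {
  skip_if_not_installed("deSolve")
  seg <- toy_segments(toy_subject(0.9, 60, 1))
  for (phase in c("single_support", "double_support")) {
    ch <- build_chain(phase, seg)
    k <- length(ch$coords)
    y0 <- c(stats::runif(k, -0.3, 0.3), stats::runif(k, -0.5, 0.5))
    deriv <- function(t, y, parms) {
      th <- y[seq_len(k)]; dth <- y[k + seq_len(k)]
      list(c(dth, free_acceleration(ch, th, dth)))
    }
    sol <- deSolve::ode(y0, seq(0, 0.3, length.out = 31), deriv, NULL,
                        method = "ode45", atol = 1e-10, rtol = 1e-10)
    E <- apply(sol[, -1, drop = FALSE], 1, function(y) {
      e <- chain_energy(ch, y[seq_len(k)], y[k + seq_len(k)])
      e$kinetic + e$position
    })
    expect_lt(max(abs(E - E[1])), 1e-6 * max(abs(E[1]), 1))
  }
})

test_that("phase mismatches between chain and states are rejected", {
  seg <- toy_segments()
  ch_s <- build_chain("single_support", seg)
  ch_d <- build_chain("double_support", seg)
  st_s <- chain_states_single(0, 0, 0, 0, segments = seg)
  st_d <- chain_states_double(0, 0, 0, segments = seg)
  expect_error(single_support_moments(ch_d, st_d), "single_support")
  expect_error(double_support_moments(ch_s, st_s), "double_support")
  expect_error(single_support_moments(ch_s, st_d), "single_support")
})
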