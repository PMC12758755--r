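test_that("the default schedule partitions the cycle 12/38/12/38", {
  sch <- phase_schedule()
  u <- (0:99) / 100
  lab <- phase_labels(sch, u)
  expect_equal(as.vector(table(lab)), c(12, 38, 12, 38))
  expect_equal(sch$double_support_fraction + sch$single_support_fraction, 0.5)
  # every sample has exactly one label
  expect_false(anyNA(lab))
  expect_error(phase_schedule(0.6), "0.5")
  expect_error(phase_schedule(resolution = 101), "even")
})

test_that("non-default schedules keep counts within one sample of fractions", {
  sch <- phase_schedule(0.10, resolution = 200)
  lab <- phase_labels(sch, (0:199) / 200)
  counts <- as.vector(table(lab))
  expect_equal(counts, c(20, 80, 20, 80))
})

test_that("right-side series are the left-side series shifted half a cycle", {
  cyc <- predict_cycle(toy_subject(0.9, 60, 1), table = toy_table())
  res <- length(cyc$time)
  half <- res / 2
  shift <- function(v) v[((seq_len(res) - 1 + half) %% res) + 1]
  # GRF and moments: exact by construction (bitwise)
  expect_identical(cyc$grf$right_fy, shift(cyc$grf$left_fy))
  expect_identical(cyc$grf$right_fx, shift(cyc$grf$left_fx))
  expect_identical(cyc$moments$right_ankle, shift(cyc$moments$left_ankle))
  expect_identical(cyc$moments$right_hip, shift(cyc$moments$left_hip))
  expect_identical(cyc$moments$right_knee, shift(cyc$moments$left_knee))
  # angles: analytic identity of the half-period phase shift
  expect_equal(cyc$angles$right_hip, shift(cyc$angles$left_hip),
               tolerance = 1e-12)
  expect_equal(cyc$angles$right_knee, shift(cyc$angles$left_knee),
               tolerance = 1e-12)
})

test_that("angle series are periodic over the cycle", {
  subj <- toy_subject(0.9, 60, 0.9)
  cyc <- predict_cycle(subj, table = toy_table())
  for (joint in c("hip", "knee")) {
    for (side in c("left", "right")) {
      closing <- evaluate_angle(cyc$models[[joint]], subj, subj$period, side)
      expect_equal(closing, cyc$angles[[paste(side, joint, sep = "_")]][1],
                   tolerance = 1e-9)
    }
  }
})

test_that("a motionless degenerate subject stands at body weight", {
  zero_models <- list(
    hip = fourier_angle_model("hip", B = c(0, 0), phi = 0),
    knee = fourier_angle_model("knee", B = c(0, 0), phi = 0))
  sub <- toy_subject(0.9, 70, 1)
  cyc <- predict_cycle(sub, models = zero_models, table = toy_table())
  bw <- 70 * 9.81
  total_fy <- cyc$grf$left_fy + cyc$grf$right_fy
  expect_equal(total_fy, rep(bw, length(total_fy)))
  expect_equal(cyc$grf$left_fx + cyc$grf$right_fx,
               rep(0, length(total_fy)))
  # all single-support moments vanish in the static vertical configuration
  ss <- cyc$phase %in% c("ss1", "ss2")
  expect_equal(cyc$moments$left_ankle[cyc$phase == "ss1"],
               rep(0, sum(cyc$phase == "ss1")))
  expect_true(all(abs(cyc$moments$left_knee[ss]) < 1e-12 |
                    is.na(cyc$moments$left_knee[ss])))
  # per-foot vertical load ramps linearly with the transfer fraction
  i_ds1 <- which(cyc$phase == "ds1")
  s_frac <- cyc$detail$double$split$s
  expect_equal(cyc$grf$left_fy[i_ds1], bw * s_frac)
})

test_that("cycle-averaged total vertical GRF is body weight within 1%", {
  cyc <- predict_cycle(default_subject())
  bw <- cyc$segments$body_mass * cyc$segments$g
  avg <- mean(cyc$grf$left_fy + cyc$grf$right_fy)
  expect_lt(abs(avg - bw) / bw, 0.01)
})

test_that("moment provenance matches the phase labels", {
  cyc <- predict_cycle(toy_subject(), table = toy_table())
  ph <- cyc$phase
  # left ankle defined while the left foot is on the ground leading/stance
  expect_false(anyNA(cyc$moments$left_ankle[ph %in% c("ds1", "ss1")]))
  expect_true(all(is.na(cyc$moments$left_ankle[ph %in% c("ds2", "ss2")])))
  # left hip defined while left leg trails or swings
  expect_false(anyNA(cyc$moments$left_hip[ph %in% c("ds2", "ss2")]))
  expect_true(all(is.na(cyc$moments$left_hip[ph == "ds1"])))
  # left knee: stance decomposition in ss1/ds2, swing solution in ss2
  expect_false(anyNA(cyc$moments$left_knee[ph %in% c("ss1", "ds2", "ss2")]))
  expect_true(all(is.na(cyc$moments$left_knee[ph == "ds1"])))
  # swing foot carries no force
  expect_equal(cyc$grf$left_fy[ph == "ss2"], rep(0, sum(ph == "ss2")))
})

test_that("stance-knee series equals the lever-arm combination in the cycle", {
  cyc <- predict_cycle(toy_subject(), table = toy_table())
  seg <- cyc$segments
  i_ss1 <- which(cyc$phase == "ss1")
  expect_equal(cyc$moments$left_knee[i_ss1],
               stance_knee_moment(cyc$moments$left_ankle[i_ss1],
                                  cyc$detail$single$moments$swing_hip, seg))
})

test_that("transition jumps: anchored-leg boundaries are continuous", {
  cyc <- predict_cycle(default_subject())
  td <- transition_discontinuity(cyc)
  bw_jump <- function(bnd) {
    td$jump_normalised[td$signal == "total_fy" & td$boundary == bnd]
  }
  # heel-strike boundaries keep the trunk on the same rod: near-continuous
  expect_lt(bw_jump("ss1->ds2"), 0.02)
  expect_lt(bw_jump("ss2->ds1"), 0.02)
  # toe-off boundaries re-anchor the trunk to the new stance leg; the
  # diagnostic must expose that jump rather than hide it
  expect_gt(bw_jump("ds1->ss1"), 0.02)
  expect_equal(bw_jump("ds1->ss1"), bw_jump("ds2->ss2"))
})

test_that("transition jumps scale with mass when unnormalised only", {
  sub1 <- toy_subject(0.9, 60, 1)
  sub2 <- toy_subject(0.9, 120, 1)
  td1 <- transition_discontinuity(predict_cycle(sub1, table = toy_table()))
  td2 <- transition_discontinuity(predict_cycle(sub2, table = toy_table()))
  i <- td1$signal == "total_fy"
  expect_equal(td2$jump[i], 2 * td1$jump[i])
  expect_equal(td2$jump_normalised[i], td1$jump_normalised[i])
  # a zero-motion cycle has no jumps anywhere
  zero_models <- list(hip = fourier_angle_model("hip", c(0, 0), 0),
                      knee = fourier_angle_model("knee", c(0, 0), 0))
  td0 <- transition_discontinuity(
    predict_cycle(sub1, models = zero_models, table = toy_table()))
  expect_equal(max(td0$jump[td0$signal == "total_fy"]), 0)
})

test_that("double-support loop-closure diagnostics are reported", {
  cyc <- predict_cycle(default_subject())
  expect_named(cyc$diagnostics, c("time", "step_length", "ground_residual_y"))
  expect_equal(nrow(cyc$diagnostics), sum(cyc$phase == "ds1"))
  # the predicted leading foot lands near but not exactly on the ground:
  # the residual is small relative to leg length yet nonzero (no projection)
  expect_lt(max(abs(cyc$diagnostics$ground_residual_y)),
            0.2 * cyc$segments$l_1)
  expect_gt(max(abs(cyc$diagnostics$ground_residual_y)), 0)
})
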