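#' Gait-cycle phase schedule
#'
#' Partition of the normalised gait cycle [0, 1) into the four walking
#' phases, using half-open intervals: first double support \code{ds1}
#' starting at the reference (left) heel strike, first single support
#' \code{ss1} (left stance, right swing), second double support \code{ds2},
#' and second single support \code{ss2}. The default allocates 12% of the
#' cycle to each double support and 38% to each single support, so each half
#' cycle is one double support followed by one single support.
#'
#' @param double_support_fraction Fraction of the cycle spent in each double
#'   support phase (default 0.12).
#' @param resolution Samples per cycle on the grid \code{0, 1/n, ...,
#'   (n-1)/n}; must be even so a half-cycle shift is a whole number of
#'   samples (default 100).
#' @return An object of class \code{"phase_schedule"} with the four interval
#'   start/end fractions and the resolution.
#' @export
phase_schedule <- function(double_support_fraction = 0.12, resolution = 100L) {
  ds <- double_support_fraction
  if (!is.numeric(ds) || length(ds) != 1L || ds <= 0 || ds >= 0.5)
    stop("`double_support_fraction` must lie in (0, 0.5)")
  resolution <- as.integer(resolution)
  if (resolution < 10L || resolution %% 2L != 0L)
    stop("`resolution` must be an even integer >= 10")
  structure(
    list(ds1 = c(0, ds), ss1 = c(ds, 0.5),
         ds2 = c(0.5, 0.5 + ds), ss2 = c(0.5 + ds, 1),
         double_support_fraction = ds,
         single_support_fraction = 0.5 - ds,
         resolution = resolution),
    class = "phase_schedule"
  )
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "Phase schedule: ds 2 x %.0f%%, ss 2 x %.0f%%, %d samples/cycle\n",
    100 * x$double_support_fraction, 100 * x$single_support_fraction,
    x$resolution))
  invisible(x)
}

#' Phase label for cycle fractions
#'
#' @param schedule A \code{\link{phase_schedule}}.
#' @param u Cycle fractions in [0, 1).
#' @return Factor with levels \code{ds1}, \code{ss1}, \code{ds2}, \code{ss2}.
#' @export
phase_labels <- function(schedule, u) {
  stopifnot(inherits(schedule, "phase_schedule"),
            all(u >= 0), all(u < 1))
  lev <- c("ds1", "ss1", "ds2", "ss2")
  lab <- character(length(u))
  for (p in lev) {
    iv <- schedule[[p]]
    lab[u >= iv[1] & u < iv[2]] <- p
  }
  factor(lab, levels = lev)
}

# rotate a vector by k samples: out[i] = v[i - k] cyclically; with k = n/2
# this is the half-cycle shift in either direction.
rotate_half <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1 - k) %% n) + 1]
}

#' Predict a full gait cycle
#'
#' Runs the whole predictive pipeline from the three subject scalars: hip
#' and knee angles for both legs from the Fourier empirical model, point-mass
#' chain states per phase, ground reaction forces (with the linear
#' mass-transfer per-foot split in double support), and joint moments by
#' Lagrangian inverse dynamics. Only the first half cycle (one double support
#' then one single support) is computed dynamically; the second half follows
#' from left/right symmetry, i.e. every right-side series is the left-side
#' series shifted by exactly half a cycle.
#'
#' Sign conventions: x anterior, y up, angles measured from the vertical and
#' positive when the distal end of a segment is anterior to its proximal end.
#' Rigid ground-to-hip rods (stance and trailing legs) therefore carry the
#' \emph{negated} hip angle of their limb, so that a flexed hip at heel
#' strike places the foot ahead of the hip; in double support the rigid-leg
#' orientation is taken from the thigh (hip) angle.
#'
#' @param subject A \code{\link{subject_params}} object.
#' @param models Named list with \code{hip} and \code{knee}
#'   \code{\link{fourier_angle_model}}s (default the shipped population set).
#' @param table An \code{\link{anthropometric_table}}.
#' @param schedule A \code{\link{phase_schedule}}.
#' @param split_variant Passed to \code{\link{split_double_support}}.
#' @return An object of class \code{"gait_cycle"}: a list with
#'   \code{percent}, \code{time}, \code{phase} (labels per sample),
#'   \code{angles} (radians, both sides), \code{grf} (per-foot N and
#'   body-weight units), \code{moments} (per-limb N m and N m/kg; \code{NA}
#'   where the phase model defines no moment at that joint), the per-phase
#'   \code{detail} objects, and double-support loop-closure
#'   \code{diagnostics}.
#' @examples
#' cyc <- predict_cycle(default_subject())
#' head(cyc$grf)
#' @export
predict_cycle <- function(subject,
                          models = default_angle_models(),
                          table = anthropometric_table(),
                          schedule = phase_schedule(),
                          split_variant = "as_published") {
  stopifnot(inherits(subject, "subject_params"),
            inherits(table, "anthropometric_table"),
            inherits(schedule, "phase_schedule"),
            all(c("hip", "knee") %in% names(models)))
  segments <- build_segment_set(subject, table)
  res <- schedule$resolution
  half <- res %/% 2L
  u <- (seq_len(res) - 1L) / res
  tt <- u * subject$period
  phase <- phase_labels(schedule, u)

  # full-cycle joint angles, both sides, with analytic derivatives
  ang <- list(
    hip_L = angle_state(models$hip, subject, tt, "left"),
    hip_R = angle_state(models$hip, subject, tt, "right"),
    knee_L = angle_state(models$knee, subject, tt, "left"),
    knee_R = angle_state(models$knee, subject, tt, "right"))
  angles <- data.frame(
    left_hip = ang$hip_L$th, right_hip = ang$hip_R$th,
    left_knee = ang$knee_L$th, right_knee = ang$knee_R$th)

  take <- function(a, idx) list(th = a$th[idx], d1 = a$d$d1[idx], d2 = a$d$d2[idx])
  neg <- function(a) list(th = -a$th, d1 = -a$d1, d2 = -a$d2)

  # --- first double support: left leading, right trailing -------------------
  i_ds1 <- which(phase == "ds1")
  th_trail <- neg(take(ang$hip_R, i_ds1))       # ground-to-hip rod
  th_lead <- take(ang$hip_L, i_ds1)             # hip-to-ground rod
  states_d <- chain_states_double(tt[i_ds1], th_trail, th_lead, segments)
  timing <- phase_timing(0, schedule$double_support_fraction * subject$period)
  grf_d_total <- grf_double_support_total(states_d, segments)
  split_d <- split_double_support(states_d, segments, timing,
                                  variant = split_variant)
  chain_d <- build_chain("double_support", segments)
  mom_d <- double_support_moments(chain_d, states_d)
  knee_ds <- stance_knee_moment(mom_d$leading_ankle, mom_d$trailing_hip,
                                segments)

  # --- first single support: left stance, right swing -----------------------
  i_ss1 <- which(phase == "ss1")
  seg_ang <- segment_angles_from_joints(
    hip = take(ang$hip_R, i_ss1), knee = take(ang$knee_R, i_ss1))
  th_stance <- neg(take(ang$hip_L, i_ss1))
  states_s <- chain_states_single(tt[i_ss1], th_stance,
                                  seg_ang$thigh, seg_ang$shank, segments)
  grf_s <- grf_single_support(states_s, segments)
  chain_s <- build_chain("single_support", segments)
  mom_s <- single_support_moments(chain_s, states_s)
  knee_ss <- stance_knee_moment(mom_s$stance_ankle, mom_s$swing_hip, segments)

  # --- assemble the left-foot / left-limb series over the full cycle --------
  i_ds2 <- i_ds1 + half   # same window half a cycle later
  i_ss2 <- i_ss1 + half
  fy_L <- numeric(res); fx_L <- numeric(res)
  fy_L[i_ds1] <- split_d$fy_leading;  fx_L[i_ds1] <- split_d$fx_leading
  fy_L[i_ss1] <- grf_s$fy;            fx_L[i_ss1] <- grf_s$fx
  fy_L[i_ds2] <- split_d$fy_trailing; fx_L[i_ds2] <- split_d$fx_trailing
  # ss2: left foot is in swing, zero by construction
  fy_R <- rotate_half(fy_L, half); fx_R <- rotate_half(fx_L, half)
  bw <- segments$body_mass * segments$g
  grf <- data.frame(
    left_fy = fy_L, left_fx = fx_L, right_fy = fy_R, right_fx = fx_R,
    left_fy_bw = fy_L / bw, left_fx_bw = fx_L / bw,
    right_fy_bw = fy_R / bw, right_fx_bw = fx_R / bw)

  na <- rep(NA_real_, res)
  ankle_L <- na; hip_L <- na; knee_L <- na
  ankle_L[i_ds1] <- mom_d$leading_ankle
  ankle_L[i_ss1] <- mom_s$stance_ankle
  hip_L[i_ds2] <- mom_d$trailing_hip
  hip_L[i_ss2] <- mom_s$swing_hip
  knee_L[i_ss1] <- knee_ss
  knee_L[i_ds2] <- knee_ds
  knee_L[i_ss2] <- mom_s$swing_knee
  ankle_R <- rotate_half(ankle_L, half)
  hip_R <- rotate_half(hip_L, half)
  knee_R <- rotate_half(knee_L, half)
  bm <- segments$body_mass
  moments <- data.frame(
    left_ankle = ankle_L, left_hip = hip_L, left_knee = knee_L,
    right_ankle = ankle_R, right_hip = hip_R, right_knee = knee_R,
    left_ankle_nmkg = ankle_L / bm, left_hip_nmkg = hip_L / bm,
    left_knee_nmkg = knee_L / bm, right_ankle_nmkg = ankle_R / bm,
    right_hip_nmkg = hip_R / bm, right_knee_nmkg = knee_R / bm)

  # loop-closure diagnostic: the two predicted rod angles over-determine the
  # closed double-support chain; report where the leading foot lands
  l1 <- segments$l_1
  closure <- data.frame(
    time = tt[i_ds1],
    step_length = l1 * sin(states_d$theta[, 1]) + l1 * sin(states_d$theta[, 2]),
    ground_residual_y = l1 * cos(states_d$theta[, 1]) -
      l1 * cos(states_d$theta[, 2]))

  structure(
    list(subject = subject, segments = segments, schedule = schedule,
         models = models, percent = 100 * u, time = tt, phase = phase,
         angles = angles, grf = grf, moments = moments,
         detail = list(
           double = list(states = states_d, grf_total = grf_d_total,
                         split = split_d, moments = mom_d,
                         stance_knee = knee_ds, timing = timing),
           single = list(states = states_s, grf = grf_s, moments = mom_s,
                         stance_knee = knee_ss)),
         diagnostics = closure),
    class = "gait_cycle"
  )
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("Predicted gait cycle: %d samples, period %.3f s\n",
              length(x$time), x$subject$period))
  cat(sprintf("  subject: l = %.3f m, M = %.1f kg, f = %.3f strides/s\n",
              x$subject$leg_length, x$subject$body_mass, x$subject$cadence))
  tab <- table(x$phase)
  cat("  phases :", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Signal jumps at phase transitions
#'
#' Measures the discontinuity of every assembled signal at the four phase
#' boundaries of the cycle (including the wrap from the last sample back to
#' the first): the absolute difference between the last sample of a phase
#' and the first sample of the next. Forces are additionally reported in
#' body-weight units and moments per kilogram of body mass. A boundary whose
#' flanking samples include an undefined (NA) moment reports \code{NA}.
#'
#' @param cycle A \code{\link{predict_cycle}} result.
#' @return Data frame: \code{signal}, \code{boundary}, \code{jump} (native
#'   units) and \code{jump_normalised}.
#' @export
transition_discontinuity <- function(cycle) {
  stopifnot(inherits(cycle, "gait_cycle"))
  res <- length(cycle$time)
  phase <- cycle$phase
  starts <- vapply(levels(phase), function(p) min(which(phase == p)), 1L)
  # boundary k: last sample before starts[k] (cyclically) vs starts[k]
  bw <- cycle$segments$body_mass * cycle$segments$g
  bm <- cycle$segments$body_mass
  sigs <- c(as.list(cycle$grf[c("left_fy", "left_fx", "right_fy", "right_fx")]),
            as.list(cycle$moments[c("left_ankle", "left_hip", "left_knee",
                                    "right_ankle", "right_hip", "right_knee")]),
            as.list(cycle$angles))
  norm_div <- c(rep(bw, 4), rep(bm, 6), rep(1, ncol(cycle$angles)))
  total_fy <- cycle$grf$left_fy + cycle$grf$right_fy
  total_fx <- cycle$grf$left_fx + cycle$grf$right_fx
  sigs <- c(sigs, list(total_fy = total_fy, total_fx = total_fx))
  norm_div <- c(norm_div, bw, bw)

  rows <- list()
  for (k in seq_along(starts)) {
    s <- starts[[k]]
    e <- if (s == 1L) res else s - 1L
    bnd <- sprintf("%s->%s", phase[e], phase[s])
    for (j in seq_along(sigs)) {
      v <- sigs[[j]]
      jump <- abs(v[s] - v[e])
      rows[[length(rows) + 1L]] <- data.frame(
        signal = names(sigs)[j], boundary = bnd,
        jump = jump, jump_normalised = jump / norm_div[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a predicted gait cycle to CSV files
#'
#' Writes \code{angles.csv} (long: \code{percent_gait, joint, side,
#' value_deg} -- angles are exported in degrees, the in-memory
#' representation stays in radians), \code{grf.csv} (long:
#' \code{percent_gait, foot, component, value_N, value_bw}),
#' \code{moments.csv} (long: \code{percent_gait, joint, side, value_Nm,
#' value_Nm_per_kg}) and \code{phases.csv} into a directory.
#'
#' @param cycle A \code{\link{predict_cycle}} result.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_gait_cycle <- function(cycle, dir) {
  stopifnot(inherits(cycle, "gait_cycle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pct <- cycle$percent

  ang <- do.call(rbind, lapply(c("left_hip", "right_hip",
                                 "left_knee", "right_knee"), function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    data.frame(percent_gait = pct, joint = parts[2], side = parts[1],
               value_deg = cycle$angles[[nm]] * 180 / pi)
  }))
  utils::write.csv(ang, file.path(dir, "angles.csv"), row.names = FALSE)

  grf <- do.call(rbind, lapply(list(
    c("left_fy", "left", "vertical"),
    c("left_fx", "left", "anterior_posterior"),
    c("right_fy", "right", "vertical"),
    c("right_fx", "right", "anterior_posterior")), function(spec3) {
      data.frame(percent_gait = pct, foot = spec3[2], component = spec3[3],
                 value_N = cycle$grf[[spec3[1]]],
                 value_bw = cycle$grf[[paste0(spec3[1], "_bw")]])
    }))
  utils::write.csv(grf, file.path(dir, "grf.csv"), row.names = FALSE)

  mom <- do.call(rbind, lapply(c("left_ankle", "left_hip", "left_knee",
                                 "right_ankle", "right_hip", "right_knee"),
                               function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    data.frame(percent_gait = pct, joint = parts[2], side = parts[1],
               value_Nm = cycle$moments[[nm]],
               value_Nm_per_kg = cycle$moments[[paste0(nm, "_nmkg")]])
  }))
  utils::write.csv(mom, file.path(dir, "moments.csv"), row.names = FALSE)

  utils::write.csv(data.frame(percent_gait = pct, phase = cycle$phase),
                   file.path(dir, "phases.csv"), row.names = FALSE)
  invisible(dir)
}

#' Compare two gait-cycle CSV directories
#'
#' Reads the \code{angles.csv}, \code{grf.csv} and \code{moments.csv} files
#' written by \code{\link{write_gait_cycle}} from a predicted and a measured
#' directory and computes the agreement metrics per signal. Files absent
#' from either directory are skipped.
#'
#' @param predicted_dir,measured_dir Directories of CSV files.
#' @return A metrics data frame (see \code{\link{metrics_report}}).
#' @export
evaluate_directories <- function(predicted_dir, measured_dir) {
  one <- function(file, keys, value_col, prefix) {
    fp <- file.path(predicted_dir, file)
    fm <- file.path(measured_dir, file)
    if (!file.exists(fp) || !file.exists(fm)) return(NULL)
    p <- utils::read.csv(fp); m <- utils::read.csv(fm)
    key <- function(d) paste(prefix, do.call(paste, c(d[keys], sep = "_")),
                             sep = "_")
    p$signal <- key(p); m$signal <- key(m)
    sigs <- intersect(unique(p$signal), unique(m$signal))
    pw <- as.data.frame(lapply(stats::setNames(sigs, sigs), function(sg)
      p[[value_col]][p$signal == sg]), check.names = FALSE)
    mw <- as.data.frame(lapply(stats::setNames(sigs, sigs), function(sg)
      m[[value_col]][m$signal == sg]), check.names = FALSE)
    metrics_report(pw, mw)
  }
  out <- rbind(one("angles.csv", c("side", "joint"), "value_deg", "angle"),
               one("grf.csv", c("foot", "component"), "value_N", "grf"),
               one("moments.csv", c("side", "joint"), "value_Nm", "moment"))
  if (is.null(out)) stop("no comparable CSV files found")
  out
}
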