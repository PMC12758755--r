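# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate synthetic pseudo-measured gait trials
#'
#' Emulates a validation data set: repeated walking trials of one subject,
#' each equal to the model-predicted cycle plus independent Gaussian
#' measurement noise, time-normalised to the common percent-gait grid. This
#' is the statistical structure the validation workflow assumes (trials are
#' averaged into a single representative cycle before fitting or scoring);
#' it deliberately contains no biomechanically structured inter-trial
#' variability. Default noise levels: 1 degree on angles, 2% of body weight
#' on forces, 0.02 N m/kg on moments. Regeneration with the same seed is
#' bit-identical.
#'
#' @param cycle A \code{\link{predict_cycle}} result.
#' @param n_trials Number of trials (default 8).
#' @param noise_sd Named list of noise standard deviations:
#'   \code{angle_deg} (degrees), \code{grf_bw} (fraction of body weight),
#'   \code{moment_nmkg} (N m per kg).
#' @param seed Integer seed for the trial noise.
#' @param phase_jitter_sd Standard deviation (fraction of a cycle) of a
#'   per-trial random circular shift; default 0 (off).
#' @return An object of class \code{"trial_set"}: a list with
#'   \code{trials} (each a list of \code{angles}, \code{grf}, \code{moments}
#'   data frames in native units: radians, newtons, newton-metres),
#'   \code{percent}, \code{noise_sd} (native units), \code{seed} and the
#'   source \code{cycle}.
#' @export
generate_trials <- function(cycle, n_trials = 8L,
                            noise_sd = list(angle_deg = 1, grf_bw = 0.02,
                                            moment_nmkg = 0.02),
                            seed = 1L, phase_jitter_sd = 0) {
  stopifnot(inherits(cycle, "gait_cycle"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  sds <- list(angle_deg = 1, grf_bw = 0.02, moment_nmkg = 0.02)
  sds[names(noise_sd)] <- noise_sd
  if (any(unlist(sds) < 0) || phase_jitter_sd < 0)
    stop("noise standard deviations must be non-negative")

  bw <- cycle$segments$body_mass * cycle$segments$g
  bm <- cycle$segments$body_mass
  native <- list(angle = sds$angle_deg * pi / 180,
                 grf = sds$grf_bw * bw,
                 moment = sds$moment_nmkg * bm)
  base <- list(angles = cycle$angles,
               grf = cycle$grf[c("left_fy", "left_fx", "right_fy", "right_fx")],
               moments = cycle$moments[c("left_ankle", "left_hip", "left_knee",
                                         "right_ankle", "right_hip",
                                         "right_knee")])
  sd_of <- c(angles = "angle", grf = "grf", moments = "moment")
  res <- length(cycle$time)

  trials <- with_seed(seed, lapply(seq_len(n_trials), function(i) {
    shift <- if (phase_jitter_sd > 0)
      round(stats::rnorm(1, 0, phase_jitter_sd) * res) %% res else 0L
    lapply(stats::setNames(names(base), names(base)), function(blk) {
      df <- base[[blk]]
      sd_nat <- native[[sd_of[[blk]]]]
      noisy <- as.data.frame(lapply(df, function(col) {
        if (shift != 0L) col <- rotate_half(col, shift)
        col + stats::rnorm(length(col), 0, sd_nat)
      }))
      noisy
    })
  }))

  structure(list(trials = trials, n_trials = n_trials,
                 percent = cycle$percent, noise_sd = native,
                 seed = seed, cycle = cycle),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials, %d samples/cycle, seed %d\n",
              x$n_trials, length(x$percent), x$seed))
  cat(sprintf("  noise sd: %.4f rad, %.2f N, %.3f N m\n",
              x$noise_sd$angle, x$noise_sd$grf, x$noise_sd$moment))
  invisible(x)
}

#' Average trials into a representative cycle
#'
#' Pointwise mean across trials per signal, the standard reduction of
#' repeated time-normalised gait trials to one representative cycle.
#'
#' @param trial_set A \code{\link{generate_trials}} result.
#' @return A list of data frames (\code{angles}, \code{grf}, \code{moments})
#'   on the trial grid.
#' @export
average_trials <- function(trial_set) {
  stopifnot(inherits(trial_set, "trial_set"))
  if (trial_set$n_trials < 1L) stop("empty trial set")
  blocks <- names(trial_set$trials[[1]])
  out <- lapply(stats::setNames(blocks, blocks), function(blk) {
    mats <- lapply(trial_set$trials, function(tr) as.matrix(tr[[blk]]))
    avg <- Reduce(`+`, mats) / length(mats)
    as.data.frame(avg)
  })
  out
}

#' Write / read a trial set as CSV files
#'
#' One sub-directory per trial in the same CSV dialects as
#' \code{\link{write_gait_cycle}} would use for wide tables, plus a
#' \code{manifest.csv} recording the trial count, seed and noise levels.
#'
#' @param trial_set A \code{\link{generate_trials}} result.
#' @param dir Output directory.
#' @return \code{dir} (write) or a list of trials (read), invisibly for write.
#' @export
write_trials <- function(trial_set, dir) {
  stopifnot(inherits(trial_set, "trial_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(trial_set$n_trials)) {
    td <- file.path(dir, sprintf("trial_%02d", i))
    dir.create(td, showWarnings = FALSE)
    for (blk in names(trial_set$trials[[i]])) {
      df <- cbind(percent_gait = trial_set$percent, trial_set$trials[[i]][[blk]])
      utils::write.csv(df, file.path(td, paste0(blk, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(
    data.frame(n_trials = trial_set$n_trials, seed = trial_set$seed,
               angle_sd_rad = trial_set$noise_sd$angle,
               grf_sd_N = trial_set$noise_sd$grf,
               moment_sd_Nm = trial_set$noise_sd$moment),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  trials <- lapply(seq_len(manifest$n_trials), function(i) {
    td <- file.path(dir, sprintf("trial_%02d", i))
    blks <- c("angles", "grf", "moments")
    lapply(stats::setNames(blks, blks), function(blk) {
      df <- utils::read.csv(file.path(td, paste0(blk, ".csv")))
      df[names(df) != "percent_gait"]
    })
  })
  list(trials = trials, manifest = manifest)
}
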