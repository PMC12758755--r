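#' Fourier-series empirical joint-angle model
#'
#' A per-joint truncated Fourier series in amplitude--phase form. The left
#' joint angle (radians) at time \code{t} is
#' \deqn{\phi_L(t) = B_0 l + \sum_{j=1}^{n} B_j\, l \sin(2\pi j f t + \varphi_j)}
#' where \code{l} is leg length (m) and \code{f} cadence (strides/s); the
#' right side replaces \eqn{\varphi_j} with \eqn{\varphi_j + j\pi}, which is
#' exactly a half-period time shift. Amplitude coefficients \code{B} are in
#' rad/m so the same population coefficients scale to any subject.
#'
#' @param joint Joint label: \code{"hip"}, \code{"knee"} or \code{"ankle"}.
#' @param B Numeric vector \code{B_0..B_n} (rad/m), length \code{n + 1}.
#' @param phi Numeric vector of initial phases \code{phi_1..phi_n} (rad),
#'   length \code{n}.
#' @return An object of class \code{"fourier_angle_model"}.
#' @export
fourier_angle_model <- function(joint, B, phi) {
  joint <- match.arg(joint, c("hip", "knee", "ankle"))
  stopifnot(is.numeric(B), is.numeric(phi), all(is.finite(B)), all(is.finite(phi)))
  n <- length(phi)
  if (n < 1L) stop("at least one harmonic is required")
  if (length(B) != n + 1L)
    stop("`B` must have length(phi) + 1 entries (B_0..B_n)")
  structure(list(joint = joint, n_harmonics = n, B = B, phi = phi),
            class = "fourier_angle_model")
}

#' @export
print.fourier_angle_model <- function(x, ...) {
  cat(sprintf("Fourier angle model: %s, %d harmonics\n", x$joint, x$n_harmonics))
  cat("  B  :", paste(sprintf("% .4f", x$B), collapse = " "), "(rad/m)\n")
  cat("  phi:", paste(sprintf("% .4f", x$phi), collapse = " "), "(rad)\n")
  invisible(x)
}

#' Published hip and knee coefficient sets
#'
#' The shipped population coefficients for the sagittal hip and knee models
#' (three harmonics each), estimated from healthy adults by linear
#' least-squares harmonic regression. No ankle set is shipped: the dynamic
#' model treats each stance leg as a rigid rod and ignores the foot, so ankle
#' kinematics are never required; users with their own ankle coefficients can
#' construct a four-harmonic \code{\link{fourier_angle_model}} directly.
#'
#' @return A named list with elements \code{hip} and \code{knee}.
#' @export
default_angle_models <- function() {
  list(
    hip = fourier_angle_model("hip",
                              B = c(0.086, -0.316, -0.067, 0.026),
                              phi = c(-1.105, 1.433, 0.187)),
    knee = fourier_angle_model("knee",
                               B = c(0.468, 0.465, 0.311, -0.093),
                               phi = c(0.244, -0.990, 0.266))
  )
}

# Effective phases for a side: right adds j*pi to harmonic j.
side_phases <- function(model, side) {
  side <- match.arg(side, c("left", "right"))
  j <- seq_len(model$n_harmonics)
  if (side == "right") model$phi + j * pi else model$phi
}

#' Evaluate a joint-angle model
#'
#' @param model A \code{\link{fourier_angle_model}}.
#' @param subject A \code{\link{subject_params}} object supplying leg length
#'   and cadence.
#' @param t Time(s) in seconds (vectorised).
#' @param side \code{"left"} or \code{"right"}; the right side shifts
#'   harmonic \code{j} by \code{j * pi}, equivalent to a half-period delay.
#' @return \code{evaluate_angle}: joint angle(s) in radians.
#' @examples
#' m <- default_angle_models()$hip
#' s <- subject_params(1, 60, 1)
#' evaluate_angle(m, s, t = 0, side = "left")
#' @export
evaluate_angle <- function(model, subject, t, side = "left") {
  stopifnot(inherits(model, "fourier_angle_model"),
            inherits(subject, "subject_params"),
            is.numeric(t), all(is.finite(t)))
  phi <- side_phases(model, side)
  l <- subject$leg_length
  f <- subject$cadence
  j <- seq_len(model$n_harmonics)
  # outer(t, j): n_t x n columns of harmonic arguments
  arg <- outer(2 * pi * f * t, j) + rep(phi, each = length(t))
  drop(model$B[1] * l + sin(arg) %*% (model$B[-1] * l))
}

#' @return \code{angle_derivatives}: a list with elements \code{d1} (rad/s)
#'   and \code{d2} (rad/s^2), the analytic first and second time derivatives.
#' @rdname evaluate_angle
#' @export
angle_derivatives <- function(model, subject, t, side = "left") {
  stopifnot(inherits(model, "fourier_angle_model"),
            inherits(subject, "subject_params"),
            is.numeric(t), all(is.finite(t)))
  phi <- side_phases(model, side)
  l <- subject$leg_length
  f <- subject$cadence
  j <- seq_len(model$n_harmonics)
  w <- 2 * pi * j * f
  arg <- outer(2 * pi * f * t, j) + rep(phi, each = length(t))
  amp <- model$B[-1] * l
  list(d1 = drop(cos(arg) %*% (amp * w)),
       d2 = drop(-sin(arg) %*% (amp * w^2)))
}

# value + derivatives in one pass (internal fast path for cycle assembly)
angle_state <- function(model, subject, t, side = "left") {
  list(th = evaluate_angle(model, subject, t, side),
       d = angle_derivatives(model, subject, t, side))
}

# Canonicalise amplitude-phase pairs: phases are folded into (-pi/2, pi/2],
# the amplitude sign absorbing half-turn shifts. This is the representative
# of the equivalence class (B, phi) ~ (-B, phi + pi) ~ (B, phi + 2*pi) whose
# phase band matches the shipped population tables.
canonicalise_harmonics <- function(amp, phase, tol = 1e-12) {
  phase <- ((phase + pi / 2) %% (2 * pi))
  # phase now in [0, 2*pi); fold: [0, pi) keeps sign, [pi, 2*pi) flips
  flip <- phase >= pi
  amp[flip] <- -amp[flip]
  phase <- ifelse(flip, phase - pi, phase) - pi / 2
  # map the open/closed boundary: phase in (-pi/2, pi/2]
  at_low <- abs(phase + pi / 2) < tol
  amp[at_low] <- -amp[at_low]
  phase[at_low] <- pi / 2
  zero <- abs(amp) < tol
  amp[zero] <- 0
  phase[zero] <- 0
  list(amp = amp, phase = phase)
}

#' Fit Fourier coefficients to a measured joint-angle trajectory
#'
#' Ordinary linear least squares on the harmonic basis
#' \code{\{1, sin(2*pi*j*f*t), cos(2*pi*j*f*t)\}_{j=1..n}}, converted to
#' amplitude--phase form and scaled by leg length so the returned amplitudes
#' are in rad/m. The canonical form places every phase in
#' \code{(-pi/2, pi/2]}, the amplitude sign absorbing half-turn shifts;
#' exactly-zero harmonics report phase 0.
#'
#' @param times Sample times in seconds; must span at least one period and
#'   provide at least \code{2 * n_harmonics + 1} distinct samples.
#' @param angles Joint angles in radians at \code{times}.
#' @param leg_length Subject leg length in metres.
#' @param cadence Walking cadence in strides/s (fixes the fundamental
#'   frequency; it is not estimated).
#' @param n_harmonics Number of harmonics \code{n}.
#' @param joint Joint label stored on the returned model.
#' @return A \code{\link{fourier_angle_model}} with attributes
#'   \code{residual_norm} (root-mean-square residual, rad) and \code{n_obs}.
#' @examples
#' s <- subject_params(1, 60, 1)
#' tt <- seq(0, 1, length.out = 101)
#' y <- evaluate_angle(default_angle_models()$hip, s, tt)
#' fit_fourier_coefficients(tt, y, leg_length = 1, cadence = 1, n_harmonics = 3)
#' @export
fit_fourier_coefficients <- function(times, angles, leg_length, cadence,
                                     n_harmonics, joint = "hip") {
  stopifnot(is.numeric(times), is.numeric(angles),
            length(times) == length(angles),
            all(is.finite(times)), all(is.finite(angles)))
  if (leg_length <= 0) stop("`leg_length` must be positive")
  if (cadence <= 0) stop("`cadence` must be positive")
  n <- as.integer(n_harmonics)
  if (n < 1L) stop("`n_harmonics` must be >= 1")
  if (length(times) < 2L * n + 1L)
    stop("need at least 2*n_harmonics + 1 samples")

  j <- seq_len(n)
  arg <- outer(2 * pi * cadence * times, j)
  X <- cbind(1, sin(arg), cos(arg))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient harmonic design matrix: samples are too few or ",
         "degenerate to identify ", n, " harmonics")
  beta <- qr.coef(qrX, angles)
  a <- beta[1L + j]        # sin coefficients
  b <- beta[1L + n + j]    # cos coefficients
  can <- canonicalise_harmonics(sqrt(a^2 + b^2), atan2(b, a))

  fit <- fourier_angle_model(joint,
                             B = c(beta[1L], can$amp) / leg_length,
                             phi = can$phase)
  res <- angles - drop(X %*% beta)
  attr(fit, "residual_norm") <- sqrt(mean(res^2))
  attr(fit, "n_obs") <- length(angles)
  fit
}

#' Read / write Fourier coefficient tables
#'
#' Coefficient sets are serialised as a plain-text CSV with columns
#' \code{joint, n, B_0..B_n, phi_1..phi_n}; rows may have different harmonic
#' counts (short rows leave trailing columns empty).
#'
#' @param models A named list of \code{\link{fourier_angle_model}} objects.
#' @param path File path.
#' @return \code{read_angle_models} returns a named list of models;
#'   \code{write_angle_models} returns \code{path} invisibly.
#' @export
write_angle_models <- function(models, path) {
  stopifnot(all(vapply(models, inherits, logical(1), "fourier_angle_model")))
  nmax <- max(vapply(models, function(m) m$n_harmonics, integer(1)))
  rows <- lapply(models, function(m) {
    pad <- function(v, len) c(v, rep(NA_real_, len - length(v)))
    c(list(joint = m$joint, n = m$n_harmonics),
      as.list(stats::setNames(pad(m$B, nmax + 1), paste0("B_", 0:nmax))),
      as.list(stats::setNames(pad(m$phi, nmax), paste0("phi_", 1:nmax))))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_models
#' @export
read_angle_models <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    n <- df$n[i]
    B <- as.numeric(df[i, paste0("B_", 0:n)])
    phi <- as.numeric(df[i, paste0("phi_", seq_len(n))])
    fourier_angle_model(df$joint[i], B, phi)
  })
  stats::setNames(out, df$joint)
}
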