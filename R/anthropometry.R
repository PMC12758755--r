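#' Subject parameters
#'
#' Bundle the three measured inputs of the predictive gait model: leg length
#' (anterior superior iliac spine to medial malleolus, metres), body mass (kg)
#' and walking cadence (strides per second). The gait period is derived as
#' \code{period = 1 / cadence}.
#'
#' @param leg_length Leg length in metres (ASIS to medial malleolus).
#' @param body_mass Body mass in kilograms.
#' @param cadence Walking cadence in strides per second (stride rate, i.e.
#'   initial contacts of the same foot per second).
#' @return An object of class \code{"subject_params"}: a list with elements
#'   \code{leg_length}, \code{body_mass}, \code{cadence} and \code{period}.
#' @examples
#' subject_params(leg_length = 0.9, body_mass = 58.7, cadence = 0.92)
#' @export
subject_params <- function(leg_length, body_mass, cadence) {
  stopifnot(is.numeric(leg_length), length(leg_length) == 1L, is.finite(leg_length),
            is.numeric(body_mass), length(body_mass) == 1L, is.finite(body_mass),
            is.numeric(cadence), length(cadence) == 1L, is.finite(cadence))
  if (leg_length <= 0) stop("`leg_length` must be positive (metres)")
  if (body_mass <= 0) stop("`body_mass` must be positive (kg)")
  if (cadence <= 0) stop("`cadence` must be positive (strides/s)")
  structure(
    list(leg_length = leg_length, body_mass = body_mass,
         cadence = cadence, period = 1 / cadence),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Subject parameters\n")
  cat(sprintf("  leg length: %.3f m\n", x$leg_length))
  cat(sprintf("  body mass : %.1f kg\n", x$body_mass))
  cat(sprintf("  cadence   : %.3f strides/s (period %.3f s)\n",
              x$cadence, x$period))
  invisible(x)
}

#' Default subject used in examples and shape checks
#'
#' Body mass 58.7 kg (a typical healthy-adult cohort mean), leg length 0.89 m
#' (about 0.53 of a 1.68 m stature, the usual ASIS-to-malleolus proportion)
#' and cadence 0.92 strides/s (a self-selected adult pace of roughly 110
#' steps per minute).
#'
#' @return A \code{\link{subject_params}} object.
#' @export
default_subject <- function() {
  subject_params(leg_length = 0.89, body_mass = 58.7, cadence = 0.92)
}

#' Anthropometric (body segment parameter) table
#'
#' Fractional body-segment parameters used to turn body mass and leg length
#' into the segment masses, lengths and centroid offsets of the dynamic model.
#' All values are dimensionless fractions. Defaults follow the classic
#' Dempster adult cadaver proportions (per-limb thigh mass 0.100, shank mass
#' 0.0465 of body mass; segment centroids 0.433 of segment length from the
#' proximal end) with a 0.53/0.47 thigh/shank split of the measured leg
#' length. National body-segment-parameter standards publish comparable
#' coefficient sets; supply them here to localise the model.
#'
#' @param thigh_mass_fraction Thigh mass as a fraction of body mass, per limb.
#' @param shank_mass_fraction Shank mass as a fraction of body mass, per limb.
#' @param thigh_length_fraction Thigh length as a fraction of leg length.
#' @param shank_length_fraction Shank length as a fraction of leg length;
#'   must complement \code{thigh_length_fraction} to 1.
#' @param thigh_centroid_fraction Thigh centroid distance from the hip as a
#'   fraction of thigh length.
#' @param shank_centroid_fraction Shank centroid distance from the knee as a
#'   fraction of shank length.
#' @param stance_leg_centroid_fraction Centroid of the rigid stance/trailing
#'   leg rod as a fraction of leg length, measured from the ground contact.
#'   Default \code{NULL} computes the mass-weighted centroid of thigh plus
#'   shank implied by the other fractions.
#' @param leading_leg_centroid_fraction Centroid of the rigid leading leg in
#'   double support as a fraction of leg length, measured from the hip.
#'   Default \code{NULL} uses the mirror of the stance-rod centroid,
#'   \code{1 - stance_leg_centroid_fraction}.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return An object of class \code{"anthropometric_table"}.
#' @seealso \code{\link{build_segment_set}}, \code{\link{read_anthropometric_table}}
#' @export
anthropometric_table <- function(thigh_mass_fraction = 0.100,
                                 shank_mass_fraction = 0.0465,
                                 thigh_length_fraction = 0.53,
                                 shank_length_fraction = 1 - thigh_length_fraction,
                                 thigh_centroid_fraction = 0.433,
                                 shank_centroid_fraction = 0.433,
                                 stance_leg_centroid_fraction = NULL,
                                 leading_leg_centroid_fraction = NULL,
                                 gravity = 9.81) {
  frac <- c(thigh_mass_fraction = thigh_mass_fraction,
            shank_mass_fraction = shank_mass_fraction,
            thigh_length_fraction = thigh_length_fraction,
            shank_length_fraction = shank_length_fraction,
            thigh_centroid_fraction = thigh_centroid_fraction,
            shank_centroid_fraction = shank_centroid_fraction)
  if (!all(is.finite(frac)) || any(frac <= 0) || any(frac >= 1))
    stop("all anthropometric fractions must lie strictly in (0, 1)")
  if (2 * (thigh_mass_fraction + shank_mass_fraction) >= 1)
    stop("2*(thigh_mass_fraction + shank_mass_fraction) must be < 1 ",
         "(trunk mass would be non-positive)")
  if (abs(thigh_length_fraction + shank_length_fraction - 1) > 1e-9)
    stop("thigh_length_fraction + shank_length_fraction must equal 1")
  if (!is.finite(gravity) || gravity <= 0)
    stop("`gravity` must be positive")

  if (is.null(stance_leg_centroid_fraction)) {
    # mass-weighted centroid of thigh + shank, measured from the ground contact
    d_shank <- shank_length_fraction * (1 - shank_centroid_fraction)
    d_thigh <- shank_length_fraction +
      thigh_length_fraction * (1 - thigh_centroid_fraction)
    stance_leg_centroid_fraction <-
      (shank_mass_fraction * d_shank + thigh_mass_fraction * d_thigh) /
      (thigh_mass_fraction + shank_mass_fraction)
  }
  if (stance_leg_centroid_fraction <= 0 || stance_leg_centroid_fraction >= 1)
    stop("`stance_leg_centroid_fraction` must lie strictly in (0, 1)")
  if (is.null(leading_leg_centroid_fraction))
    leading_leg_centroid_fraction <- 1 - stance_leg_centroid_fraction
  if (leading_leg_centroid_fraction <= 0 || leading_leg_centroid_fraction >= 1)
    stop("`leading_leg_centroid_fraction` must lie strictly in (0, 1)")

  structure(
    list(thigh_mass_fraction = thigh_mass_fraction,
         shank_mass_fraction = shank_mass_fraction,
         thigh_length_fraction = thigh_length_fraction,
         shank_length_fraction = shank_length_fraction,
         thigh_centroid_fraction = thigh_centroid_fraction,
         shank_centroid_fraction = shank_centroid_fraction,
         stance_leg_centroid_fraction = stance_leg_centroid_fraction,
         leading_leg_centroid_fraction = leading_leg_centroid_fraction,
         gravity = gravity),
    class = "anthropometric_table"
  )
}

#' @export
print.anthropometric_table <- function(x, ...) {
  cat("Anthropometric table (fractions)\n")
  for (nm in names(x)) cat(sprintf("  %-30s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write an anthropometric table as a plain-text key-value file
#'
#' The file is flat YAML, one \code{key: value} pair per line, keys matching
#' the arguments of \code{\link{anthropometric_table}}. Missing keys take
#' their defaults; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return \code{read_anthropometric_table} returns an
#'   \code{"anthropometric_table"}; \code{write_anthropometric_table} returns
#'   \code{path} invisibly.
#' @export
read_anthropometric_table <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(anthropometric_table))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown anthropometric keys: ", paste(bad, collapse = ", "))
  do.call(anthropometric_table, vals)
}

#' @param table An \code{"anthropometric_table"} to serialise.
#' @rdname read_anthropometric_table
#' @export
write_anthropometric_table <- function(table, path) {
  stopifnot(inherits(table, "anthropometric_table"))
  yaml::write_yaml(unclass(table), path, precision = 15L)
  invisible(path)
}

#' Build the segment set for the dynamic model
#'
#' Converts body mass and leg length into the masses, lengths and centroid
#' offsets of the planar linkage: thigh and shank masses per limb, the lumped
#' trunk-head-arms point mass, the rigid stance-rod length (equal to leg
#' length), thigh/shank lengths, and all centroid offsets.
#'
#' @param subject A \code{\link{subject_params}} object.
#' @param table An \code{\link{anthropometric_table}}.
#' @return An object of class \code{"segment_set"} with elements
#'   \code{m_t}, \code{m_s} (thigh/shank mass, kg), \code{m} (trunk + head +
#'   upper limbs, kg), \code{l_1}, \code{l_2}, \code{l_3} (stance rod, thigh,
#'   shank length, m), \code{p_1}, \code{p_2}, \code{p_3}, \code{p_2d}
#'   (centroid offsets, m), \code{g}, and \code{body_mass}.
#'   Mass is conserved: \code{m + 2 * (m_t + m_s) == body_mass}.
#' @examples
#' s <- subject_params(0.9, 58.7, 0.9)
#' build_segment_set(s, anthropometric_table())
#' @export
build_segment_set <- function(subject, table) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(table, "anthropometric_table"))
  m_t <- subject$body_mass * table$thigh_mass_fraction
  m_s <- subject$body_mass * table$shank_mass_fraction
  m <- subject$body_mass - 2 * (m_t + m_s)
  if (m <= 0) stop("trunk mass is non-positive; check the mass fractions")
  l_1 <- subject$leg_length
  l_2 <- subject$leg_length * table$thigh_length_fraction
  l_3 <- subject$leg_length * table$shank_length_fraction
  structure(
    list(m_t = m_t, m_s = m_s, m = m,
         l_1 = l_1, l_2 = l_2, l_3 = l_3,
         p_1 = l_1 * table$stance_leg_centroid_fraction,
         p_2 = l_2 * table$thigh_centroid_fraction,
         p_3 = l_3 * table$shank_centroid_fraction,
         p_2d = l_1 * table$leading_leg_centroid_fraction,
         g = table$gravity,
         body_mass = subject$body_mass),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat("Segment set\n")
  cat(sprintf("  masses  : thigh %.3f, shank %.3f, trunk+head+arms %.3f kg\n",
              x$m_t, x$m_s, x$m))
  cat(sprintf("  lengths : leg %.3f, thigh %.3f, shank %.3f m\n",
              x$l_1, x$l_2, x$l_3))
  cat(sprintf("  centroids: p1 %.3f, p2 %.3f, p3 %.3f, p2d %.3f m\n",
              x$p_1, x$p_2, x$p_3, x$p_2d))
  invisible(x)
}
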