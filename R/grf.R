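#' Double-support phase timing
#'
#' Times of the two events bounding a double-support window: the leading-leg
#' heel strike that opens it and the trailing-leg toe off that closes it.
#' The mass-transfer fraction at time \code{t} is
#' \code{s(t) = (t - t_heelstrike) / (t_toeoff - t_heelstrike)}, running from
#' 0 (all body weight on the trailing leg) to 1 (all on the leading leg).
#'
#' @param t_heelstrike Leading-leg heel-strike time (s).
#' @param t_toeoff Trailing-leg toe-off time (s); must exceed
#'   \code{t_heelstrike}.
#' @return An object of class \code{"phase_timing"} with the two events and
#'   the window duration \code{T_DT}.
#' @export
phase_timing <- function(t_heelstrike, t_toeoff) {
  stopifnot(is.numeric(t_heelstrike), is.numeric(t_toeoff),
            length(t_heelstrike) == 1L, length(t_toeoff) == 1L,
            is.finite(t_heelstrike), is.finite(t_toeoff))
  if (t_toeoff <= t_heelstrike)
    stop("`t_toeoff` must be later than `t_heelstrike`")
  structure(list(t_heelstrike = t_heelstrike, t_toeoff = t_toeoff,
                 T_DT = t_toeoff - t_heelstrike),
            class = "phase_timing")
}

transfer_fraction <- function(timing, t, tol = 1e-9) {
  s <- (t - timing$t_heelstrike) / timing$T_DT
  if (any(s < -tol) || any(s > 1 + tol))
    stop("times fall outside the double-support window")
  pmin(pmax(s, 0), 1)
}

grf_frame <- function(times, body_mass, g, cols) {
  df <- data.frame(time = times, cols, check.names = FALSE)
  attr(df, "body_weight") <- body_mass * g
  class(df) <- c("grf_series", "data.frame")
  df
}

#' Total ground reaction force in single support
#'
#' Newton's second law applied to the whole body: the vertical GRF is body
#' weight plus the sum of mass-weighted vertical centroid accelerations of
#' the stance leg, trunk, swing thigh and swing shank; the anterior-posterior
#' GRF is the corresponding horizontal sum (no gravity term). The swing foot
#' carries zero force by construction.
#'
#' @param states A \code{"segment_states"} object from
#'   \code{\link{chain_states_single}}.
#' @param segments The matching \code{\link{build_segment_set}} result.
#' @return A \code{"grf_series"} data frame with columns \code{time},
#'   \code{fy}, \code{fx} (N) and body-weight-normalised \code{fy_bw},
#'   \code{fx_bw}.
#' @export
grf_single_support <- function(states, segments) {
  stopifnot(inherits(states, "segment_states"),
            inherits(segments, "segment_set"))
  if (states$phase != "single_support")
    stop("`states` must come from the single-support chain")
  total_grf(states, segments)
}

#' Total ground reaction force in double support
#'
#' As \code{\link{grf_single_support}} for the two-link double-support chain:
#' the total over both feet, before any per-foot split.
#'
#' @param states A \code{"segment_states"} object from
#'   \code{\link{chain_states_double}}.
#' @param segments The matching segment set.
#' @return A \code{"grf_series"} data frame (total over both feet).
#' @export
grf_double_support_total <- function(states, segments) {
  stopifnot(inherits(states, "segment_states"),
            inherits(segments, "segment_set"))
  if (states$phase != "double_support")
    stop("`states` must come from the double-support chain")
  total_grf(states, segments)
}

total_grf <- function(states, segments) {
  m <- states$chain$m                    # all point masses; sums to body mass
  g <- segments$g
  bw <- segments$body_mass * g
  fy <- bw + drop(states$ydd %*% m)
  fx <- drop(states$xdd %*% m)
  grf_frame(states$times, segments$body_mass, g,
            data.frame(fy = fy, fx = fx, fy_bw = fy / bw, fx_bw = fx / bw))
}

#' Per-foot ground reaction forces in double support
#'
#' Splits the double-support load between the two feet under the linear
#' mass-transfer assumption: from leading-leg heel strike to trailing-leg
#' toe off, the body mass borne by the trailing leg falls linearly from the
#' full body mass to zero while the leading leg picks it up. With transfer
#' fraction \code{s(t)}:
#' \deqn{GRF_y^{s1} = Mg(1-s) + m\ddot y_c/2 + (m_t+m_s)\ddot y_{s1}}
#' \deqn{GRF_y^{s2} = Mg\,s + m\ddot y_c/2 + (m_t+m_s)\ddot y_{s2}}
#' (superscript s1 = trailing foot, s2 = leading foot, \code{M} the whole
#' body mass, \code{m} the trunk mass, \code{y_c} the trunk point). The
#' vertical components sum to the two-link total identically. The published
#' anterior-posterior split,
#' \deqn{GRF_x^{s1} = (m - ms)\ddot x_c/2 + (m_t+m_s)\,s\,\ddot x_{s1}},
#' \deqn{GRF_x^{s2} = (m + ms)\ddot x_c/2 + (m_t+m_s)\,s\,\ddot x_{s2}},
#' does not conserve the two-link horizontal total except at \code{s = 1};
#' it is implemented verbatim as the default, and the conservation residual
#' is returned as a diagnostic column. \code{variant = "conserving"} is a
#' non-default sensitivity variant that weights the trailing-leg inertia by
#' \code{1 - s} instead of \code{s}.
#'
#' @param states A \code{"segment_states"} object from
#'   \code{\link{chain_states_double}}.
#' @param segments The matching segment set.
#' @param timing A \code{\link{phase_timing}} covering \code{states$times}.
#' @param variant \code{"as_published"} (default) or \code{"conserving"}.
#' @return A \code{"grf_series"} data frame with per-foot columns
#'   \code{fy_trailing}, \code{fy_leading}, \code{fx_trailing},
#'   \code{fx_leading} (N), their \code{_bw} normalised copies, the transfer
#'   fraction \code{s}, and \code{fx_residual} (published horizontal split
#'   minus the two-link horizontal total, N).
#' @export
split_double_support <- function(states, segments, timing,
                                 variant = c("as_published", "conserving")) {
  stopifnot(inherits(states, "segment_states"),
            inherits(segments, "segment_set"),
            inherits(timing, "phase_timing"))
  if (states$phase != "double_support")
    stop("`states` must come from the double-support chain")
  variant <- match.arg(variant)
  s <- transfer_fraction(timing, states$times)
  g <- segments$g
  M <- segments$body_mass
  m <- segments$m
  m_leg <- segments$m_t + segments$m_s
  bw <- M * g

  ydd_c <- states$ydd[, "trunk"]
  xdd_c <- states$xdd[, "trunk"]
  ydd_s1 <- states$ydd[, "trailing_leg"]
  ydd_s2 <- states$ydd[, "leading_leg"]
  xdd_s1 <- states$xdd[, "trailing_leg"]
  xdd_s2 <- states$xdd[, "leading_leg"]

  fy_trailing <- bw * (1 - s) + m * ydd_c / 2 + m_leg * ydd_s1
  fy_leading <- bw * s + m * ydd_c / 2 + m_leg * ydd_s2
  w_trailing <- if (variant == "as_published") s else 1 - s
  fx_trailing <- (m - m * s) * xdd_c / 2 + m_leg * w_trailing * xdd_s1
  fx_leading <- (m + m * s) * xdd_c / 2 + m_leg * s * xdd_s2

  fx_total <- drop(states$xdd %*% states$chain$m)
  df <- grf_frame(states$times, M, g,
                  data.frame(s = s,
                             fy_trailing = fy_trailing,
                             fy_leading = fy_leading,
                             fx_trailing = fx_trailing,
                             fx_leading = fx_leading,
                             fy_trailing_bw = fy_trailing / bw,
                             fy_leading_bw = fy_leading / bw,
                             fx_trailing_bw = fx_trailing / bw,
                             fx_leading_bw = fx_leading / bw,
                             fx_residual = fx_trailing + fx_leading - fx_total))
  attr(df, "variant") <- variant
  df
}
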