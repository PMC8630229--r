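#' Landing velocity vector
#'
#' The belly velocity vector at first contact, computed from the smoothed
#' belly coordinates one frame before and directly at first contact:
#' `(x(t0) - x(t0-1), y(t0) - y(t0-1)) / dt`. Its norm equals the
#' kinematics-module speed for the frame interval ending at `t0`.
#'
#' @param belly A smoothed [marker_track()] for the belly.
#' @param t0 First-contact frame, 0-based; must be at least 1.
#' @return Numeric length-2 velocity `(vx, vy)` in m/s (y positive downward).
#' @export
landing_velocity_vector <- function(belly, t0) {
  stopifnot(inherits(belly, "marker_track"))
  t0 <- as.integer(t0)
  if (t0 < 1L) stop("first contact at frame 0: no preceding frame for the velocity vector",
                    call. = FALSE)
  if (t0 > n_frames(belly) - 1L) stop("t0 outside track", call. = FALSE)
  (belly$positions[t0 + 1L, ] - belly$positions[t0, ]) / belly$dt
}

#' Incidence angle between the landing velocity and the platform
#'
#' `alpha = arccos( v . h / (|v| |h|) )` where `h` is the platform's in-plane
#' direction vector (see [platform_direction()]; the conventional
#' unnormalized forms are handled by the internal normalization). The result
#' lies in `[0, 180]` degrees; 90 degrees is a perpendicular collision.
#'
#' @param v Numeric length-2 (or length-3 with zero third component)
#'   velocity vector; must be non-zero.
#' @param geom A [platform_geometry()] (or a numeric incline in degrees).
#' @return Angle in degrees.
#' @export
incidence_angle <- function(v, geom) {
  h <- if (inherits(geom, "platform_geometry")) geom$h else platform_direction(geom)
  v3 <- c(v, 0, 0)[1:3]
  nv <- sqrt(sum(v3^2))
  if (nv <= 0) stop("zero landing velocity: incidence angle undefined", call. = FALSE)
  ca <- sum(v3 * h) / (nv * sqrt(sum(h^2)))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Projected impact force
#'
#' Closed-form impact force perpendicular to the landing surface,
#' `F_i = m (v/T) sin(alpha) + m g cos(phi)`: an inertial term (average
#' deceleration `v/T` projected on the surface normal) plus the gravitational
#' projection. Also returns the surface-perpendicular landing velocity
#' `v_perp = v sin(alpha)` and both force terms. The speed `v` is the norm of
#' the landing velocity vector; `v/T` is an average-deceleration surrogate
#' and is distinct from the frame-wise peak deceleration, which is reported
#' separately by the pipeline and never substituted here.
#'
#' @param m Body mass, kg (> 0).
#' @param v Landing speed of the belly at first contact, m/s (> 0... >= 0 is
#'   accepted; the v -> 0 limit gives the resting weight projection).
#' @param T Landing duration, s (> 0).
#' @param alpha Incidence angle between velocity vector and platform, degrees
#'   in `[0, 180]`.
#' @param phi Platform incline, degrees in `[0, 90]`.
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @return List of class `impact_result`: `F_i` (N), `v_perp` (m/s),
#'   `inertial_term` (N), `gravitational_term` (N), `omega` (deg,
#'   `alpha - phi`).
#' @export
impact_force <- function(m, v, T, alpha, phi, g = 9.81) {
  stopifnot(is.finite(m), m > 0, is.finite(v), v >= 0,
            is.finite(alpha), alpha >= 0, alpha <= 180,
            is.finite(phi), phi >= 0, phi <= 90, is.finite(g), g > 0)
  if (!is.finite(T) || T <= 0) stop("landing duration T must be positive", call. = FALSE)
  ar <- alpha * pi / 180
  pr <- phi * pi / 180
  inertial <- m * (v / T) * sin(ar)
  gravitational <- m * g * cos(pr)
  structure(list(F_i = inertial + gravitational,
                 v_perp = v * sin(ar),
                 inertial_term = inertial,
                 gravitational_term = gravitational,
                 omega = alpha - phi),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("<impact_result: F_i = %.4g N (inertial %.4g + gravitational %.4g), v_perp = %.4g m/s>\n",
              x$F_i, x$inertial_term, x$gravitational_term, x$v_perp))
  invisible(x)
}

#' Predicted single-forelimb frictional adhesion
#'
#' Maximum frictional adhesive force of one forelimb predicted from body
#' mass by the published digital-adhesion scaling relation for crested
#' geckos, read as a log10-log10 power law:
#' `adhesion = 10^(1.041 * log10(mass_g) - 0.69)` newtons. (The linear
#' reading of the printed coefficients is dimensionally inconsistent with
#' the ~10 N force it is known to predict at adult mass, so the log-log form
#' is adopted; see the methods vignette.)
#'
#' @param mass_g Body mass in grams (> 0).
#' @return Adhesive force in N.
#' @export
predicted_adhesion <- function(mass_g) {
  if (!all(is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("`mass_g` must be positive", call. = FALSE)
  }
  10^(1.041 * log10(mass_g) - 0.69)
}

#' Adhesive safety factor
#'
#' Ratio of available adhesive force to the impact force demanded; values
#' below 1 indicate adhesive failure.
#'
#' @param adhesion Available adhesive force, N.
#' @param F_i Impact force, N (> 0).
#' @return Dimensionless ratio.
#' @export
safety_factor <- function(adhesion, F_i) {
  if (!all(is.finite(F_i)) || any(F_i <= 0)) {
    stop("impact force must be positive for a safety factor", call. = FALSE)
  }
  adhesion / F_i
}
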