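#' Platform geometry for a landing surface
#'
#' Describes the landing (or take-off) platform as a plane in the analysis
#' coordinate system: x horizontal, y vertical and increasing *downward*, so
#' gravity acts in +y and the animal travels in the -x direction. The plane is
#' defined by its incline `phi` (degrees from horizontal) and an anchor point
#' lying on the surface. The in-plane direction vector `h` and the unit
#' normal `e` follow the standard convention for this coordinate frame:
#' `h = (-cos(phi), sin(phi), 0)` and `e = (sin(phi), cos(phi), 0)`.
#' For the canonical inclines 0, 45 and 90 degrees, `h` is stored in its
#' conventional unnormalized integer form `(-1,0,0)`, `(-1,1,0)`, `(0,1,0)`;
#' the incidence-angle computation normalizes internally so results are
#' unaffected.
#'
#' @param phi Surface incline in degrees from horizontal (0 = horizontal,
#'   90 = vertical). Any value in `[0, 90]` is accepted.
#' @param anchor Numeric length-2: a point `(x, y)` on the surface, metres.
#' @param h_to Take-off platform height (m), metadata only.
#' @param h_l Landing platform height (m), metadata only.
#' @param d Horizontal gap between platforms (m), metadata only.
#' @return An object of class `platform_geometry` with fields `phi`, `anchor`,
#'   `h` (3-vector, z = 0), `e` (unit 3-vector), `h_to`, `h_l`, `d`.
#' @examples
#' geom <- platform_geometry(90)
#' geom$h  # c(0, 1, 0)
#' @export
platform_geometry <- function(phi, anchor = c(0, 0),
                              h_to = NA_real_, h_l = NA_real_, d = NA_real_) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (phi < 0 || phi > 90) {
    stop("platform incline `phi` must lie in [0, 90] degrees", call. = FALSE)
  }
  stopifnot(is.numeric(anchor), length(anchor) == 2L, all(is.finite(anchor)))
  obj <- list(
    phi = phi,
    anchor = as.numeric(anchor),
    h = platform_direction(phi),
    e = platform_normal(phi),
    h_to = h_to, h_l = h_l, d = d
  )
  class(obj) <- "platform_geometry"
  obj
}

#' In-plane direction vector of a landing surface
#'
#' Returns the direction vector lying in the landing plane for incline `phi`.
#' The canonical inclines use the conventional unnormalized forms
#' `(-1, 0, 0)`, `(-1, 1, 0)` and `(0, 1, 0)`; other inclines use the
#' generalization `(-cos(phi), sin(phi), 0)`, which reduces to the canonical
#' vectors at 0/45/90 degrees up to normalization.
#'
#' @param phi Incline in degrees.
#' @return Numeric 3-vector with zero third component.
#' @export
platform_direction <- function(phi) {
  if (isTRUE(all.equal(phi, 0))) return(c(-1, 0, 0))
  if (isTRUE(all.equal(phi, 45))) return(c(-1, 1, 0))
  if (isTRUE(all.equal(phi, 90))) return(c(0, 1, 0))
  r <- phi * pi / 180
  c(-cos(r), sin(r), 0)
}

#' Unit vector perpendicular to a landing surface
#'
#' `e = (sin(phi), cos(phi), 0)`, the unit normal used to project the landing
#' force onto the surface-perpendicular direction.
#'
#' @param phi Incline in degrees.
#' @return Unit numeric 3-vector.
#' @export
platform_normal <- function(phi) {
  r <- phi * pi / 180
  c(sin(r), cos(r), 0)
}

#' Perpendicular distance of points from a platform plane
#'
#' Absolute perpendicular distance of one or more 2-D points from the plane of
#' a [platform_geometry()].
#'
#' @param points Numeric matrix (n x 2) or length-2 vector of `(x, y)` metres.
#' @param geom A `platform_geometry`.
#' @return Numeric vector of non-negative distances (m).
#' @export
plane_distance <- function(points, geom) {
  stopifnot(inherits(geom, "platform_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  e <- geom$e[1:2]
  abs((points[, 1] - geom$anchor[1]) * e[1] + (points[, 2] - geom$anchor[2]) * e[2])
}
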