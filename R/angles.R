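# Pure angle geometry. Image coordinates are row-down (y grows toward the
# bottom of the frame); every angle here converts to an up-positive vertical
# displacement so that anatomy above the vertex gives positive elevation.

DEG_PER_RAD <- 180 / pi

#' Centroid of a detected fiducial marker
#'
#' The marker centre is the component-wise arithmetic mean of the four
#' detected corner coordinates. The centroid is invariant to corner order,
#' so no particular winding is required.
#'
#' @param detection A marker detection as returned by [detect_markers()]
#'   (a list with a `corners` element), or a bare 4 x 2 numeric matrix of
#'   corner `(x, y)` coordinates.
#' @return Named numeric vector `c(x =, y =)` in pixels.
#' @examples
#' marker_center(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
#' @export
marker_center <- function(detection) {
  corners <- if (is.list(detection) && !is.null(detection$corners)) {
    detection$corners
  } else {
    detection
  }
  corners <- as.matrix(corners)
  if (!is.numeric(corners) || nrow(corners) != 4L || ncol(corners) != 2L ||
      any(!is.finite(corners))) {
    stop("malformed detection: expected exactly 4 finite (x, y) corners",
         call. = FALSE)
  }
  c(x = mean(corners[, 1]), y = mean(corners[, 2]))
}

# Unsigned angle in [0, 180] between the vector from `vertex` to `toward`
# and the horizontal image axis, with image rows converted to up-positive.
.elevation_angle <- function(vertex, toward, what = "angle") {
  vertex <- as.numeric(vertex)
  toward <- as.numeric(toward)
  stopifnot(length(vertex) == 2L, length(toward) == 2L)
  dx <- toward[1] - vertex[1]
  dy_up <- vertex[2] - toward[2]  # rows grow downward
  if (dx == 0 && dy_up == 0) {
    stop("undefined ", what, ": the two landmarks coincide", call. = FALSE)
  }
  abs(atan2(dy_up, dx)) * DEG_PER_RAD
}

#' Craniovertebral angle from C7 and tragus pixel coordinates
#'
#' The craniovertebral angle (CA) is the unsigned angle, in degrees, between
#' the horizontal through the C7 spinous process and the line from C7 to the
#' ear tragus. A tragus directly above C7 yields 90 degrees; forward head
#' posture pulls the tragus toward the horizontal and the angle down.
#' Equivalent to `acos(d . (1, 0) / |d|)` with `d` the C7-to-tragus vector
#' expressed with an up-positive vertical component.
#'
#' @param c7,tragus Numeric `(x, y)` pixel coordinates (row-down image
#'   convention).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' craniovertebral_angle(c(100, 200), c(150, 150))  # 45
#' @export
craniovertebral_angle <- function(c7, tragus) {
  .elevation_angle(c7, tragus, "craniovertebral angle")
}

#' Shoulder angle from acromion and C7 pixel coordinates
#'
#' The shoulder angle (SA) is measured at the acromion between the
#' horizontal and the ray toward the upper-body landmark; the default
#' convention throughout the package takes that landmark to be C7 (see
#' `sa_convention` in [process_stream()] for the alternative tragus
#' convention). Same unsigned, up-positive definition as
#' [craniovertebral_angle()].
#'
#' @param acromion,toward Numeric `(x, y)` pixel coordinates; `toward` is
#'   the C7 (default convention) or tragus landmark.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
shoulder_angle <- function(acromion, toward) {
  .elevation_angle(acromion, toward, "shoulder angle")
}

#' Inclination of a sensor's X-axis from the horizontal
#'
#' Tilt relative to gravity derived from a 3-axis acceleration sample:
#' `atan2(ax, sqrt(ay^2 + az^2))` in degrees. This is equivalent to
#' `asin(ax / |a|)` for a resting sensor but never domain-errors when the
#' vector norm drifts from 1 g, and is invariant to the overall magnitude
#' of the acceleration vector.
#'
#' @param ax,ay,az Acceleration components in g-units. `ax` may also be a
#'   length-3 vector `(ax, ay, az)`. All arguments are vectorised.
#' @return Tilt in degrees, in `(-90, 90]`; positive when the X-axis points
#'   above the horizontal.
#' @examples
#' tilt_from_acceleration(0.5, 0, -0.8660254)  # 30
#' @export
tilt_from_acceleration <- function(ax, ay = NULL, az = NULL) {
  if (is.null(ay) && is.null(az)) {
    v <- as.numeric(ax)
    stopifnot(length(v) == 3L)
    ax <- v[1]; ay <- v[2]; az <- v[3]
  }
  norm2 <- ax^2 + ay^2 + az^2
  if (any(!is.finite(norm2)) || any(norm2 == 0)) {
    stop("invalid sample: acceleration vector must be finite with norm > 0",
         call. = FALSE)
  }
  atan2(ax, sqrt(ay^2 + az^2)) * DEG_PER_RAD
}

#' Kyphosis angle from the alpha/beta inclination pair
#'
#' The thoracic kyphosis index used here is the sum of the upper-back
#' (T1/T2, alpha) and mid-back (T12/L1, beta) surface inclinations.
#'
#' @param alpha_deg,beta_deg Inclinations in degrees, each in `(-90, 90)`.
#'   Vectorised.
#' @return `alpha_deg + beta_deg` in degrees.
#' @examples
#' kyphosis_angle(25, 20)  # 45
#' @export
kyphosis_angle <- function(alpha_deg, beta_deg) {
  if (any(!is.finite(alpha_deg)) || any(!is.finite(beta_deg)) ||
      any(abs(alpha_deg) >= 90) || any(abs(beta_deg) >= 90)) {
    stop("alpha and beta inclinations must be finite and within (-90, 90)",
         call. = FALSE)
  }
  alpha_deg + beta_deg
}
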