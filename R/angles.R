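## Angle conventions
##
## Image coordinates run x-right / y-down. Angles are measured directly in
## these coordinates (atan2(dy, dx)), so increasing angle is clockwise as
## printed. Because the camera views the fish from its dorsal side,
## clockwise as printed is toward the fish's RIGHT: a positive change of
## the heading angle is a rightward turn (right turns positive, as
## conventionally plotted), and the bend angle theta12 - theta is positive
## for a leftward tail bend.

#' Orientation of a directed segment
#'
#' Angle of the vector from `p` to `q`, in radians in `(-pi, pi]`, measured
#' in image coordinates (see [fishgait]): increasing angle is clockwise as
#' printed, i.e. toward the fish's right in a dorsal view.
#'
#' @param p,q Numeric length-2 points `(x, y)` in image coordinates.
#' @return Angle in radians in `(-pi, pi]`.
#' @examples
#' segment_orientation(c(0, 0), c(1, 0))  # 0
#' segment_orientation(c(0, 0), c(0, 1))  # +pi/2 (q below p as printed)
#' @export
segment_orientation <- function(p, q) {
  dx <- q[[1]] - p[[1]]
  dy <- q[[2]] - p[[2]]
  if (dx == 0 && dy == 0) stop("coincident points have no orientation")
  atan2(dy, dx)
}

#' Wrapped angular difference
#'
#' `b - a` wrapped to `(-pi, pi]`: the minimum-magnitude representative of
#' the angular change, used when tracing orientation changes across frames.
#'
#' @param a,b Angles in radians (vectorized).
#' @return Wrapped difference in `(-pi, pi]`.
#' @export
wrapped_delta <- function(a, b) {
  d <- (b - a) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

## wrap a single angle into (-pi, pi]
wrap_angle <- function(a) wrapped_delta(0, a)

#' Unwrap an angle series
#'
#' Removes +-2*pi jumps so that consecutive values differ by their wrapped
#' delta; the result is a cumulative orientation suitable for turn detection.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Unwrapped series, same length, starting at `theta[1]`.
#' @export
unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  theta[1] + c(0, cumsum(wrapped_delta(theta[-length(theta)], theta[-1])))
}

## Minimum distance from point p to a polyline (n x 2 matrix).
point_polyline_distance <- function(p, poly) {
  n <- nrow(poly)
  if (n == 1) return(sqrt(sum((p - poly[1, ])^2)))
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  tt <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
    pmax(rowSums(ab^2), 1e-12)
  tt <- pmin(pmax(tt, 0), 1)
  px <- a[, 1] + ab[, 1] * tt
  py <- a[, 2] + ab[, 2] * tt
  sqrt(min((p[1] - px)^2 + (p[2] - py)^2))
}
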