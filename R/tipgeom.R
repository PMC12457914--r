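# Tip geometry: principal-axis analysis of a nut's pixel coordinates, tip
# localisation at the farther long-axis extreme, and distance-to-tip ranking.

#' Principal axes of a pixel ensemble
#'
#' PCA on the (x, y) pixel coordinates of a nut. A pistachio is nearly
#' elliptical, so the leading eigenvector of the coordinate covariance gives
#' the long axis of the approximating ellipse; semi-axis lengths are taken as
#' `2 * sqrt(eigenvalue)` (an internal convention — only the axis direction
#' and the extreme points matter downstream).
#'
#' @param pixels data frame with integer columns `x`, `y` (0-based, x =
#'   column, y = row, origin top-left).
#' @return list of class `axis_frame`: `centre` (coordinate mean),
#'   `long_axis_dir` (unit vector), `long_len`, `short_len`,
#'   `rotation_angle` (radians; rotating the coordinates by this angle maps
#'   the long axis to horizontal; normalized to (-pi/2, pi/2]).
#' @export
principal_axes <- function(pixels) {
  xy <- cbind(pixels$x, pixels$y)
  if (nrow(xy) < 3) stop("need at least 3 pixels", call. = FALSE)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1)) {
    stop("degenerate (collinear) pixel ensemble", call. = FALSE)
  }
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(
    list(
      centre = colMeans(xy),
      long_axis_dir = c(cos(ang), sin(ang)),
      long_len = 2 * sqrt(eg$values[1]),
      short_len = 2 * sqrt(eg$values[2]),
      rotation_angle = -ang
    ),
    class = "axis_frame"
  )
}

#' Locate the tip of a nut
#'
#' In the rotated frame where the long axis is horizontal, the two extreme
#' pixels on either side of the centre are candidates; the one farther from
#' the centre is the tip (the slightly protruding pointed end of the nut).
#' An exact tie between the two extremes is broken towards the candidate with
#' larger rotated |x|, then smaller original y. Per-pixel Euclidean distances
#' to the tip are computed in the original frame and ranked ascending, ties
#' broken by pixel index order so downstream region partitions are
#' deterministic.
#'
#' @param pixels data frame with columns `x`, `y` (and optionally colours,
#'   ignored here).
#' @param frame an [principal_axes()] result; computed from `pixels` when
#'   omitted.
#' @return list of class `tip_result`: `tip` (named x, y), `frame`, and
#'   `pixels` — the input with added `distance` and `rank` columns (`rank` is
#'   a permutation of `1..n`).
#' @export
locate_tip <- function(pixels, frame = NULL) {
  if (is.null(frame)) frame <- principal_axes(pixels)
  u <- frame$long_axis_dir
  dx <- pixels$x - frame$centre[1]
  dy <- pixels$y - frame$centre[2]
  xr <- dx * u[1] + dy * u[2]           # rotated x (long-axis coordinate)
  i_lo <- which.min(xr)
  i_hi <- which.max(xr)
  if (abs(xr[i_lo]) > abs(xr[i_hi])) {
    tip_i <- i_lo
  } else if (abs(xr[i_hi]) > abs(xr[i_lo])) {
    tip_i <- i_hi
  } else {
    # exact tie: larger |rotated x| is equal, fall back to smaller original y
    tip_i <- if (pixels$y[i_lo] <= pixels$y[i_hi]) i_lo else i_hi
  }
  d <- sqrt((pixels$x - pixels$x[tip_i])^2 + (pixels$y - pixels$y[tip_i])^2)
  rk <- integer(length(d))
  rk[order(d, seq_along(d))] <- seq_along(d)
  out <- tibble::as_tibble(pixels)
  out$distance <- d
  out$rank <- rk
  structure(
    list(tip = c(x = pixels$x[tip_i], y = pixels$y[tip_i]),
         frame = frame, pixels = out),
    class = "tip_result"
  )
}
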