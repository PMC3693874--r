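# Low-level planar geometry used by the stadium (rod) shapes.
# Convention throughout the package: x = column, y = row, pixel centers at
# integer coordinates starting at (1, 1); all lengths in pixels.

#' Distance from points to a line segment
#'
#' Vectorised Euclidean distance from one or more points to the segment
#' joining `a` and `b`. Degenerate segments (`a == b`) reduce to the distance
#' to the point.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param a,b numeric length-2 endpoints `c(x, y)`.
#' @return numeric vector of distances.
#' @keywords internal
point_segment_distance <- function(px, py, a, b) {
  vx <- b[1] - a[1]
  vy <- b[2] - a[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) {
    return(sqrt((px - a[1])^2 + (py - a[2])^2))
  }
  t <- pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / len2))
  sqrt((px - a[1] - t * vx)^2 + (py - a[2] - t * vy)^2)
}

#' Signed distance to a stadium boundary
#'
#' A stadium (discorectangle) is the set of points within `radius` of the
#' axis segment `a`--`b`. Negative values are inside.
#'
#' @inheritParams point_segment_distance
#' @param radius stadium radius in px.
#' @keywords internal
stadium_signed_distance <- function(px, py, a, b, radius) {
  point_segment_distance(px, py, a, b) - radius
}

# C2-continuous edge profile (quintic smootherstep) over a 1-px band:
# 1 well inside (sd <= -0.5), 0 well outside (sd >= 0.5). Twice-continuous
# differentiability in the signed distance keeps the contrast energy smooth
# enough for step-consistent finite-difference gradients.
edge_profile <- function(sd) {
  t <- pmin(1, pmax(0, 0.5 - sd))
  t * t * t * (10 + t * (-15 + 6 * t))
}

#' Anti-aliased stadium coverage weight
#'
#' Smooth 1-px ramp across the boundary: 1 well inside, 0 well outside,
#' C2-continuous in between. Used both to rasterise phantom cells and to
#' integrate the contrast energy; smoothness in the shape parameters keeps
#' finite-difference gradients stable.
#'
#' @inheritParams stadium_signed_distance
#' @keywords internal
stadium_coverage <- function(px, py, a, b, radius) {
  edge_profile(stadium_signed_distance(px, py, a, b, radius))
}

# Minimum distance between two segments a1-b1 and a2-b2 (used for the
# cell-overlap check: two stadiums are disjoint iff the segment distance
# exceeds the sum of their radii).
segment_segment_distance <- function(a1, b1, a2, b2) {
  ends <- min(
    point_segment_distance(a2[1], a2[2], a1, b1),
    point_segment_distance(b2[1], b2[2], a1, b1),
    point_segment_distance(a1[1], a1[2], a2, b2),
    point_segment_distance(b1[1], b1[2], a2, b2)
  )
  # if the segments properly intersect the distance is 0
  d1 <- b1 - a1
  d2 <- b2 - a2
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) > 1e-12) {
    t <- ((a2[1] - a1[1]) * d2[2] - (a2[2] - a1[2]) * d2[1]) / den
    u <- ((a2[1] - a1[1]) * d1[2] - (a2[2] - a1[2]) * d1[1]) / den
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1) {
      return(0)
    }
  }
  ends
}

# Wrap an angle into (-pi/2, pi/2] (orientation of an undirected axis).
normalize_orientation <- function(theta) {
  th <- theta %% pi
  if (th > pi / 2) th <- th - pi
  if (th <= -pi / 2) th <- th + pi
  th
}

# Reflect out-of-range indices at the image border (mirror boundary).
mirror_index <- function(idx, n) {
  out <- idx
  out[out < 1] <- 2 - out[out < 1]
  out[out > n] <- 2 * n - out[out > n]
  pmin(pmax(out, 1), n)
}
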