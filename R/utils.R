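# Small numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped.
#' @keywords internal
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; the convention here is (-180, 180]
  w[w == -180] <- 180
  w
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Angle a-b-c in degrees (vertex at b).
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Dihedral angle defined by four points, in degrees, wrapped to (-180, 180].
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("cyclicdesign_invalid_input", "error")))
}

# Rotation matrix for angle `theta` (radians) about unit axis `ax`
# (Rodrigues), acting on column vectors.
rotation_about_axis <- function(ax, theta) {
  k <- unit(ax)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
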