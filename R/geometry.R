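## Internal 3D geometry helpers shared by the feature engine and the
## fixture builder. All coordinates are in Angstrom, all angles in degrees.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Standard IUPAC sign convention: looking from `b` to `c`, the angle is
#' positive when `d` is rotated clockwise relative to `a`. Result in
#' degrees within (-180, 180].
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## NeRF atom placement: position a new atom D bonded to C, with bond
## length |CD|, bond angle B-C-D and torsion A-B-C-D. Used to grow
## fixture structures from internal coordinates, so placement must be
## the exact inverse of dihedralAngle().
.placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Angle at vertex b (degrees)
.bondAngle <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Deterministic quasi-uniform points on the unit sphere (golden spiral);
## used by the surface-area sampler.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Rigid-body transform of an n x 3 coordinate matrix: rotation about
## axis (unit vector) by angle degrees, then translation. Used by the
## invariance tests.
#' Apply a rigid-body motion to a coordinate matrix
#'
#' @param xyz n x 3 coordinate matrix.
#' @param axis Rotation axis (length-3, need not be unit).
#' @param angleDeg Rotation angle in degrees.
#' @param translation Length-3 translation vector.
#' @return Transformed n x 3 matrix.
#' @export
rigidTransform <- function(xyz, axis = c(0, 0, 1), angleDeg = 0,
                           translation = c(0, 0, 0)) {
  u <- .unit(axis)
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(xyz %*% t(R), 2, translation, "+")
}
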