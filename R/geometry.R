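# Vector geometry primitives shared by every module: torsions, bond angles
# and the internal-to-Cartesian (NeRF) atom placement used by the builder.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed torsion angle between four points
#'
#' Computes the standard signed dihedral about the p2--p3 axis, in degrees,
#' in the interval (-180, 180]. Positive angles follow the IUPAC convention
#' (clockwise rotation of p4 relative to p1 when viewed from p2 towards p3).
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates in Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("dihedral: consecutive points coincide")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("dihedral: collinear points, torsion undefined")
  m1 <- vcross(b2 / vnorm(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle at p2, in degrees
#' @param p1,p2,p3 Numeric length-3 coordinates.
#' @return Angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Place a new atom X given three reference atoms so that |X - p3| = bond,
# angle(p2, p3, X) = angle and dihedral(p1, p2, p3, X) = torsion.
place_atom <- function(p1, p2, p3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- p3 - p2
  bc <- bc / vnorm(bc)
  ab <- p2 - p1
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  p3 + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Wrapped angular difference in degrees, result in [0, 180].
wrap_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Rotation matrix for rotation by theta (degrees) about unit axis u.
rotation_matrix <- function(axis, theta) {
  u <- axis / vnorm(axis)
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}
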