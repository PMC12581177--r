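# Low-level 3-D geometry used by the builder and the torsion engine.
# All coordinates are in Angstrom, all angles in degrees unless noted.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle defined by three points
#'
#' @param a,b,c numeric 3-vectors; the angle is measured at \code{b}.
#' @return angle in degrees, in \code{[0, 180]}.
#' @keywords internal
.pointAngle <- function(a, b, c) {
  u <- .vunit(a - b)
  v <- .vunit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle of four points
#'
#' Signed torsion angle a-b-c-d about the b-c axis, IUPAC sign convention
#' (right-handed rotation of d about b->c increases the angle).
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral in degrees, in \code{(-180, 180]}.
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  ang <- .rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle difference into (-180, 180].
.wrapAngle <- function(x) {
  x <- x %% 360
  x[x > 180] <- x[x > 180] - 360
  x
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given positions of three reference atoms a-b-c, returns the position d such
#' that |c-d| = bond, angle(b,c,d) = theta and dihedral(a,b,c,d) = phi.
#'
#' @param a,b,c numeric 3-vectors.
#' @param bond bond length c-d in Angstrom.
#' @param theta bond angle at c, degrees.
#' @param phi dihedral a-b-c-d, degrees.
#' @keywords internal
.nerfPlace <- function(a, b, c, bond, theta, phi) {
  th <- .deg2rad(theta)
  ph <- .deg2rad(phi)
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Rotate points about an arbitrary axis
#'
#' Right-handed (counter-clockwise looking down the axis vector) rotation of
#' \code{xyz} by \code{angle} degrees about the line through \code{origin} with
#' direction \code{axis}.
#'
#' @param xyz n x 3 matrix.
#' @param origin point on the axis.
#' @param axis direction vector (need not be unit length).
#' @param angle degrees.
#' @return rotated n x 3 matrix.
#' @keywords internal
.rotateAboutAxis <- function(xyz, origin, axis, angle) {
  if (angle == 0) return(xyz)
  u <- .vunit(axis)
  th <- .deg2rad(angle)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shifted <- sweep(xyz, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, FUN = "+")
}

# The two free substituent directions of a tetrahedral centre that already has
# two substituents along u1 and u2 (unit vectors from the centre). Returned as
# a 2 x 3 matrix of unit vectors; row order is (+n, -n) with n = u1 x u2, which
# fixes chirality for the caller.
.tetrahedralDirections <- function(u1, u2) {
  b <- -.vunit(u1 + u2)
  n <- .vunit(.vcross(u1, u2))
  half <- .deg2rad(109.47 / 2)
  v1 <- .vunit(b * cos(half) + n * sin(half))
  v2 <- .vunit(b * cos(half) - n * sin(half))
  rbind(v1, v2)
}
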