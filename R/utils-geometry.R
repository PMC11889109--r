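# Low-level vector geometry shared across the package. All coordinates are in
# Angstrom, all angles in degrees unless a function name says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' Values exactly at -180 map to +180 so every angle has one representative.
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the direction `axis`
#' (right-handed, axis need not be normalized).
#'
#' @param axis length-3 numeric direction.
#' @param angle rotation angle in degrees.
#' @return a 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

rot_z <- function(angle) rotation_about_axis(c(0, 0, 1), angle)
rot_y <- function(angle) rotation_about_axis(c(0, 1, 0), angle)
rot_x <- function(angle) rotation_about_axis(c(1, 0, 0), angle)

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: looking down the b-c axis, the angle from the
#' a-b bond to the c-d bond, positive clockwise. Result in (-180, 180].
#'
#' @param a,b,c,d length-3 numeric coordinates.
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(-rad2deg(atan2(y, x)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place an atom from internal coordinates (NERF construction): the new atom is
# at `bond` Angstrom from atom C, with angle B-C-new of `angle` degrees and
# torsion A-B-C-new of `torsion` degrees.
place_atom_zmat <- function(A, B, C, bond, angle, torsion) {
  bc <- unit(C - B)
  n <- unit(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  th <- deg2rad(180 - angle)
  ph <- deg2rad(torsion)
  d2 <- bond * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed angle from vector u to vector v measured about axis `ax` (degrees).
signed_angle_about <- function(u, v, ax) {
  ax <- unit(ax)
  u <- u - sum(u * ax) * ax
  v <- v - sum(v * ax) * ax
  rad2deg(atan2(sum(pracma_cross(u, v) * ax), sum(u * v)))
}
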