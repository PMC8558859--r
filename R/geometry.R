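# Small 3-D geometry kernel shared by the builder, the classifier and the
# synthetic-trajectory generator. Coordinates are row-wise n x 3 matrices in nm.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` degrees about the unit direction `axis`.
#' Positive angles are right-handed (counter-clockwise looking down the axis
#' toward the origin).
#'
#' @param axis numeric length-3 direction (normalized internally).
#' @param theta rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, theta) {
  stopifnot(length(axis) == 3, is.finite(theta))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length", call. = FALSE)
  u <- axis / n
  th <- theta * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotate points (n x 3) about a line through `origin` with direction `axis`
rotate_about_axis <- function(xyz, axis, theta, origin = c(0, 0, 0)) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle (IUPAC convention) of the bond b--c viewed from
#' a--b--c--d, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate (collinear) atoms in dihedral definition", call. = FALSE)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame (NeRF) placement: position a fourth atom
# given three predecessors, a bond length, a bond angle (deg, at c) and a
# dihedral (deg, about b--c).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  as.vector(c + cbind(bc, m, n) %*% d2)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain (unsuperposed) RMSD: the square root of the mean squared atom
#' displacement over paired rows. No fitting is performed.
#'
#' @param a,b n x 3 coordinate matrices with matching rows.
#' @return RMSD in the coordinate units.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b), nrow(a) > 0)
  sqrt(mean(rowSums((a - b)^2)))
}
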