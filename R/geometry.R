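# Internal-coordinate geometry helpers (NeRF atom placement, dihedrals,
# minimum-image distances).  All lengths Angstrom, all angles degrees at the
# interface, radians internally.

.deg2rad <- function(x) x * pi / 180

.vnorm <- function(v) sqrt(sum(v * v))
.vunit <- function(v) v / .vnorm(v)
.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C, bond length |CD|, angle BCD (deg),
# dihedral ABCD (deg).  Standard natural-extension reference frame.
.place_atom <- function(A, B, C, length, angle, dihedral) {
  th <- .deg2rad(angle)
  ph <- .deg2rad(dihedral)
  bc <- .vunit(C - B)
  n  <- .vunit(.vcross(B - A, bc))
  m  <- .vcross(n, bc)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Dihedral angle ABCD in degrees, in (-180, 180].
.dihedral <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -atan2(y, x) * 180 / pi
}

.angle_deg <- function(A, B, C) {
  u <- A - B; v <- C - B
  acos(max(-1, min(1, sum(u * v) / (.vnorm(u) * .vnorm(v))))) * 180 / pi
}

# Minimum-image displacement(s) for a cubic box of side L (L <= 0: no PBC).
# dx may be a vector of length 3 or an n x 3 matrix.
.min_image <- function(dx, L) {
  if (is.null(L) || is.na(L) || L <= 0) return(dx)
  dx - L * round(dx / L)
}

# Pairwise minimum-image distance matrix between two coordinate matrices.
.dist_pbc <- function(a, b, L) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- .min_image(d, L)
    out <- out + d * d
  }
  sqrt(out)
}

# Rotation matrix for angle (rad) about unit axis.
.rot_axis <- function(axis, angle) {
  u <- .vunit(axis); ca <- cos(angle); sa <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ca + ux^2 * (1 - ca),      ux * uy * (1 - ca) - uz * sa, ux * uz * (1 - ca) + uy * sa,
    uy * ux * (1 - ca) + uz * sa, ca + uy^2 * (1 - ca),      uy * uz * (1 - ca) - ux * sa,
    uz * ux * (1 - ca) - uy * sa, uz * uy * (1 - ca) + ux * sa, ca + uz^2 * (1 - ca)),
    3, 3, byrow = TRUE)
}
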