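# Low-level vector geometry shared across modules. All coordinates are
# orthogonal Angstroms; angles in degrees unless noted.

cross3 <- function(a, b) {
  c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3], a[1]*b[2] - a[2]*b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) v / vnorm(v)

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be unit length)
#' @param theta rotation angle in radians
#' @return 3x3 rotation matrix
#' @export
rotAxis <- function(axis, theta) {
  u <- unitv(axis); ct <- cos(theta); st <- sin(theta)
  u1 <- u[1]; u2 <- u[2]; u3 <- u[3]
  matrix(c(ct + u1^2*(1-ct),   u1*u2*(1-ct) - u3*st, u1*u3*(1-ct) + u2*st,
           u2*u1*(1-ct) + u3*st, ct + u2^2*(1-ct),   u2*u3*(1-ct) - u1*st,
           u3*u1*(1-ct) - u2*st, u3*u2*(1-ct) + u1*st, ct + u3^2*(1-ct)),
         3, 3, byrow = TRUE)
}

#' Signed dihedral angle (degrees) defined by four points
#' @keywords internal
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180/pi
}

#' Bond angle (degrees) at vertex b
#' @keywords internal
bondAngle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180/pi
}

# Place atom D from reference atoms A-B-C with bond |CD|, angle B-C-D and
# torsion A-B-C-D (natural extension reference frame).
nerfPlace <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi/180; tor <- -torsion * pi/180
  bc <- unitv(c - b)
  n  <- unitv(cross3(b - a, bc))
  m  <- cross3(n, bc)
  d  <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1]*bc + d[2]*m + d[3]*n
}

# All pairwise distances between two coordinate matrices (rows = points).
crossDist <- function(A, B) {
  dd <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(dd, 0))
}

# wrap angular difference into [0, 180]
circularDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
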