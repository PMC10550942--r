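# Small 3-vector helpers used throughout the geometric construction.
# All take/return plain numeric length-3 vectors; distances in Angstrom,
# angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two vectors in degrees
#' @noRd
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

#' Dihedral angle a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Circular (wrapped) difference of two angles in degrees, result in [0, 180]
#' @noRd
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Place an atom by internal coordinates (natural extension reference frame).
#'
#' Returns the position of atom D given positions of A, B, C, the bond length
#' C-D, the angle B-C-D (degrees) and the dihedral A-B-C-D (degrees).
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotate vector v about unit axis k by theta degrees (Rodrigues)
#' @noRd
rotate_about <- function(v, k, theta) {
  k <- unitv(k); th <- deg2rad(theta)
  v * cos(th) + vcross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

#' An arbitrary unit vector perpendicular to v (deterministic)
#' @noRd
any_perp <- function(v) {
  v <- unitv(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(vcross(v, ref))
}

# Row-wise euclidean distances between an n x 3 matrix and a point
dist_to_point <- function(xyz, p) {
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

atoms_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
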