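# Primitive 3D measurements shared by all interaction detectors.
# Units: Angstroms for lengths, degrees for user-facing angles.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

#' Interior angle at a vertex
#'
#' Computes the angle a-b-c (at vertex `b`) between the arms `b -> a` and
#' `b -> c`, in degrees.
#'
#' @param a,b,c Numeric 3-vectors (coordinates in Angstroms).
#' @return The angle in degrees, in `[0, 180]`.
#' @examples
#' angle_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
angle_deg <- function(a, b, c) {
  u <- a - b
  w <- c - b
  nu <- vec_norm(u)
  nw <- vec_norm(w)
  if (nu < 1e-12 || nw < 1e-12)
    stop("angle_deg: zero-length arm (a or c coincides with vertex b)", call. = FALSE)
  cs <- sum(u * w) / (nu * nw)
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}

#' Centroid and best-fit plane of an atom ring
#'
#' Fits a plane to `>= 3` non-collinear points by least squares (the
#' principal direction of smallest variance of the centered coordinates)
#' and returns the ring centroid plus a unit normal. The normal's sign is
#' made deterministic: its z-component is non-negative; on a z-tie the
#' y-component decides, then x.
#'
#' @param coords Numeric matrix with one row per atom and 3 columns (x, y, z).
#' @param atom_ids Optional identifiers stored alongside the frame.
#' @return An object of class `ring_frame`: list with `centroid` (3-vector),
#'   `normal` (unit 3-vector) and `atom_ids`.
#' @export
ring_frame <- function(coords, atom_ids = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L || ncol(coords) != 3L)
    stop("ring_frame: need at least 3 points with 3 coordinates each", call. = FALSE)
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  # collinear iff the second singular value vanishes relative to the first
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("ring_frame: points are collinear (degenerate ring)", call. = FALSE)
  normal <- sv$v[, 3]
  normal <- normal / vec_norm(normal)
  # sign convention: first non-zero of (z, y, x) made positive
  for (k in c(3L, 2L, 1L)) {
    if (abs(normal[k]) > 1e-9) {
      if (normal[k] < 0) normal <- -normal
      break
    }
  }
  structure(
    list(centroid = centroid, normal = normal, atom_ids = atom_ids),
    class = "ring_frame"
  )
}

#' Acute angle between two planes
#'
#' Given two plane normals, returns the acute dihedral between the planes:
#' `min(theta, 180 - theta)` of the angle between the normals, so the result
#' lies in `[0, 90]` and antiparallel normals give 0.
#'
#' @param n1,n2 Unit 3-vectors. Inputs whose norm differs from 1 by no more
#'   than `1e-6` are normalized silently; anything further off is an error.
#' @return Angle in degrees in `[0, 90]`.
#' @export
plane_angle_deg <- function(n1, n2) {
  n1 <- check_unit(n1, "n1")
  n2 <- check_unit(n2, "n2")
  cs <- abs(sum(n1 * n2))
  cs <- min(1, cs)
  acos(cs) * 180 / pi
}

check_unit <- function(v, what) {
  n <- vec_norm(v)
  if (abs(n - 1) > 1e-6)
    stop(sprintf("plane_angle_deg: %s is not a unit vector (|v| = %g)", what, n),
         call. = FALSE)
  v / n
}

# Rotation matrix for angle `deg` (degrees) about unit axis `axis`
# (Rodrigues' formula). Used by the fixture generator to realize angular
# parameters exactly.
rotation_about <- function(axis, deg) {
  u <- unit_vec(axis)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}
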