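# Geometry kernels: dihedrals, internal-coordinate atom placement, rotations
# about arbitrary axes, least-squares rigid superposition. Angles are degrees
# at every interface; radians appear only inside the kernels.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 using the standard IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * .rad2deg
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * .rad2deg
}

# place an atom at (bond, angle, dihedral) from parent c, grandparent b,
# great-grandparent a (NeRF construction)
place_atom <- function(a, b, c, bond, angle, dih) {
  ang <- angle * .deg2rad
  tor <- dih * .deg2rad
  bc <- unit_vector(c - b)
  n <- unit_vector(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# 3x3 rotation matrix for angle theta (degrees) about unit axis
rotation_matrix <- function(axis, theta) {
  u <- unit_vector(axis)
  th <- theta * .deg2rad
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux * ux * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# rotate rows of `xyz` by theta degrees about the axis through `origin`
rotate_about_axis <- function(xyz, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  shifted <- sweep(xyz, 2, origin)
  sweep(shifted %*% t(R), 2, origin, FUN = "+")
}

#' Least-squares rigid superposition over mapped atoms
#'
#' Kabsch superposition of a mobile coordinate set onto a reference over an
#' explicit atom mapping. Returns the rigid transform and the post-fit RMSD;
#' the inputs are not modified.
#'
#' @param mobile,reference Numeric matrices with 3 columns (Angstrom), or
#'   objects with a `coords` matrix.
#' @param atom_map Two-column integer matrix of (mobile row, reference row)
#'   pairs; default maps row i to row i.
#' @return List with `rotation` (3x3), `translation` (length 3; the transform
#'   is `x %*% t(rotation) + translation`), `rmsd` (Angstrom over mapped
#'   atoms) and `transform(xyz)`, a function applying the fit to a copy.
#' @export
superpose_by_mapping <- function(mobile, reference, atom_map = NULL) {
  xm <- as_coord_matrix(mobile)
  xr <- as_coord_matrix(reference)
  if (is.null(atom_map)) {
    if (nrow(xm) != nrow(xr)) stop("atom_map required when sizes differ")
    atom_map <- cbind(seq_len(nrow(xm)), seq_len(nrow(xm)))
  }
  atom_map <- as.matrix(atom_map)
  if (nrow(atom_map) < 3) stop("superposition needs at least 3 mapped atoms")
  A <- xm[atom_map[, 1], , drop = FALSE]
  B <- xr[atom_map[, 2], , drop = FALSE]
  # degenerate (collinear) reference atoms have a rank-deficient covariance
  Bc <- sweep(B, 2, colMeans(B))
  if (svd(Bc)$d[2] < 1e-8) stop("mapped reference atoms are collinear or degenerate")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, tr, FUN = "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  transform <- function(xyz) sweep(as_coord_matrix(xyz) %*% t(R), 2, tr, FUN = "+")
  list(rotation = R, translation = tr, rmsd = rmsd, transform = transform)
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  if (is.list(x) && !is.null(x$coords)) return(as_coord_matrix(x$coords))
  if (inherits(x, "cm_ligand")) return(ligand_coords(x))
  stop("cannot interpret object as coordinates")
}

#' Root-mean-square deviation between two matched coordinate sets
#' @param a,b Matrices with matching rows.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
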