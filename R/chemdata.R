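# Static chemical data: amino-acid side-chain topology (ideal internal
# coordinates), chi definitions, polar hydrogen / donor / acceptor tables and
# Lennard-Jones element parameters for the reference energy function.
#
# Side chains are described as Z-matrix rows built off the backbone frame
# (N, CA, C). Each atom is placed at (bond, angle, dihedral) from
# (parent, gp, ggp); the dihedral is either fixed (`chi = 0`) or chi-driven
# (`chi = k`, value = chi_k + `dih` offset). Hydrogens listed here are polar
# hydrogens only; apolar hydrogens are not modelled.

#' One-letter codes of the twenty canonical amino acids
#' @format Character vector of length 20.
#' @export
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA1_FROM_3 <- stats::setNames(names(AA3), unname(AA3))

#' Canonical chi counts of the twenty amino acids
#'
#' Number of heavy-atom side-chain dihedrals per amino acid (proline's two
#' ring torsions are counted; proton chis of Ser/Thr/Tyr are not).
#'
#' @format Named integer vector over one-letter codes.
#' @export
CHI_COUNTS <- c(A = 0L, R = 4L, N = 2L, D = 2L, C = 1L, Q = 3L, E = 3L,
                G = 0L, H = 2L, I = 2L, L = 2L, K = 4L, M = 3L, F = 2L,
                P = 2L, S = 1L, T = 1L, W = 2L, Y = 2L, V = 1L)

# one extra hydroxyl proton chi
PROTON_CHI <- c(S = 1L, T = 1L, Y = 1L)

# improper dihedral C-N-CA-CB for L-amino acids (measured convention, +123)
.LCB_DIH <- 122.6

.zrow <- function(atom, element, parent, gp, ggp, bond, angle, chi, dih) {
  data.frame(atom = atom, element = element, parent = parent, gp = gp,
             ggp = ggp, bond = bond, angle = angle, chi = chi, dih = dih,
             stringsAsFactors = FALSE)
}

.cb <- .zrow("CB", "C", "CA", "N", "C", 1.530, 110.5, 0L, .LCB_DIH)

# nolint start: long data block
.SC_TOPOLOGY <- list(
  G = NULL,
  A = .cb,
  S = rbind(.cb,
    .zrow("OG",  "O", "CB", "CA", "N",  1.417, 110.8, 1L, 0),
    .zrow("HG",  "H", "OG", "CB", "CA", 0.960, 109.5, 2L, 0)),
  C = rbind(.cb,
    .zrow("SG",  "S", "CB", "CA", "N",  1.808, 114.4, 1L, 0)),
  T = rbind(.cb,
    .zrow("OG1", "O", "CB", "CA", "N",  1.433, 109.5, 1L, 0),
    .zrow("CG2", "C", "CB", "CA", "N",  1.521, 110.5, 1L, -120),
    .zrow("HG1", "H", "OG1","CB", "CA", 0.960, 109.5, 2L, 0)),
  V = rbind(.cb,
    .zrow("CG1", "C", "CB", "CA", "N",  1.521, 110.5, 1L, 0),
    .zrow("CG2", "C", "CB", "CA", "N",  1.521, 110.5, 1L, -122)),
  L = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.530, 116.3, 1L, 0),
    .zrow("CD1", "C", "CG", "CB", "CA", 1.521, 110.7, 2L, 0),
    .zrow("CD2", "C", "CG", "CB", "CA", 1.521, 110.7, 2L, 122)),
  I = rbind(.cb,
    .zrow("CG1", "C", "CB", "CA", "N",  1.530, 110.4, 1L, 0),
    .zrow("CG2", "C", "CB", "CA", "N",  1.521, 110.5, 1L, -122),
    .zrow("CD1", "C", "CG1","CB", "CA", 1.513, 113.8, 2L, 0)),
  M = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.520, 114.1, 1L, 0),
    .zrow("SD",  "S", "CG", "CB", "CA", 1.803, 112.7, 2L, 0),
    .zrow("CE",  "C", "SD", "CG", "CB", 1.791, 100.9, 3L, 0)),
  P = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.492, 104.5, 1L, 0),
    .zrow("CD",  "C", "CG", "CB", "CA", 1.503, 105.5, 2L, 0)),
  F = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.502, 113.8, 1L, 0),
    .zrow("CD1", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 0),
    .zrow("CD2", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 180),
    .zrow("CE1", "C", "CD1","CG", "CB", 1.382, 121.0, 0L, 180),
    .zrow("CE2", "C", "CD2","CG", "CB", 1.382, 121.0, 0L, 180),
    .zrow("CZ",  "C", "CE1","CD1","CG", 1.378, 120.1, 0L, 0)),
  Y = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.502, 113.8, 1L, 0),
    .zrow("CD1", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 0),
    .zrow("CD2", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 180),
    .zrow("CE1", "C", "CD1","CG", "CB", 1.382, 121.0, 0L, 180),
    .zrow("CE2", "C", "CD2","CG", "CB", 1.382, 121.0, 0L, 180),
    .zrow("CZ",  "C", "CE1","CD1","CG", 1.378, 120.1, 0L, 0),
    .zrow("OH",  "O", "CZ", "CE1","CD1",1.376, 119.9, 0L, 180),
    .zrow("HH",  "H", "OH", "CZ", "CE1",0.960, 109.5, 3L, 0)),
  W = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.498, 113.6, 1L, 0),
    .zrow("CD1", "C", "CG", "CB", "CA", 1.365, 126.9, 2L, 0),
    .zrow("CD2", "C", "CG", "CB", "CA", 1.433, 126.7, 2L, 180),
    .zrow("NE1", "N", "CD1","CG", "CB", 1.374, 110.2, 0L, 180),
    .zrow("CE2", "C", "CD2","CG", "CB", 1.409, 107.2, 0L, 180),
    .zrow("CE3", "C", "CD2","CE2","NE1",1.398, 133.9, 0L, 180),
    .zrow("CZ2", "C", "CE2","CD2","CG", 1.394, 122.4, 0L, 180),
    .zrow("CZ3", "C", "CE3","CD2","CE2",1.382, 118.7, 0L, 180),
    .zrow("CH2", "C", "CZ2","CE2","CD2",1.368, 117.5, 0L, 180),
    .zrow("HE1", "H", "NE1","CD1","CG", 1.010, 125.0, 0L, 180)),
  D = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.516, 112.6, 1L, 0),
    .zrow("OD1", "O", "CG", "CB", "CA", 1.249, 118.4, 2L, 0),
    .zrow("OD2", "O", "CG", "CB", "CA", 1.249, 118.4, 2L, 180)),
  E = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.520, 114.1, 1L, 0),
    .zrow("CD",  "C", "CG", "CB", "CA", 1.516, 112.6, 2L, 0),
    .zrow("OE1", "O", "CD", "CG", "CB", 1.249, 118.4, 3L, 0),
    .zrow("OE2", "O", "CD", "CG", "CB", 1.249, 118.4, 3L, 180)),
  N = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.516, 112.6, 1L, 0),
    .zrow("OD1", "O", "CG", "CB", "CA", 1.231, 120.8, 2L, 0),
    .zrow("ND2", "N", "CG", "CB", "CA", 1.328, 116.4, 2L, 180),
    .zrow("HD21","H", "ND2","CG", "CB", 1.010, 120.0, 0L, 0),
    .zrow("HD22","H", "ND2","CG", "CB", 1.010, 120.0, 0L, 180)),
  Q = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.520, 114.1, 1L, 0),
    .zrow("CD",  "C", "CG", "CB", "CA", 1.516, 112.6, 2L, 0),
    .zrow("OE1", "O", "CD", "CG", "CB", 1.231, 120.8, 3L, 0),
    .zrow("NE2", "N", "CD", "CG", "CB", 1.328, 116.4, 3L, 180),
    .zrow("HE21","H", "NE2","CD", "CG", 1.010, 120.0, 0L, 0),
    .zrow("HE22","H", "NE2","CD", "CG", 1.010, 120.0, 0L, 180)),
  H = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.497, 113.8, 1L, 0),
    .zrow("ND1", "N", "CG", "CB", "CA", 1.371, 122.7, 2L, 0),
    .zrow("CD2", "C", "CG", "CB", "CA", 1.356, 131.2, 2L, 180),
    .zrow("CE1", "C", "ND1","CG", "CB", 1.319, 109.3, 0L, 180),
    .zrow("NE2", "N", "CD2","CG", "CB", 1.374, 107.2, 0L, 180)),
  K = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.520, 114.1, 1L, 0),
    .zrow("CD",  "C", "CG", "CB", "CA", 1.520, 111.3, 2L, 0),
    .zrow("CE",  "C", "CD", "CG", "CB", 1.520, 111.3, 3L, 0),
    .zrow("NZ",  "N", "CE", "CD", "CG", 1.489, 111.9, 4L, 0),
    .zrow("HZ1", "H", "NZ", "CE", "CD", 1.010, 109.5, 0L, 60),
    .zrow("HZ2", "H", "NZ", "CE", "CD", 1.010, 109.5, 0L, 180),
    .zrow("HZ3", "H", "NZ", "CE", "CD", 1.010, 109.5, 0L, -60)),
  R = rbind(.cb,
    .zrow("CG",  "C", "CB", "CA", "N",  1.520, 114.1, 1L, 0),
    .zrow("CD",  "C", "CG", "CB", "CA", 1.520, 111.3, 2L, 0),
    .zrow("NE",  "N", "CD", "CG", "CB", 1.461, 112.0, 3L, 0),
    .zrow("CZ",  "C", "NE", "CD", "CG", 1.329, 124.2, 4L, 0),
    .zrow("NH1", "N", "CZ", "NE", "CD", 1.326, 120.0, 0L, 0),
    .zrow("NH2", "N", "CZ", "NE", "CD", 1.326, 120.0, 0L, 180),
    .zrow("HE",  "H", "NE", "CZ", "NH1",1.010, 120.0, 0L, 180),
    .zrow("HH11","H", "NH1","CZ", "NE", 1.010, 120.0, 0L, 0),
    .zrow("HH12","H", "NH1","CZ", "NE", 1.010, 120.0, 0L, 180),
    .zrow("HH21","H", "NH2","CZ", "NE", 1.010, 120.0, 0L, 0),
    .zrow("HH22","H", "NH2","CZ", "NE", 1.010, 120.0, 0L, 180))
)
# nolint end

# extra covalent bonds closing rings (beyond the parent links of the Z-matrix)
.RING_CLOSURES <- list(
  F = rbind(c("CZ",  "CE2")),
  Y = rbind(c("CZ",  "CE2")),
  H = rbind(c("CE1", "NE2")),
  W = rbind(c("NE1", "CE2"), c("CZ3", "CH2")),
  P = rbind(c("CD",  "N"))
)

# hydrogen-bond roles: donor polar hydrogens (atom -> base heavy atom) and
# acceptor heavy atoms, per amino acid (side chains; backbone handled
# generically: amide H donates, carbonyl O accepts)
.HB_DONOR_H <- list(
  S = c(HG = "OG"), T = c(HG1 = "OG1"), Y = c(HH = "OH"),
  N = c(HD21 = "ND2", HD22 = "ND2"), Q = c(HE21 = "NE2", HE22 = "NE2"),
  K = c(HZ1 = "NZ", HZ2 = "NZ", HZ3 = "NZ"),
  R = c(HE = "NE", HH11 = "NH1", HH12 = "NH1", HH21 = "NH2", HH22 = "NH2"),
  W = c(HE1 = "NE1")
)

.HB_ACCEPTORS <- list(
  S = "OG", T = "OG1", Y = "OH",
  D = c("OD1", "OD2"), E = c("OE1", "OE2"),
  N = "OD1", Q = "OE1", H = c("ND1", "NE2")
)

# Lennard-Jones element parameters: radius (Angstrom, sigma_pair = r_i + r_j)
# and well depth (energy units, eps_pair = sqrt(e_i e_j))
.LJ_PARAMS <- list(
  C  = c(r = 1.75, e = 0.080),
  N  = c(r = 1.55, e = 0.170),
  O  = c(r = 1.50, e = 0.160),
  S  = c(r = 1.80, e = 0.250),
  H  = c(r = 0.90, e = 0.020),
  P  = c(r = 1.90, e = 0.200),
  F  = c(r = 1.47, e = 0.080),
  CL = c(r = 1.75, e = 0.250),
  BR = c(r = 1.85, e = 0.300),
  I  = c(r = 2.00, e = 0.350)
)

lj_radius <- function(element) {
  el <- toupper(element)
  vapply(el, function(e) {
    p <- .LJ_PARAMS[[e]]
    if (is.null(p)) .LJ_PARAMS[["C"]][["r"]] else p[["r"]]
  }, numeric(1), USE.NAMES = FALSE)
}

lj_eps <- function(element) {
  el <- toupper(element)
  vapply(el, function(e) {
    p <- .LJ_PARAMS[[e]]
    if (is.null(p)) .LJ_PARAMS[["C"]][["e"]] else p[["e"]]
  }, numeric(1), USE.NAMES = FALSE)
}

# ideal backbone geometry (helix builder, hydrogen placement)
.BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.1
)

sc_topology <- function(aa) {
  if (!aa %in% AA1) stop("unknown amino acid code: ", aa)
  .SC_TOPOLOGY[[aa]]
}

# 4-atom name tuples defining each canonical chi of `aa`
chi_atom_tuples <- function(aa) {
  topo <- sc_topology(aa)
  n <- CHI_COUNTS[[aa]]
  if (n == 0L) return(list())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    row <- topo[topo$chi == k & topo$dih == 0 & topo$element != "H", , drop = FALSE][1, ]
    out[[k]] <- c(row$ggp, row$gp, row$parent, row$atom)
  }
  out
}
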