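# Ligand model: one fixed atom topology (atoms + bonds), a set of discrete
# conformers over that topology, and a rigid-body frame applied to the active
# conformer. Conformer coordinates are stored frame-free; the frame composes
# rigid-body Monte Carlo moves without touching the conformer library.

#' Construct a ligand
#'
#' @param atoms Tibble/data frame with columns `name` and `element`.
#' @param bonds Two-column integer matrix of bonded atom index pairs (may
#'   have zero rows for a single-atom probe).
#' @param conformers List of coordinate matrices (same atom count and order).
#' @param resname HETATM residue code used in PDB output.
#' @param chain Chain identifier for PDB output.
#' @param seqpos Residue number for PDB output.
#' @return Object of class `cm_ligand` with identity frame and active
#'   conformer 1.
#' @export
new_ligand <- function(atoms, bonds, conformers, resname = "LIG",
                       chain = "X", seqpos = 1L) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "element") %in% names(atoms)))
  n <- nrow(atoms)
  conformers <- lapply(conformers, function(x) {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("conformer atom count differs from topology")
    dimnames(x) <- NULL
    x
  })
  if (length(conformers) == 0L) stop("ligand needs at least one conformer")
  bonds <- if (is.null(bonds) || length(bonds) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    as.matrix(bonds)
  }
  structure(list(atoms = atoms, bonds = bonds, conformers = conformers,
                 frame = list(R = diag(3), t = c(0, 0, 0)),
                 active_conformer = 1L, resname = resname, chain = chain,
                 seqpos = as.integer(seqpos)),
            class = "cm_ligand")
}

#' Coordinates of a ligand conformer with the rigid-body frame applied
#'
#' @param ligand A ligand.
#' @param conformer Conformer index (default the active conformer).
#' @param frame Optional frame override (list with 3x3 `R` and length-3 `t`).
#' @return Coordinate matrix (atoms x 3, Angstrom).
#' @export
ligand_coords <- function(ligand, conformer = ligand$active_conformer,
                          frame = ligand$frame) {
  xyz <- ligand$conformers[[conformer]]
  sweep(xyz %*% t(frame$R), 2, frame$t, FUN = "+")
}

# compose an additional rotation (about `center`) and translation onto the
# frame: x -> R2 (x - center) + center + t2 applied after the current frame
compose_frame <- function(frame, R2, t2, center) {
  list(R = R2 %*% frame$R,
       t = as.numeric(R2 %*% (frame$t - center)) + center + t2)
}

#' Read a multi-record SDF file as a ligand conformer set
#'
#' Each SDF record becomes one conformer; all records must share the same
#' atom topology (count and element order). Bonds are taken from the first
#' record.
#'
#' @param path SDF file path.
#' @param resname HETATM residue code to use when the ligand is written to
#'   PDB.
#' @return A ligand with frame = identity and active conformer 1.
#' @export
read_ligand_conformers <- function(path, resname = "LIG") {
  sdf <- ChemmineR::read.SDFset(path)
  n_rec <- length(sdf)
  if (n_rec == 0L) stop("no records in SDF file: ", path)
  parse_rec <- function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    xyz <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    elements <- gsub("_[0-9]+$", "", rownames(ab))
    list(xyz = xyz, elements = elements)
  }
  first <- parse_rec(1)
  n_atoms <- nrow(first$xyz)
  confs <- vector("list", n_rec)
  confs[[1]] <- first$xyz
  if (n_rec > 1) {
    for (i in 2:n_rec) {
      rec <- parse_rec(i)
      if (nrow(rec$xyz) != n_atoms || !identical(rec$elements, first$elements))
        stop("SDF record ", i, " has a different atom topology than record 1")
      confs[[i]] <- rec$xyz
    }
  }
  bb <- ChemmineR::bondblock(sdf[[1]])
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    unname(as.matrix(bb[, 1:2, drop = FALSE]))
  }
  atoms <- tibble::tibble(
    name = paste0(first$elements, seq_len(n_atoms)),
    element = first$elements
  )
  new_ligand(atoms, bonds, confs, resname = resname)
}

#' Write ligand conformers as a multi-record SDF (V2000) file
#'
#' @param ligand A ligand.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_ligand_sdf <- function(ligand, path) {
  n <- nrow(ligand$atoms)
  nb <- nrow(ligand$bonds)
  lines <- character(0)
  for (ci in seq_along(ligand$conformers)) {
    xyz <- ligand$conformers[[ci]]
    rec <- c(
      paste0(ligand$resname, "_conf", ci), "  coupledmoves", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], ligand$atoms$element),
      if (nb > 0) sprintf("%3d%3d  1  0  0  0  0",
                          ligand$bonds[, 1], ligand$bonds[, 2]),
      "M  END", "$$$$"
    )
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

# bond-count distances between ligand atoms (intra-ligand exclusions)
ligand_graph_dist <- function(ligand) {
  n <- nrow(ligand$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(ligand$bonds) == 0) return(d)
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds[k, 1]; j <- ligand$bonds[k, 2]
    adj[i, j] <- adj[j, i] <- TRUE
  }
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    while (length(frontier) > 0 && depth < 6) {
      depth <- depth + 1
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !is.finite(d[s, ]))
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Expose ligand conformers through the discrete-state selection interface
#'
#' Conformers are presented like a rotamer set: each conformer has a uniform
#' prior probability and the current (active) conformer is always a member,
#' so a null move exists.
#'
#' @param ligand A ligand.
#' @return Tibble with columns `conformer` and `prob`.
#' @export
ligand_conformer_set <- function(ligand) {
  k <- length(ligand$conformers)
  tibble::tibble(conformer = seq_len(k), prob = rep(1 / k, k))
}
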