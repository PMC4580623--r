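# Pose and residue data model. A pose is the complete mutable state of one
# simulation: an ordered list of residues (one protein chain set) plus an
# optional ligand. Residues hold backbone and side-chain coordinates, the
# amino-acid identity and the side-chain chi angles; side chains are always
# stored in canonical template atom order (heavy atoms plus polar hydrogens)
# so rotamer substitution is an atomic matrix swap.

.template_cache <- new.env(parent = emptyenv())

# Z-matrix template for one amino acid, with 0-based reference indices into
# the combined array [N, CA, C, side-chain atoms...]
sidechain_template <- function(aa) {
  tpl <- .template_cache[[aa]]
  if (!is.null(tpl)) return(tpl)
  topo <- sc_topology(aa)
  if (is.null(topo)) {
    tpl <- list(m = 0L, atoms = character(0), elements = character(0))
  } else {
    anchor_names <- c("N", "CA", "C")
    idx_of <- function(name, upto) {
      i <- match(name, anchor_names)
      if (!is.na(i)) return(i - 1L)
      j <- match(name, topo$atom[seq_len(upto)])
      if (is.na(j)) stop("template reference to unplaced atom: ", name)
      2L + j
    }
    n <- nrow(topo)
    parent <- gp <- ggp <- integer(n)
    for (t in seq_len(n)) {
      parent[t] <- idx_of(topo$parent[t], t - 1L)
      gp[t] <- idx_of(topo$gp[t], t - 1L)
      ggp[t] <- idx_of(topo$ggp[t], t - 1L)
    }
    tpl <- list(
      m = n, atoms = topo$atom, elements = topo$element,
      parent = parent, gp = gp, ggp = ggp,
      bond = topo$bond, angle = topo$angle, dih = topo$dih,
      chi_idx = as.integer(topo$chi),
      rad = lj_radius(topo$element), eps = lj_eps(topo$element),
      n_chi = CHI_COUNTS[[aa]],
      n_proton_chi = if (aa %in% names(PROTON_CHI)) PROTON_CHI[[aa]] else 0L
    )
    # hydrogen-bond roles within the side chain (0-based donor-base index)
    hb <- rep(-1L, n)
    don <- .HB_DONOR_H[[aa]]
    if (!is.null(don)) {
      for (h in names(don)) hb[match(h, tpl$atoms)] <- match(don[[h]], tpl$atoms) - 1L
    }
    acc <- rep(0L, n)
    acc[match(.HB_ACCEPTORS[[aa]], tpl$atoms)] <- 1L
    tpl$hb <- hb
    tpl$acc <- acc
  }
  assign(aa, tpl, envir = .template_cache)
  tpl
}

# build k side-chain conformations; chis matrix k x (n_chi + n_proton_chi)
build_sidechain_matrix <- function(aa, bbN, bbCA, bbC, chis, proton_chi = 180) {
  tpl <- sidechain_template(aa)
  if (tpl$m == 0L) return(NULL)
  if (is.null(chis)) chis <- numeric(0)
  chimat <- matrix(c(chis, rep(proton_chi, tpl$n_proton_chi)), nrow = 1)
  anchors <- rbind(bbN, bbCA, bbC)
  xyz <- cpp_build_chains(anchors, tpl$parent, tpl$gp, tpl$ggp, tpl$bond,
                          tpl$angle, tpl$dih, tpl$chi_idx, chimat)
  rownames(xyz) <- tpl$atoms
  xyz
}

# measure canonical chi angles from stored coordinates
extract_chis <- function(aa, backbone, sidechain) {
  tuples <- chi_atom_tuples(aa)
  if (length(tuples) == 0L) return(numeric(0))
  getp <- function(name) {
    if (name %in% rownames(backbone)) backbone[name, ] else sidechain[name, ]
  }
  vapply(tuples, function(tp) {
    dihedral_angle(getp(tp[1]), getp(tp[2]), getp(tp[3]), getp(tp[4]))
  }, numeric(1))
}

new_residue <- function(chain, seqpos, aa, backbone, sidechain = NULL,
                        chis = NULL, proton_chi = 180, rot_prob = 1) {
  stopifnot(all(c("N", "CA", "C", "O") %in% rownames(backbone)))
  if (is.null(sidechain) && CHI_COUNTS[[aa]] >= 0L) {
    sidechain <- build_sidechain_matrix(aa, backbone["N", ], backbone["CA", ],
                                        backbone["C", ], chis, proton_chi)
  }
  if (is.null(chis)) {
    chis <- extract_chis(aa, backbone, sidechain)
  }
  structure(list(chain = chain, seqpos = as.integer(seqpos), aa = aa,
                 backbone = backbone, sidechain = sidechain,
                 chis = as.numeric(chis), proton_chi = proton_chi,
                 rot_prob = rot_prob),
            class = "cm_residue")
}

#' Construct a pose
#'
#' A pose is the single mutable state of a design simulation: an ordered
#' residue list plus an optional ligand.
#'
#' @param residues List of residue objects (internal constructor).
#' @param ligand Optional ligand object from [read_ligand_conformers()] or a
#'   fixture generator.
#' @param id Free-text provenance string.
#' @param atoms Optional tibble of raw parsed atom records (kept so
#'   alternate-location information survives parsing).
#' @return An object of class `cm_pose`.
#' @export
new_pose <- function(residues, ligand = NULL, id = "", atoms = NULL) {
  keys <- vapply(residues, function(r) paste0(r$chain, ":", r$seqpos), character(1))
  if (anyDuplicated(keys)) stop("duplicate (chain, seqpos) in pose")
  structure(list(residues = residues, ligand = ligand, id = id,
                 atoms = atoms, keys = keys),
            class = "cm_pose")
}

#' @export
print.cm_pose <- function(x, ...) {
  cat("<pose>", x$id, "\n")
  cat("  residues:", length(x$residues), " sequence:", pose_sequence(x), "\n")
  if (!is.null(x$ligand)) {
    cat("  ligand:", x$ligand$resname, "with", length(x$ligand$conformers),
        "conformer(s),", nrow(x$ligand$atoms), "atoms\n")
  }
  invisible(x)
}

residue_index <- function(pose, chain, seqpos) {
  i <- match(paste0(chain, ":", seqpos), pose$keys)
  if (is.na(i)) stop("no residue ", chain, ":", seqpos, " in pose")
  i
}

#' Amino-acid sequence of a pose
#'
#' @param pose A pose.
#' @param positions Optional two-column data frame / tibble with `chain` and
#'   `seqpos`; default all residues in order.
#' @return Single character string of one-letter codes.
#' @export
pose_sequence <- function(pose, positions = NULL) {
  if (is.null(positions)) {
    return(paste0(vapply(pose$residues, `[[`, character(1), "aa"), collapse = ""))
  }
  idx <- mapply(function(ch, sp) residue_index(pose, ch, sp),
                positions$chain, positions$seqpos)
  paste0(vapply(pose$residues[idx], `[[`, character(1), "aa"), collapse = "")
}

# replace the side chain (and possibly amino acid) at residue index i
set_sidechain <- function(pose, i, aa, sidechain, chis, proton_chi = 180,
                          rot_prob = 1) {
  r <- pose$residues[[i]]
  r$aa <- aa
  r$sidechain <- sidechain
  r$chis <- as.numeric(chis)
  r$proton_chi <- proton_chi
  r$rot_prob <- rot_prob
  pose$residues[[i]] <- r
  pose
}

# backbone amide hydrogen, placed from ideal sp2 geometry (bisector of the
# two N bonds); NULL for chain starts and proline
amide_h <- function(pose, i) {
  r <- pose$residues[[i]]
  if (r$aa == "P" || i == 1L) return(NULL)
  prev <- pose$residues[[i - 1L]]
  if (prev$chain != r$chain || prev$seqpos != r$seqpos - 1L) return(NULL)
  N <- r$backbone["N", ]
  u1 <- unit_vector(r$backbone["CA", ] - N)
  u2 <- unit_vector(prev$backbone["C", ] - N)
  N + .BB_GEOM$n_h * unit_vector(-(u1 + u2))
}

# -- bond graphs and exclusion bookkeeping ----------------------------------

.graph_cache <- new.env(parent = emptyenv())

# all-atom bond-count distance matrix for one residue type
# atom order: N, CA, C, O, [H], side-chain template atoms
residue_graph_dist <- function(aa, has_h) {
  key <- paste0(aa, if (has_h) "+H" else "")
  d <- .graph_cache[[key]]
  if (!is.null(d)) return(d)
  tpl <- sidechain_template(aa)
  atoms <- c("N", "CA", "C", "O", if (has_h) "H", tpl$atoms)
  n <- length(atoms)
  edges <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (has_h) edges <- rbind(edges, c("N", "H"))
  if (tpl$m > 0L) {
    topo <- sc_topology(aa)
    edges <- rbind(edges, cbind(topo$parent, topo$atom))
    rc <- .RING_CLOSURES[[aa]]
    if (!is.null(rc)) edges <- rbind(edges, rc)
  }
  adj <- matrix(FALSE, n, n, dimnames = list(atoms, atoms))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[a, b] <- adj[b, a] <- TRUE
  }
  # BFS all-pairs on a tiny graph
  d <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    while (length(frontier) > 0 && depth < 6) {
      depth <- depth + 1
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !is.finite(d[s, ]))
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  assign(key, d, envir = .graph_cache)
  d
}

#' Validate pose invariants
#'
#' Checks backbone completeness, unique numbering, finite coordinates, and
#' that side-chain dihedrals rebuilt from the stored chis reproduce the
#' stored chi values.
#'
#' @param pose A pose.
#' @param tol Chi agreement tolerance in degrees.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_pose <- function(pose, tol = 1e-6) {
  for (r in pose$residues) {
    if (!all(c("N", "CA", "C", "O") %in% rownames(r$backbone)))
      stop("residue ", r$chain, ":", r$seqpos, " missing backbone atoms")
    if (!all(is.finite(r$backbone))) stop("non-finite backbone coordinates")
    if (length(r$chis) != CHI_COUNTS[[r$aa]])
      stop("chi count mismatch at ", r$chain, ":", r$seqpos)
    if (!is.null(r$sidechain)) {
      got <- extract_chis(r$aa, r$backbone, r$sidechain)
      dd <- abs(((got - r$chis + 180) %% 360) - 180)
      if (length(dd) && max(dd) > tol)
        stop("stored chis disagree with coordinates at ", r$chain, ":", r$seqpos)
    }
  }
  invisible(TRUE)
}
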