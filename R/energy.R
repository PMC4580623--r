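# Pluggable energy contract and the simplified reference implementation.
#
# The decomposition contract is what the sampler needs: per-position one-body
# terms, unordered-pair two-body terms, and a protein-ligand component that
# scales linearly with `w_lig`. The reference score is NOT a physical
# all-atom force field; it is the documented stand-in defined by this
# package: split soft Lennard-Jones (the repulsive component alone is the
# "clash" energy used for repack-neighbor selection), a directional
# hydrogen-bond term, a rotamer self-energy -ln(prob), and per-amino-acid
# reference constants. Energies are in arbitrary "energy units"; kT = 0.6 in
# the sampler is expressed in the same units.

#' Energy-function configuration
#'
#' @param w_lig Protein-ligand up-weighting factor (> 0). The benchmark
#'   settings in the sources of this method are 1, 2 and 3.
#' @param w_attr,w_rep,w_hb,w_rot Term weights of the reference score
#'   (attractive/repulsive Lennard-Jones split, hydrogen bond, rotamer
#'   self-energy).
#' @param ref Named numeric vector of per-amino-acid reference energies
#'   (defaults to 0 for all twenty).
#' @param cutoff Pair interaction cutoff in Angstrom.
#' @param rep_frac The repulsive branch is linearized below
#'   `rep_frac * sigma` so overlapping atoms stay finite.
#' @param hb_depth Hydrogen-bond well depth (energy units; an ideal linear
#'   bond at optimum distance scores exactly `-hb_depth`).
#' @param hb_dmin,hb_d0,hb_dmax Donor-acceptor distance window and optimum
#'   (Angstrom).
#' @return Object of class `cm_energy_config`.
#' @export
energy_config <- function(w_lig = 1, w_attr = 1, w_rep = 1, w_hb = 1,
                          w_rot = 1, ref = NULL, cutoff = 10,
                          rep_frac = 0.6, hb_depth = 2,
                          hb_dmin = 1.5, hb_d0 = 2.8, hb_dmax = 3.3) {
  if (w_lig <= 0) stop("w_lig must be > 0")
  if (is.null(ref)) ref <- stats::setNames(rep(0, 20), AA1)
  structure(list(w_lig = w_lig, w_attr = w_attr, w_rep = w_rep, w_hb = w_hb,
                 w_rot = w_rot, ref = ref, cutoff = cutoff,
                 rep_frac = rep_frac, hb_depth = hb_depth, hb_dmin = hb_dmin,
                 hb_d0 = hb_d0, hb_dmax = hb_dmax),
            class = "cm_energy_config")
}

kernel_params <- function(config) {
  c(cutoff = config$cutoff, rep_frac = config$rep_frac,
    hb_depth = config$hb_depth, hb_dmin = config$hb_dmin,
    hb_d0 = config$hb_d0, hb_dmax = config$hb_dmax)
}

weighted_components <- function(comp, config) {
  config$w_attr * comp[["attr"]] + config$w_rep * comp[["rep"]] +
    config$w_hb * comp[["hb"]]
}

.empty_excl <- matrix(0L, 0, 2)

# fixed backbone atom properties (amide H donates from N; carbonyl O accepts)
.BB_PROPS4 <- list(names = c("N", "CA", "C", "O"),
                   rad = c(1.55, 1.75, 1.75, 1.50),
                   eps = c(0.170, 0.080, 0.080, 0.160),
                   hb = c(-1L, -1L, -1L, -1L), acc = c(0L, 0L, 0L, 1L))
.BB_PROPS5 <- list(names = c("N", "CA", "C", "O", "H"),
                   rad = c(1.55, 1.75, 1.75, 1.50, 0.90),
                   eps = c(0.170, 0.080, 0.080, 0.160, 0.020),
                   hb = c(-1L, -1L, -1L, -1L, 0L), acc = c(0L, 0L, 0L, 1L, 0L))

# scoring atom sets of residue i: backbone (N, CA, C, O, optional amide H)
# and side chain (template order, polar hydrogens included)
residue_sets <- function(pose, i) {
  r <- pose$residues[[i]]
  tpl <- sidechain_template(r$aa)
  h <- amide_h(pose, i)
  props <- if (is.null(h)) .BB_PROPS4 else .BB_PROPS5
  bb_xyz <- rbind(r$backbone[c("N", "CA", "C", "O"), ], if (!is.null(h)) h)
  bb <- list(xyz = bb_xyz, rad = props$rad, eps = props$eps,
             hb = props$hb, acc = props$acc, names = props$names)
  sc <- NULL
  if (!is.null(r$sidechain) && nrow(r$sidechain) > 0) {
    sc <- list(xyz = unname(r$sidechain), rad = tpl$rad, eps = tpl$eps,
               hb = tpl$hb, acc = tpl$acc, names = tpl$atoms)
  }
  gd <- residue_graph_dist(r$aa, !is.null(h))
  list(bb = bb, sc = sc, gd = gd, aa = r$aa)
}

set_concat <- function(sets) {
  list(xyz = do.call(rbind, lapply(sets, `[[`, "xyz")),
       rad = unlist(lapply(sets, `[[`, "rad")),
       eps = unlist(lapply(sets, `[[`, "eps")),
       hb = {
         # donor-base indices must be offset into the concatenated array
         offs <- cumsum(c(0L, vapply(sets, function(s) nrow(s$xyz), integer(1))))
         unlist(lapply(seq_along(sets), function(k) {
           h <- sets[[k]]$hb
           ifelse(h >= 0L, h + offs[k], -1L)
         }))
       },
       acc = unlist(lapply(sets, `[[`, "acc")),
       names = unlist(lapply(sets, `[[`, "names")))
}

residue_all_set <- function(rs) {
  if (is.null(rs$sc)) set_concat(list(rs$bb)) else set_concat(list(rs$bb, rs$sc))
}

# exclusion pairs (0-based) between the full atom sets of residues i and j;
# only bonded neighbours (|i - j| == 1, same chain, consecutive numbering)
# have any
adjacent_exclusions <- function(rs_i, rs_j, names_i, names_j, direction) {
  # direction +1: j follows i (path a -> C(i) -> N(j) -> b)
  if (direction == 1L) {
    di <- rs_i$gd[names_i, "C"]
    dj <- rs_j$gd["N", names_j]
  } else {
    di <- rs_i$gd[names_i, "N"]
    dj <- rs_j$gd["C", names_j]
  }
  sep <- outer(di, dj, `+`) + 1
  idx <- which(sep <= 3, arr.ind = TRUE)
  if (nrow(idx) == 0) return(.empty_excl)
  cbind(idx[, 1] - 1L, idx[, 2] - 1L)
}

intra_exclusions <- function(gd, names_a, names_b) {
  sep <- gd[names_a, names_b, drop = FALSE]
  idx <- which(sep <= 3, arr.ind = TRUE)
  if (nrow(idx) == 0) return(.empty_excl)
  cbind(idx[, 1] - 1L, idx[, 2] - 1L)
}

ligand_set <- function(pose) {
  lig <- pose$ligand
  if (is.null(lig)) return(NULL)
  el <- lig$atoms$element
  list(xyz = ligand_coords(lig), rad = lj_radius(el), eps = lj_eps(el),
       hb = rep(-1L, length(el)),
       acc = as.integer(toupper(el) %in% c("O", "N")),
       names = lig$atoms$name)
}

score_pair_sets <- function(s1, s2, excl, par) {
  cpp_score_sets(s1$xyz, s1$rad, s1$eps, s1$hb, s1$acc,
                 s2$xyz, s2$rad, s2$eps, s2$hb, s2$acc,
                 numeric(0), excl, par)
}

# intra-residue energy: side chain vs own backbone (bonded-path exclusions)
# plus side-chain internal Lennard-Jones
residue_intra <- function(rs, par) {
  if (is.null(rs$sc)) return(c(attr = 0, rep = 0, hb = 0))
  excl_cross <- intra_exclusions(rs$gd, rs$sc$names, rs$bb$names)
  cross <- score_pair_sets(rs$sc, rs$bb, excl_cross, par)
  excl_self <- intra_exclusions(rs$gd, rs$sc$names, rs$sc$names)
  self <- cpp_score_self(rs$sc$xyz, rs$sc$rad, rs$sc$eps, rs$sc$hb,
                         excl_self, par)
  cross + self
}

# are residues i, j bonded neighbours?
.bonded <- function(pose, i, j) {
  ri <- pose$residues[[i]]; rj <- pose$residues[[j]]
  ri$chain == rj$chain && abs(ri$seqpos - rj$seqpos) == 1L && abs(i - j) == 1L
}

pair_components <- function(pose, rs, sets_all, i, j, par) {
  excl <- .empty_excl
  if (.bonded(pose, i, j)) {
    dir <- if (pose$residues[[j]]$seqpos > pose$residues[[i]]$seqpos) 1L else -1L
    names_i <- sets_all[[i]]$names
    names_j <- sets_all[[j]]$names
    excl <- adjacent_exclusions(rs[[i]], rs[[j]], names_i, names_j, dir)
  }
  score_pair_sets(sets_all[[i]], sets_all[[j]], excl, par)
}

#' Score a pose with the reference energy function
#'
#' Returns the full one-body / two-body / protein-ligand decomposition. The
#' invariant `total = sum(one_body) + sum(two_body) + w_lig * protein_ligand`
#' holds to floating-point accuracy; the ligand's internal (conformer
#' strain) energy is the one-body term of the ligand position.
#'
#' @param pose A pose.
#' @param config An [energy_config()].
#' @return Object of class `cm_energy_breakdown` with elements `total`,
#'   `one_body` (named by position key), `two_body` (named `"key1|key2"`),
#'   `protein_ligand`.
#' @export
score_pose <- function(pose, config = energy_config()) {
  par <- kernel_params(config)
  n <- length(pose$residues)
  rs <- lapply(seq_len(n), function(i) residue_sets(pose, i))
  sets_all <- lapply(rs, residue_all_set)
  one_body <- stats::setNames(numeric(n), pose$keys)
  for (i in seq_len(n)) {
    r <- pose$residues[[i]]
    comp <- residue_intra(rs[[i]], par)
    one_body[i] <- weighted_components(comp, config) +
      config$w_rot * (-log(r$rot_prob)) + config$ref[[r$aa]]
  }
  two_body <- numeric(0)
  if (n > 1) {
    keys <- character(0)
    vals <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        comp <- pair_components(pose, rs, sets_all, i, j, par)
        keys <- c(keys, paste(pose$keys[i], pose$keys[j], sep = "|"))
        vals <- c(vals, weighted_components(comp, config))
      }
    }
    two_body <- stats::setNames(vals, keys)
  }
  protein_ligand <- 0
  lig <- ligand_set(pose)
  if (!is.null(lig)) {
    pl <- vapply(seq_len(n), function(i) {
      weighted_components(score_pair_sets(sets_all[[i]], lig, .empty_excl, par),
                          config)
    }, numeric(1))
    protein_ligand <- sum(pl)
    gd <- ligand_graph_dist(pose$ligand)
    excl <- intra_exclusions(gd, seq_len(nrow(gd)), seq_len(nrow(gd)))
    internal <- cpp_score_self(lig$xyz, lig$rad, lig$eps, lig$hb, excl, par)
    one_body <- c(one_body, LIG = weighted_components(internal, config))
  }
  total <- sum(one_body) + sum(two_body) + config$w_lig * protein_ligand
  structure(list(total = total, one_body = one_body, two_body = two_body,
                 protein_ligand = protein_ligand, config = config),
            class = "cm_energy_breakdown")
}

#' @export
print.cm_energy_breakdown <- function(x, ...) {
  cat("<energy breakdown> total:", format(x$total, digits = 6), "\n")
  cat("  one-body positions:", length(x$one_body),
      " two-body pairs:", length(x$two_body),
      " protein-ligand:", format(x$protein_ligand, digits = 6), "\n")
  invisible(x)
}

# energy of all terms touching a set of residue indices (and/or the ligand)
local_energy <- function(pose, idx, config, include_ligand = FALSE) {
  par <- kernel_params(config)
  n <- length(pose$residues)
  rs <- lapply(seq_len(n), function(i) residue_sets(pose, i))
  sets_all <- lapply(rs, residue_all_set)
  lig <- ligand_set(pose)
  total <- 0
  in_set <- logical(n)
  in_set[idx] <- TRUE
  for (i in seq_len(n)) {
    if (!in_set[i]) next
    r <- pose$residues[[i]]
    comp <- residue_intra(rs[[i]], par)
    total <- total + weighted_components(comp, config) +
      config$w_rot * (-log(r$rot_prob)) + config$ref[[r$aa]]
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!in_set[i] && !in_set[j]) next
        total <- total +
          weighted_components(pair_components(pose, rs, sets_all, i, j, par),
                              config)
      }
    }
  }
  if (!is.null(lig)) {
    which_res <- if (include_ligand) seq_len(n) else which(in_set)
    for (i in which_res) {
      total <- total + config$w_lig *
        weighted_components(score_pair_sets(sets_all[[i]], lig, .empty_excl, par),
                            config)
    }
    if (include_ligand) {
      gd <- ligand_graph_dist(pose$ligand)
      excl <- intra_exclusions(gd, seq_len(nrow(gd)), seq_len(nrow(gd)))
      internal <- cpp_score_self(lig$xyz, lig$rad, lig$eps, lig$hb, excl, par)
      total <- total + weighted_components(internal, config)
    }
  }
  total
}

# apply a trial move description to a copy of the pose
apply_change <- function(pose, change) {
  switch(change$type,
    rotamer = build_sidechain(pose, change$position, change$rotamer),
    backrub = apply_backrub(pose, change$move),
    ligand = {
      lig <- pose$ligand
      if (is.null(lig)) stop("pose has no ligand")
      if (!is.null(change$frame)) lig$frame <- change$frame
      if (!is.null(change$conformer)) lig$active_conformer <- change$conformer
      pose$ligand <- lig
      pose
    },
    stop("unknown change type: ", change$type))
}

# residue indices whose terms a change affects
.affected_idx <- function(pose, change) {
  switch(change$type,
    rotamer = residue_index(pose, change$position[["chain"]],
                            as.integer(change$position[["seqpos"]])),
    backrub = {
      i <- residue_index(pose, change$move$pivot[["chain"]],
                         as.integer(change$move$pivot[["seqpos"]]))
      (i - 1L):(i + 1L)
    },
    ligand = integer(0))
}

#' Incremental energy change of a trial move
#'
#' Computes `score(after) - score(before)` by re-evaluating only the terms
#' the move touches (one-body and two-body terms of affected residues, and
#' their ligand interactions). Agrees with a full rescore to floating-point
#' accuracy.
#'
#' @param pose A pose.
#' @param change Move description: `list(type = "rotamer", position, rotamer)`,
#'   `list(type = "backrub", move)` or
#'   `list(type = "ligand", frame, conformer)`.
#' @param config An [energy_config()].
#' @return Energy difference (after minus before), plus the proposed pose in
#'   attribute `"pose"`.
#' @export
delta_energy <- function(pose, change, config = energy_config()) {
  after <- apply_change(pose, change)
  idx <- .affected_idx(pose, change)
  include_lig <- change$type == "ligand"
  e_before <- local_energy(pose, idx, config, include_ligand = include_lig)
  e_after <- local_energy(after, idx, config, include_ligand = include_lig)
  out <- e_after - e_before
  attr(out, "pose") <- after
  out
}
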