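# Deterministic synthetic test systems: ideal-geometry helical
# peptide-ligand complexes whose energetics are constructed (and verified by
# brute-force enumeration at build time) to favour a known pocket mutation,
# discrete toy energy landscapes for sampler oracles, and synthetic
# "natural" alignments with known per-column profiles. Every generator is
# seed-deterministic and fails loudly if its own ground-truth check fails.

#' Build an ideal-geometry alpha-helical peptide
#'
#' Backbone from ideal bond geometry at constant (phi, psi, omega); side
#' chains are built from the rotamer library's top rotamer at the local
#' (phi, psi) bin.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi,omega Backbone dihedrals in degrees (defaults: alpha
#'   helix).
#' @param chain Chain identifier.
#' @param library Rotamer-library handle.
#' @param relax Deterministically repack after building: two sweeps of
#'   per-position greedy minimum-energy rotamer selection, so the fixture
#'   starts free of accidental side-chain clashes.
#' @return A pose.
#' @export
make_helix_pose <- function(sequence, phi = -57, psi = -47, omega = 180,
                            chain = "A",
                            library = default_rotamer_library(),
                            relax = TRUE) {
  aas <- strsplit(sequence, "")[[1]]
  stopifnot(all(aas %in% AA1))
  n <- length(aas)
  g <- .BB_GEOM
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * .deg2rad
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_n, g$ang_ca_c_n, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], g$n_ca,
                              g$ang_c_n_ca, omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], g$ca_c,
                             g$ang_n_ca_c, phi)
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    psi_i <- if (i < n) dihedral_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1]]) else psi
    O <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o, psi_i + 180)
    backbone <- rbind(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
    rot <- .library_bin(library, aas[i], bin10(phi), bin10(psi))
    chis <- rot$chis[[1]]
    sc <- build_sidechain_matrix(aas[i], backbone["N", ], backbone["CA", ],
                                 backbone["C", ], chis)
    residues[[i]] <- new_residue(chain, i, aas[i], backbone, sc, chis,
                                 rot_prob = rot$prob[1])
  }
  pose <- new_pose(residues, id = paste0("helix_", sequence))
  if (relax) pose <- greedy_repack(pose, library = library)
  pose
}

# deterministic per-position greedy minimum-energy repack (used to relax
# fixture starting structures; no randomness)
greedy_repack <- function(pose, config = energy_config(),
                          library = default_rotamer_library(), sweeps = 2L) {
  for (s in seq_len(sweeps)) {
    for (i in seq_along(pose$residues)) {
      r <- pose$residues[[i]]
      if (CHI_COUNTS[[r$aa]] == 0L) next
      pos <- list(chain = r$chain, seqpos = r$seqpos)
      rotset <- get_rotamers(pose, pos, allowed_aas = r$aa, library = library)
      E <- candidate_energies(pose, i, rotset, config)
      best <- which.min(E)
      if (!rotset$current[best]) {
        pose <- build_sidechain(pose, pos, rotset[best, ])
      }
    }
  }
  pose
}

#' Toy protein-ligand complex specification
#'
#' @param n_residues Helix length.
#' @param target_seqpos Position of the engineered pocket (default centre).
#' @param wt_aa Wild-type amino acid at the pocket.
#' @param target_aa The mutation the energetics are constructed to favour.
#' @param ligand_shape `"sphere-probe"` (single apolar atom),
#'   `"two-atom-dumbbell"` (bulky apolar probe) or `"hbond-probe"`
#'   (acceptor probe driving a hydroxyl hydrogen bond).
#' @param candidate_aas Amino acids allowed at the pocket (the ground-truth
#'   enumeration runs over these).
#' @param extra_design Optional tibble `chain`,`seqpos` plus list-column
#'   `allowed`: additional, energetically neutral design positions that
#'   generate sequence diversity.
#' @param offset Placement distance override in Angstrom (e.g. 30 for a
#'   no-signal far-away probe).
#' @param min_gap Required energy gap (energy units) of the target over the
#'   wild type (and, for the hbond probe, over every candidate).
#' @param hb_depth Hydrogen-bond well depth used by the fixture's energy
#'   configuration.
#' @param seed Integer seed.
#' @return List of class `cm_toy_spec`.
#' @export
toy_complex_spec <- function(n_residues = 9L, target_seqpos = 5L,
                             wt_aa = "L", target_aa = "A",
                             ligand_shape = c("two-atom-dumbbell",
                                              "sphere-probe", "hbond-probe"),
                             candidate_aas = c("L", "A", "S", "G", "V", "I",
                                               "C", "M"),
                             extra_design = NULL, offset = NULL,
                             min_gap = 3, hb_depth = 6, seed = 1L) {
  ligand_shape <- match.arg(ligand_shape)
  structure(list(n_residues = as.integer(n_residues),
                 target_seqpos = as.integer(target_seqpos), wt_aa = wt_aa,
                 target_aa = target_aa, ligand_shape = ligand_shape,
                 candidate_aas = candidate_aas, extra_design = extra_design,
                 offset = offset, min_gap = min_gap, hb_depth = hb_depth,
                 seed = as.integer(seed)),
            class = "cm_toy_spec")
}

# direction from CA outward through the side-chain tip of residue i
.tip_direction <- function(pose, i) {
  r <- pose$residues[[i]]
  ca <- r$backbone["CA", ]
  tpl <- sidechain_template(r$aa)
  heavy <- tpl$atoms[tpl$elements != "H"]
  sc <- r$sidechain[heavy, , drop = FALSE]
  d <- sqrt(rowSums(sweep(sc, 2, ca)^2))
  tip <- sc[which.max(d), ]
  list(ca = ca, tip = tip, dir = unit_vector(tip - ca), reach = max(d))
}

# brute-force best candidate energy per amino acid at one position
.enumerate_best <- function(pose, i, aas, config,
                            library = default_rotamer_library()) {
  pos <- list(chain = pose$residues[[i]]$chain,
              seqpos = pose$residues[[i]]$seqpos)
  rotset <- get_rotamers(pose, pos, allowed_aas = aas, library = library)
  E <- candidate_energies(pose, i, rotset, config)
  out <- vapply(aas, function(a) min(E[rotset$aa == a]), numeric(1))
  tibble::tibble(aa = aas, E_best = unname(out))
}

#' Build a toy helical peptide-ligand complex with known ground truth
#'
#' Constructs the helix, places the ligand so that the intended pocket
#' mutation either relieves a steric clash (dumbbell) or completes a
#' hydrogen bond (hbond probe), enumerates the best energy of every
#' candidate amino acid at the pocket by brute force, and fails loudly if
#' the intended energy gap is not achieved.
#'
#' @param spec A [toy_complex_spec()].
#' @param library Rotamer-library handle.
#' @return List with `pose`, `task` (a [design_task()]), `config` (the
#'   fixture's [energy_config()]), `notes` (ground-truth enumeration tibble)
#'   and `spec`.
#' @export
make_toy_complex <- function(spec, library = default_rotamer_library()) {
  set.seed(spec$seed)
  aas <- rep("A", spec$n_residues)
  aas[spec$target_seqpos] <- spec$wt_aa
  pose <- make_helix_pose(paste0(aas, collapse = ""), library = library)
  t_idx <- spec$target_seqpos
  config <- energy_config(hb_depth = spec$hb_depth)
  tipinfo <- .tip_direction(pose, t_idx)

  place_ligand <- function(d) {
    if (spec$ligand_shape == "sphere-probe") {
      p1 <- tipinfo$ca + d * tipinfo$dir
      lig <- new_ligand(tibble::tibble(name = "C1", element = "C"),
                        bonds = NULL, conformers = list(matrix(p1, 1, 3)))
    } else if (spec$ligand_shape == "two-atom-dumbbell") {
      p1 <- tipinfo$ca + d * tipinfo$dir
      p2 <- p1 + 1.5 * tipinfo$dir
      lig <- new_ligand(tibble::tibble(name = c("C1", "C2"),
                                       element = c("C", "C")),
                        bonds = cbind(1L, 2L),
                        conformers = list(rbind(p1, p2)))
    } else {
      # hbond probe: acceptor O placed on the donor axis of the target
      # hydroxyl rotamer, carbon continuing outward
      r <- pose$residues[[t_idx]]
      rot <- .library_bin(library, spec$target_aa, bin10(-57), bin10(-47))
      best <- NULL
      for (ri in seq_len(nrow(rot))) {
        for (pchi in c(-60, 60, 180)) {
          sc <- build_sidechain_matrix(spec$target_aa, r$backbone["N", ],
                                       r$backbone["CA", ], r$backbone["C", ],
                                       rot$chis[[ri]], pchi)
          hrow <- which(sidechain_template(spec$target_aa)$elements == "H")[1]
          if (is.na(hrow)) stop("hbond-probe target must have a hydroxyl")
          og <- sc[sidechain_template(spec$target_aa)$hb[hrow] + 1L, ]
          hg <- sc[hrow, ]
          acc <- og + d * unit_vector(hg - og)
          clearance <- min(sqrt(rowSums(sweep(
            do.call(rbind, lapply(pose$residues, function(rr)
              rr$backbone[c("N", "CA", "C", "O"), ])), 2, acc)^2)))
          if (is.null(best) || clearance > best$clearance) {
            best <- list(acc = acc, dir = unit_vector(acc - og),
                         clearance = clearance)
          }
        }
      }
      p1 <- best$acc
      p2 <- p1 + 1.4 * best$dir
      lig <- new_ligand(tibble::tibble(name = c("O1", "C2"),
                                       element = c("O", "C")),
                        bonds = cbind(1L, 2L),
                        conformers = list(rbind(p1, p2)))
    }
    pose$ligand <- lig
    pose
  }

  target_pos <- list(chain = "A", seqpos = spec$target_seqpos)
  check <- function(notes) {
    e_t <- notes$E_best[notes$aa == spec$target_aa]
    e_wt <- notes$E_best[notes$aa == spec$wt_aa]
    gap_wt <- e_wt - e_t
    ok <- gap_wt >= spec$min_gap
    if (spec$ligand_shape == "hbond-probe") {
      others <- notes$E_best[notes$aa != spec$target_aa]
      ok <- ok && all(others - e_t >= spec$min_gap)
    }
    ok
  }

  if (!is.null(spec$offset)) {
    pose <- place_ligand(spec$offset)
    notes <- .enumerate_best(pose, t_idx, spec$candidate_aas, config, library)
  } else if (spec$ligand_shape == "sphere-probe") {
    # apolar contact at the Lennard-Jones optimum of the side-chain tip
    pose <- place_ligand(tipinfo$reach + 2 * lj_radius("C"))
    notes <- .enumerate_best(pose, t_idx, spec$candidate_aas, config, library)
  } else if (spec$ligand_shape == "hbond-probe") {
    pose <- place_ligand(config$hb_d0)
    notes <- .enumerate_best(pose, t_idx, spec$candidate_aas, config, library)
    if (!check(notes)) {
      stop("toy complex build failed: intended hydrogen-bond gap not achieved")
    }
  } else {
    # scan the dumbbell inward until the wild type clashes but the target
    # amino acid stays comfortable
    notes <- NULL
    found <- FALSE
    for (d in seq(tipinfo$reach + 3.6, 2.0, by = -0.1)) {
      pose_try <- place_ligand(d)
      nt <- .enumerate_best(pose_try, t_idx, spec$candidate_aas, config, library)
      e_t <- nt$E_best[nt$aa == spec$target_aa]
      if (check(nt) && e_t < 1) {
        pose <- pose_try; notes <- nt; found <- TRUE
        break
      }
    }
    if (!found) stop("toy complex build failed: intended energy gap not achieved")
  }
  if (is.null(spec$offset) && spec$ligand_shape != "sphere-probe" &&
      !check(notes)) {
    stop("toy complex build failed: intended energy gap not achieved")
  }
  design <- tibble::tibble(chain = "A", seqpos = spec$target_seqpos,
                           allowed = list(spec$candidate_aas))
  if (!is.null(spec$extra_design)) {
    design <- dplyr::bind_rows(design, tibble::as_tibble(spec$extra_design))
  }
  task <- design_task(design = design, pose = pose)
  list(pose = pose, task = task, config = config, notes = notes, spec = spec)
}

#' Matched native / non-native toy complexes for the specificity benchmark
#'
#' The same helix bound to two different probes: the "native" sphere probe
#' packs favourably against the wild-type side chain, while the "non-native"
#' hydrogen-bond probe is placed so that only the target mutation can form a
#' hydrogen bond with it. Designing against both and comparing percent
#' enrichment reproduces the specificity-benchmark logic at desk scale.
#'
#' @param target_aa The specificity-switch mutation (hydroxyl donor).
#' @param seed Integer seed.
#' @return List with `native`, `nonnative` (toy complexes), shared `task`
#'   and the target mutation description.
#' @export
make_specificity_pair <- function(target_aa = "S", seed = 1L) {
  # neutral positions carry no hydroxyl so the engineered hydrogen bond
  # stays unique to the pocket target
  extra <- tibble::tibble(chain = "A", seqpos = c(2L, 8L),
                          allowed = list(c("A", "V", "G"), c("A", "V", "G")))
  native <- make_toy_complex(toy_complex_spec(
    ligand_shape = "sphere-probe", target_aa = target_aa,
    extra_design = extra, seed = seed))
  nonnative <- make_toy_complex(toy_complex_spec(
    ligand_shape = "hbond-probe", target_aa = target_aa,
    extra_design = extra, seed = seed))
  list(native = native, nonnative = nonnative, task = nonnative$task,
       target = list(chain = "A", seqpos = native$spec$target_seqpos,
                     from_aa = native$spec$wt_aa, to_aa = target_aa))
}

#' Crowded pocket fixture for selection-variant ablations
#'
#' A helix with bulky residues around a closely placed dumbbell probe; all
#' 20 amino acids are allowed at the pocket positions, most of which clash.
#'
#' @param seed Integer seed.
#' @return List with `pose`, `task`, `config`.
#' @export
make_crowded_complex <- function(seed = 1L) {
  fix <- make_toy_complex(toy_complex_spec(
    n_residues = 9L, target_seqpos = 5L, wt_aa = "L", target_aa = "A",
    ligand_shape = "two-atom-dumbbell",
    candidate_aas = c("L", "A", "G", "V", "S"), seed = seed))
  design <- tibble::tibble(chain = "A", seqpos = c(4L, 5L, 6L),
                           allowed = list(AA1, AA1, AA1))
  task <- design_task(design = design, pose = fix$pose)
  list(pose = fix$pose, task = task, config = fix$config)
}

#' Discrete toy energy landscape
#'
#' A minimal system whose "rotamers" are the listed states with exactly the
#' listed energies, driven through the same Boltzmann-selection and
#' acceptance machinery as the molecular sampler.
#'
#' @param energies Numeric vector (>= 2 finite energies).
#' @return Object of class `cm_landscape`.
#' @export
make_discrete_landscape <- function(energies) {
  if (length(energies) < 1 || !all(is.finite(energies)))
    stop("need finite state energies")
  structure(list(energies = as.numeric(energies)), class = "cm_landscape")
}

#' Run a Markov chain on a discrete landscape
#'
#' Proposal `"boltzmann"` draws the next state by Boltzmann selection over
#' all states (the coupled-moves selection rule); proposal `"uniform"` draws
#' uniformly. Acceptance `"hastings"` applies the Metropolis-Hastings
#' correction for the proposal distribution -- for Boltzmann proposals with
#' selection energies equal to the state energies this always accepts, and
#' the chain samples the Boltzmann distribution exactly. Acceptance
#' `"metropolis"` applies the plain Metropolis criterion to the energy
#' change, reproducing the design protocol's biased chain (which
#' over-occupies low-energy states; see the methods vignette).
#'
#' @param landscape A [make_discrete_landscape()].
#' @param kT Temperature factor.
#' @param n_moves Number of moves.
#' @param proposal `"boltzmann"` or `"uniform"`.
#' @param acceptance `"hastings"` or `"metropolis"`.
#' @param start Starting state index.
#' @param seed Optional seed.
#' @return List with `occupancy` (fraction of moves spent in each state),
#'   `acceptance_ratio` and the visited-state vector `trace`.
#' @export
run_landscape <- function(landscape, kT = 0.6, n_moves = 1e4L,
                          proposal = c("boltzmann", "uniform"),
                          acceptance = c("hastings", "metropolis"),
                          start = 1L, seed = NULL) {
  proposal <- match.arg(proposal)
  acceptance <- match.arg(acceptance)
  if (!is.null(seed)) set.seed(seed)
  E <- landscape$energies
  k <- length(E)
  q <- exp(-(E - min(E)) / kT)
  q <- q / sum(q)
  state <- start
  visits <- integer(k)
  n_acc <- 0L
  trace <- integer(n_moves)
  for (m in seq_len(n_moves)) {
    j <- if (proposal == "boltzmann") sample.int(k, 1L, prob = q)
    else sample.int(k, 1L)
    ratio <- exp(-(E[j] - E[state]) / kT)
    if (acceptance == "hastings" && proposal == "boltzmann") {
      ratio <- ratio * q[state] / q[j]
    }
    if (ratio >= 1 || stats::runif(1) < ratio) {
      state <- j
      n_acc <- n_acc + 1L
    }
    visits[state] <- visits[state] + 1L
    trace[m] <- state
  }
  list(occupancy = visits / n_moves, acceptance_ratio = n_acc / n_moves,
       trace = trace)
}

#' Sample a synthetic "natural" alignment from target column profiles
#'
#' Sequences are drawn i.i.d. per column; the empirical profile converges to
#' the target as the number of sequences grows.
#'
#' @param profiles List of named probability vectors over amino acids (one
#'   per column), e.g. rows of [build_profiles()] output.
#' @param n_seqs Number of sequences.
#' @param seed Integer seed.
#' @return Character vector of aligned sequences.
#' @export
make_natural_msa <- function(profiles, n_seqs, seed = 1L) {
  set.seed(seed)
  cols <- lapply(profiles, function(p) {
    p <- p / sum(p)
    aa <- names(p)
    if (is.null(aa)) aa <- AA1[seq_along(p)]
    sample(aa, n_seqs, replace = TRUE, prob = p)
  })
  apply(do.call(cbind, cols), 1, paste0, collapse = "")
}

#' Attach alternate-location C-alpha records from a second conformation
#'
#' Builds the raw atom table a crystallographic structure with alternate
#' locations would carry: every C-alpha gets an altloc A record from
#' `pose_a` and an altloc B record from `pose_b`. Used to test the
#' backrub-angle measurement on constructed inverse problems.
#'
#' @param pose_a,pose_b Poses with identical residue numbering.
#' @return `pose_a` with a populated `$atoms` table.
#' @export
with_altloc_conformations <- function(pose_a, pose_b) {
  rows <- list()
  for (i in seq_along(pose_a$residues)) {
    ra <- pose_a$residues[[i]]; rb <- pose_b$residues[[i]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = "ATOM", name = "CA", altloc = c("A", "B"),
      resid = AA3[[ra$aa]], chain = ra$chain, seqpos = ra$seqpos,
      x = c(ra$backbone["CA", 1], rb$backbone["CA", 1]),
      y = c(ra$backbone["CA", 2], rb$backbone["CA", 2]),
      z = c(ra$backbone["CA", 3], rb$backbone["CA", 3]),
      occupancy = 0.5, element = "C")
  }
  pose_a$atoms <- dplyr::bind_rows(rows)
  pose_a
}
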