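# The coupled-moves Monte Carlo protocol and the fixed-backbone simulated
# annealing baseline.
#
# One coupled protein move: pick a pivot uniformly from design + repack
# positions; perturb the backbone with a backrub move (flexible-backbone
# variant); regenerate the rotamer set at the pivot on the new backbone;
# select one rotamer per amino acid by Boltzmann-weighted selection, then an
# amino acid among the per-amino-acid winners (both stages uniform in the
# "Uni SC" variant); accept or reject the whole coupled proposal with the
# Metropolis criterion at constant kT. Ligand moves combine a rigid-body
# perturbation with Boltzmann conformer selection the same way. One kT
# (default 0.6 energy units) governs both selection and acceptance.

#' Sampler configuration
#'
#' Defaults are the protocol's study conditions: kT = 0.6 for both Boltzmann
#' selection and Metropolis acceptance; 1000 moves per simulation and 20
#' independent simulations; a 90/10 protein/ligand move mix; backrub width
#' 4.57 degrees; ligand rigid-body widths 1 degree (rotation) and 0.1
#' Angstrom (total translation displacement).
#'
#' @param kT Temperature factor (energy units).
#' @param n_moves Moves per simulation.
#' @param n_sims Independent simulations (used by [run_simulations()]).
#' @param p_ligand Probability that a move is a ligand move.
#' @param sigma_theta Backrub angle standard deviation (degrees).
#' @param sigma_rot Ligand rotation standard deviation (degrees).
#' @param sigma_trans Ligand translation standard deviation (Angstrom, of
#'   the total displacement vector; each axis uses sigma/sqrt(3)).
#' @param sc_selection `"boltzmann"` or `"uniform"` (the Uni SC ablation).
#' @param backbone `"flexible"` or `"fixed"` (the Fix BB ablation).
#' @param seed Integer seed; simulation s of an ensemble uses `seed + s`.
#' @return Object of class `cm_sampler_config`.
#' @export
sampler_config <- function(kT = 0.6, n_moves = 1000L, n_sims = 20L,
                           p_ligand = 0.1, sigma_theta = 4.57,
                           sigma_rot = 1, sigma_trans = 0.1,
                           sc_selection = c("boltzmann", "uniform"),
                           backbone = c("flexible", "fixed"), seed = 1L) {
  sc_selection <- match.arg(sc_selection)
  backbone <- match.arg(backbone)
  if (kT <= 0) stop("kT must be > 0")
  if (n_moves < 1) stop("n_moves must be >= 1")
  if (p_ligand < 0 || p_ligand > 1) stop("p_ligand must be in [0, 1]")
  structure(list(kT = kT, n_moves = as.integer(n_moves),
                 n_sims = as.integer(n_sims), p_ligand = p_ligand,
                 sigma_theta = sigma_theta, sigma_rot = sigma_rot,
                 sigma_trans = sigma_trans, sc_selection = sc_selection,
                 backbone = backbone, seed = as.integer(seed)),
            class = "cm_sampler_config")
}

#' Boltzmann-weighted selection among discrete states
#'
#' P(E_i) = exp(-E_i / kT) / sum_j exp(-E_j / kT), computed with a max-shift
#' for numerical stability; an index is drawn from P using R's global random
#' stream.
#'
#' @param energies Finite numeric vector (typically energies relative to the
#'   current state; a constant shift does not change P).
#' @param kT Temperature factor.
#' @return List with `index` (the draw) and `probs` (the probability
#'   vector, summing to 1).
#' @export
boltzmann_select <- function(energies, kT = 0.6) {
  if (length(energies) == 0) stop("empty energy list")
  if (!all(is.finite(energies))) stop("energies must be finite")
  w <- exp(-(energies - min(energies)) / kT)
  p <- w / sum(w)
  idx <- sample.int(length(p), 1L, prob = p)
  list(index = idx, probs = p)
}

#' Metropolis acceptance
#'
#' Accept when the energy change is non-positive, otherwise with probability
#' exp(-delta_E / kT).
#'
#' @param delta_E Finite energy change.
#' @param kT Temperature factor.
#' @return Logical flag.
#' @export
metropolis_accept <- function(delta_E, kT = 0.6) {
  if (!is.finite(delta_E)) stop("delta_E must be finite")
  delta_E <= 0 || stats::runif(1) < exp(-delta_E / kT)
}

# two-stage side-chain selection over a scored rotamer set; returns the
# chosen row index
.select_sidechain <- function(rotset, E_rel, is_design, kT, mode) {
  aas <- unique(rotset$aa)
  winners <- integer(length(aas))
  for (k in seq_along(aas)) {
    rows <- which(rotset$aa == aas[k])
    if (length(rows) == 1L) {
      winners[k] <- rows
    } else if (mode == "boltzmann") {
      winners[k] <- rows[boltzmann_select(E_rel[rows], kT)$index]
    } else {
      winners[k] <- rows[sample.int(length(rows), 1L)]
    }
  }
  if (!is_design || length(winners) == 1L) {
    # repack-only: identity amino acid
    cur_aa <- rotset$aa[rotset$current][1]
    return(winners[match(cur_aa, aas)])
  }
  if (mode == "boltzmann") {
    winners[boltzmann_select(E_rel[winners], kT)$index]
  } else {
    winners[sample.int(length(winners), 1L)]
  }
}

#' Propose one coupled backbone / side-chain move
#'
#' @param pose A pose.
#' @param task A [design_task()].
#' @param library Rotamer-library handle.
#' @param energy An [energy_config()].
#' @param config A [sampler_config()].
#' @param positions Precomputed position table (internal; built from the
#'   task when `NULL`).
#' @return List with the proposed `pose`, the total energy change `dE`, and
#'   bookkeeping fields (`pivot`, `theta`, `aa_from`, `aa_to`).
#' @export
coupled_protein_move <- function(pose, task, library = default_rotamer_library(),
                                 energy = energy_config(),
                                 config = sampler_config(),
                                 positions = NULL) {
  pos_all <- if (is.null(positions)) .move_positions(task) else positions
  if (nrow(pos_all) == 0) stop("task has no design or repack positions")
  k <- sample.int(nrow(pos_all), 1L)
  pick <- list(chain = pos_all$chain[k], seqpos = pos_all$seqpos[k],
               design = pos_all$design[k], allowed = pos_all$allowed[[k]])
  pivot <- list(chain = pick$chain, seqpos = pick$seqpos)
  i <- residue_index(pose, pivot$chain, pivot$seqpos)
  dE_bb <- 0
  theta <- NA_real_
  pose_bb <- pose
  if (config$backbone == "flexible" &&
      i > 1L && i < length(pose$residues)) {
    th <- sample_backrub_angle(backrub_params(config$sigma_theta))
    if (abs(th) < 90) {
      mv <- tryCatch(backrub_move(pose, pivot, th), error = function(e) NULL)
      if (!is.null(mv)) {
        theta <- th
        pose_bb <- apply_backrub(pose, mv)
        idx <- (i - 1L):(i + 1L)
        dE_bb <- local_energy(pose_bb, idx, energy) -
          local_energy(pose, idx, energy)
      }
    }
  }
  allowed <- if (pick$design) pick$allowed else pose$residues[[i]]$aa
  rotset <- get_rotamers(pose_bb, pivot, allowed_aas = allowed, library = library)
  E <- candidate_energies(pose_bb, i, rotset, energy)
  cur_row <- which(rotset$current)[1]
  E_rel <- E - E[cur_row]
  sel <- .select_sidechain(rotset, E_rel, pick$design, config$kT,
                           config$sc_selection)
  pose_prop <- if (sel == cur_row) pose_bb else
    build_sidechain(pose_bb, pivot, rotset[sel, ])
  dE_sc <- E_rel[sel]
  if ((rotset$aa[sel] == "P") != (pose$residues[[i]]$aa == "P")) {
    # proline gains/loses the backbone amide hydrogen; the fast candidate
    # shortcut cannot see that, so rescore the affected terms exactly
    dE_sc <- local_energy(pose_prop, i, energy) - local_energy(pose_bb, i, energy)
  }
  list(pose = pose_prop, dE = dE_bb + dE_sc, type = "protein",
       pivot = pivot, theta = theta,
       aa_from = pose$residues[[i]]$aa, aa_to = rotset$aa[sel])
}

# interaction + internal energy of each ligand conformer under a frame
.ligand_conformer_energies <- function(pose, frame, energy) {
  par <- kernel_params(energy)
  lig <- pose$ligand
  prot <- set_concat(lapply(seq_along(pose$residues), function(j) {
    residue_all_set(residue_sets(pose, j))
  }))
  el <- lig$atoms$element
  rad <- lj_radius(el); eps <- lj_eps(el)
  hb <- rep(-1L, length(el))
  acc <- as.integer(toupper(el) %in% c("O", "N"))
  gd <- ligand_graph_dist(lig)
  excl <- intra_exclusions(gd, seq_len(nrow(gd)), seq_len(nrow(gd)))
  vapply(seq_along(lig$conformers), function(ci) {
    xyz <- ligand_coords(lig, conformer = ci, frame = frame)
    cross <- cpp_score_sets(xyz, rad, eps, hb, acc, prot$xyz, prot$rad,
                            prot$eps, prot$hb, prot$acc, numeric(0),
                            .empty_excl, par)
    internal <- cpp_score_self(xyz, rad, eps, hb, excl, par)
    energy$w_lig * weighted_components(cross, energy) +
      weighted_components(internal, energy)
  }, numeric(1))
}

#' Propose one coupled ligand move
#'
#' Rigid-body rotation about a random axis through the ligand centroid
#' (angle ~ N(0, sigma_rot^2)) plus an isotropic translation whose total
#' displacement has standard deviation sigma_trans, followed by Boltzmann
#' (or uniform) selection of a conformer on the perturbed frame.
#'
#' @inheritParams coupled_protein_move
#' @return List with the proposed `pose`, `dE` and bookkeeping fields
#'   (`conformer`).
#' @export
coupled_ligand_move <- function(pose, energy = energy_config(),
                                config = sampler_config()) {
  lig <- pose$ligand
  if (is.null(lig)) stop("pose has no ligand")
  center <- colMeans(ligand_coords(lig))
  ax <- stats::rnorm(3)
  R2 <- if (vnorm(ax) < 1e-12 || config$sigma_rot == 0) diag(3) else
    rotation_matrix(ax, stats::rnorm(1, 0, config$sigma_rot))
  t2 <- if (config$sigma_trans == 0) c(0, 0, 0) else
    stats::rnorm(3, 0, config$sigma_trans / sqrt(3))
  frame_new <- compose_frame(lig$frame, R2, t2, center)
  E_new <- .ligand_conformer_energies(pose, frame_new, energy)
  E_old <- .ligand_conformer_energies(pose, lig$frame, energy)
  cur <- lig$active_conformer
  sel <- if (length(E_new) == 1L) 1L
  else if (config$sc_selection == "boltzmann")
    boltzmann_select(E_new - E_new[cur], config$kT)$index
  else sample.int(length(E_new), 1L)
  lig$frame <- frame_new
  lig$active_conformer <- sel
  pose$ligand <- lig
  list(pose = pose, dE = E_new[sel] - E_old[cur], type = "ligand",
       pivot = list(chain = lig$chain, seqpos = lig$seqpos),
       theta = NA_real_, aa_from = NA_character_, aa_to = NA_character_,
       conformer = sel)
}

.design_order <- function(task) {
  tibble::tibble(chain = task$design$chain, seqpos = task$design$seqpos)
}

# flat position table for move proposals: design + repack with allowed sets
.move_positions <- function(task) {
  nd <- nrow(task$design); nr <- nrow(task$repack)
  tibble::tibble(
    chain = c(task$design$chain, task$repack$chain),
    seqpos = c(task$design$seqpos, task$repack$seqpos),
    design = rep(c(TRUE, FALSE), times = c(nd, nr)),
    allowed = c(task$design$allowed, rep(list(NULL), nr)))
}

new_design_trace <- function(sequences, ledger, best_pose, best_energy,
                             start_seq, design_positions, config) {
  structure(list(sequences = sequences, ledger = ledger,
                 best_pose_per_sequence = best_pose,
                 best_energy = best_energy,
                 acceptance_ratio = if (nrow(ledger) > 0)
                   mean(ledger$accepted) else 0,
                 start_seq = start_seq, design_positions = design_positions,
                 config = config),
            class = "cm_design_trace")
}

#' @export
print.cm_design_trace <- function(x, ...) {
  cat("<design trace>", nrow(x$ledger), "moves,",
      length(x$sequences), "unique sequence(s), acceptance",
      sprintf("%.3f", x$acceptance_ratio), "\n")
  invisible(x)
}

#' Run one coupled-moves design simulation
#'
#' Runs `config$n_moves` Monte Carlo moves: each move is a coupled ligand
#' move with probability `p_ligand` (when a ligand is present) and a coupled
#' protein move otherwise. Accepted moves mutate the pose; every accepted
#' sequence change over the design positions is recorded, and the
#' lowest-energy pose per unique sequence is retained. With a fixed seed the
#' trace is bit-reproducible.
#'
#' @inheritParams coupled_protein_move
#' @param keep_poses Retain the lowest-energy pose per sequence (set FALSE
#'   to save memory in large ensembles).
#' @return A design trace: unique `sequences` in order of first acceptance,
#'   a per-move `ledger` tibble, `best_pose_per_sequence`,
#'   `acceptance_ratio`, and the final pose in `$final_pose`.
#' @export
run_coupled_moves <- function(pose, task, library = default_rotamer_library(),
                              energy = energy_config(),
                              config = sampler_config(), keep_poses = TRUE) {
  set.seed(config$seed)
  dp <- .design_order(task)
  pos_all <- .move_positions(task)
  n_pos <- nrow(pos_all)
  start_seq <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
  e0 <- score_pose(pose, energy)$total
  sequences <- start_seq
  # names must be non-empty strings for list indexing
  seq_key <- function(s) if (nzchar(s)) s else "<start>"
  best_energy <- stats::setNames(e0, seq_key(start_seq))
  best_pose <- list()
  if (keep_poses) best_pose[[seq_key(start_seq)]] <- pose
  mv_type <- character(config$n_moves)
  mv_pos <- character(config$n_moves)
  mv_dE <- numeric(config$n_moves)
  mv_acc <- logical(config$n_moves)
  mv_seq <- character(config$n_moves)
  e_cur <- e0
  for (m in seq_len(config$n_moves)) {
    do_ligand <- !is.null(pose$ligand) &&
      (n_pos == 0 || stats::runif(1) < config$p_ligand)
    if (!do_ligand && n_pos == 0) {
      mv_type[m] <- "none"; mv_pos[m] <- ""; mv_dE[m] <- 0
      mv_acc[m] <- FALSE; mv_seq[m] <- start_seq
      next
    }
    prop <- if (do_ligand) {
      coupled_ligand_move(pose, energy, config)
    } else {
      coupled_protein_move(pose, task, library, energy, config,
                           positions = pos_all)
    }
    acc <- metropolis_accept(prop$dE, config$kT)
    if (acc) {
      pose <- prop$pose
      e_cur <- e_cur + prop$dE
      sq <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
      if (!sq %in% sequences) sequences <- c(sequences, sq)
      sk <- seq_key(sq)
      if (!sk %in% names(best_energy) || e_cur < best_energy[[sk]]) {
        best_energy[sk] <- e_cur
        if (keep_poses) best_pose[[sk]] <- pose
      }
    }
    mv_type[m] <- prop$type
    mv_pos[m] <- paste0(prop$pivot$chain, ":", prop$pivot$seqpos)
    mv_dE[m] <- prop$dE
    mv_acc[m] <- acc
    mv_seq[m] <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
  }
  ledger <- tibble::tibble(move = seq_len(config$n_moves), type = mv_type,
                           position = mv_pos, dE = mv_dE, accepted = mv_acc,
                           sequence = mv_seq)
  out <- new_design_trace(sequences, ledger, best_pose, best_energy,
                          start_seq, dp, config)
  out$final_pose <- pose
  out$final_energy <- e_cur
  out
}

#' Geometric annealing schedule for the fixed-backbone packer
#'
#' @param kT_start,kT_end Temperatures of the first and last stage.
#' @param stages Number of cooling stages.
#' @return Numeric vector of stage temperatures.
#' @export
anneal_schedule <- function(kT_start = 100, kT_end = 0.3, stages = 8L) {
  kT_start * (kT_end / kT_start)^((seq_len(stages) - 1) / (stages - 1))
}

#' Fixed-backbone simulated-annealing design (baseline packer)
#'
#' The standard packer baseline: uniform random (position, rotamer)
#' proposals over design and repack positions, Metropolis acceptance under a
#' geometrically cooled temperature schedule, backbone and ligand frozen.
#' Returns the same trace form as [run_coupled_moves()] so both methods feed
#' the same metrics.
#'
#' @inheritParams run_coupled_moves
#' @param schedule Stage temperatures from [anneal_schedule()]; the
#'   `config$n_moves` proposals are divided evenly among stages.
#' @return A design trace.
#' @export
run_fixed_backbone_design <- function(pose, task,
                                      library = default_rotamer_library(),
                                      energy = energy_config(),
                                      config = sampler_config(),
                                      schedule = anneal_schedule()) {
  set.seed(config$seed)
  dp <- .design_order(task)
  pos_all <- .move_positions(task)
  if (nrow(pos_all) == 0) stop("task has no design or repack positions")
  start_seq <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
  e0 <- score_pose(pose, energy)$total
  sequences <- start_seq
  seq_key <- function(s) if (nzchar(s)) s else "<start>"
  best_energy <- stats::setNames(e0, seq_key(start_seq))
  best_pose <- list()
  best_pose[[seq_key(start_seq)]] <- pose
  kTs <- rep(schedule, each = ceiling(config$n_moves / length(schedule)))
  kTs <- kTs[seq_len(config$n_moves)]
  mv_dE <- numeric(config$n_moves)
  mv_acc <- logical(config$n_moves)
  mv_pos <- character(config$n_moves)
  mv_seq <- character(config$n_moves)
  e_cur <- e0
  for (m in seq_len(config$n_moves)) {
    k <- sample.int(nrow(pos_all), 1L)
    pivot <- list(chain = pos_all$chain[k], seqpos = pos_all$seqpos[k])
    i <- residue_index(pose, pivot$chain, pivot$seqpos)
    allowed <- if (pos_all$design[k]) pos_all$allowed[[k]] else
      pose$residues[[i]]$aa
    rotset <- get_rotamers(pose, pivot, allowed_aas = allowed, library = library)
    cur_row <- which(rotset$current)[1]
    sel <- sample.int(nrow(rotset), 1L)
    sub <- rotset[unique(c(sel, cur_row)), ]
    E <- candidate_energies(pose, i, sub, energy)
    dE <- if (sel == cur_row) 0 else E[1] - E[length(E)]
    pose_prop <- NULL
    if (sel != cur_row &&
        (rotset$aa[sel] == "P") != (pose$residues[[i]]$aa == "P")) {
      pose_prop <- build_sidechain(pose, pivot, rotset[sel, ])
      dE <- local_energy(pose_prop, i, energy) - local_energy(pose, i, energy)
    }
    acc <- metropolis_accept(dE, kTs[m])
    if (acc && sel != cur_row) {
      pose <- if (is.null(pose_prop)) build_sidechain(pose, pivot, rotset[sel, ])
      else pose_prop
      e_cur <- e_cur + dE
      sq <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
      if (!sq %in% sequences) sequences <- c(sequences, sq)
      sk <- seq_key(sq)
      if (!sk %in% names(best_energy) || e_cur < best_energy[[sk]]) {
        best_energy[sk] <- e_cur
        best_pose[[sk]] <- pose
      }
    }
    mv_dE[m] <- dE
    mv_acc[m] <- acc
    mv_pos[m] <- paste0(pivot$chain, ":", pivot$seqpos)
    mv_seq[m] <- if (nrow(dp) > 0) pose_sequence(pose, dp) else ""
  }
  ledger <- tibble::tibble(move = seq_len(config$n_moves), type = "packer",
                           position = mv_pos, dE = mv_dE, accepted = mv_acc,
                           sequence = mv_seq)
  out <- new_design_trace(sequences, ledger, best_pose, best_energy,
                          start_seq, dp, config)
  out$final_pose <- pose
  out$final_energy <- e_cur
  out
}

#' Run an ensemble of independent simulations
#'
#' Simulation s uses seed `config$seed + s`. Traces are pooled with
#' [pool_sequences()].
#'
#' @inheritParams run_coupled_moves
#' @param method `"coupled"` or `"fixed_backbone"`.
#' @return List with `traces` (length `config$n_sims`) and `pooled`
#'   (a sequence set).
#' @export
run_simulations <- function(pose, task, library = default_rotamer_library(),
                            energy = energy_config(),
                            config = sampler_config(),
                            method = c("coupled", "fixed_backbone")) {
  method <- match.arg(method)
  traces <- lapply(seq_len(config$n_sims), function(s) {
    cfg <- config
    cfg$seed <- config$seed + s
    if (method == "coupled") {
      run_coupled_moves(pose, task, library, energy, cfg, keep_poses = FALSE)
    } else {
      run_fixed_backbone_design(pose, task, library, energy, cfg)
    }
  })
  list(traces = traces, pooled = pool_sequences(traces))
}

#' Pool unique sequences across traces
#'
#' Union of the unique accepted sequences of several traces, order-stable by
#' first occurrence. All traces must share the same design positions.
#'
#' @param traces List of design traces.
#' @return A sequence set: character vector with attributes `positions`
#'   (design positions tibble) and `wt` (the shared start sequence).
#' @export
pool_sequences <- function(traces) {
  if (length(traces) == 0) stop("no traces to pool")
  dp0 <- traces[[1]]$design_positions
  for (tr in traces) {
    if (!identical(tr$design_positions$chain, dp0$chain) ||
        !identical(tr$design_positions$seqpos, dp0$seqpos))
      stop("traces have inconsistent design positions")
  }
  seqs <- unique(unlist(lapply(traces, `[[`, "sequences")))
  structure(seqs, positions = dp0, wt = traces[[1]]$start_seq,
            class = "cm_sequence_set")
}

#' Write a sequence set as FASTA
#'
#' @param seqs Character vector (or sequence set).
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_sequence_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(as.character(seqs))
  names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read aligned sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Character vector of equal-length sequences.
#' @export
read_sequence_fasta <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}
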