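# Batched construction and scoring of side-chain candidates at one position.
# This is the hot path of a coupled move: all rotamers of one amino acid are
# built in a single C++ call and scored against a fixed environment
# (own backbone, all other residues, ligand with its weight) in another.

# group the rows of a rotamer set by amino acid and build coordinates
rotamer_candidates <- function(pose, i, rotset) {
  r <- pose$residues[[i]]
  bbN <- r$backbone["N", ]; bbCA <- r$backbone["CA", ]; bbC <- r$backbone["C", ]
  anchors <- rbind(bbN, bbCA, bbC)
  groups <- list()
  for (aa in unique(rotset$aa)) {
    rows <- which(rotset$aa == aa)
    tpl <- sidechain_template(aa)
    lib_rows <- rows[!rotset$current[rows]]
    cur_rows <- rows[rotset$current[rows]]
    xyz <- NULL
    if (tpl$m > 0L) {
      if (length(lib_rows) > 0) {
        chimat <- do.call(rbind, lapply(lib_rows, function(rr) {
          c(rotset$chis[[rr]], rep(rotset$proton_chi[rr], tpl$n_proton_chi))
        }))
        xyz <- cpp_build_chains(anchors, tpl$parent, tpl$gp, tpl$ggp, tpl$bond,
                                tpl$angle, tpl$dih, tpl$chi_idx, chimat)
      }
      if (length(cur_rows) > 0) {
        # the current conformation keeps its stored coordinates
        xyz <- rbind(xyz, unname(r$sidechain))
      }
    }
    groups[[aa]] <- list(aa = aa, idx = c(lib_rows, cur_rows), xyz = xyz,
                         m = tpl$m, tpl = tpl)
  }
  groups
}

# fixed scoring environment for candidates at residue i
build_candidate_env <- function(pose, i, config) {
  rs_i <- residue_sets(pose, i)
  n <- length(pose$residues)
  others <- setdiff(seq_len(n), i)
  sets <- c(list(rs_i$bb), lapply(others, function(j) {
    residue_all_set(residue_sets(pose, j))
  }))
  wscale <- rep(1, sum(vapply(sets, function(s) nrow(s$xyz), integer(1))))
  lig <- ligand_set(pose)
  if (!is.null(lig)) {
    sets <- c(sets, list(lig))
    wscale <- c(wscale, rep(config$w_lig, nrow(lig$xyz)))
  }
  env <- set_concat(sets)
  # offsets of each block in the concatenated environment
  sizes <- vapply(sets, function(s) nrow(s$xyz), integer(1))
  offs <- cumsum(c(0L, sizes))
  list(env = env, wscale = wscale, rs_i = rs_i,
       bb_off = 0L, bb_names = rs_i$bb$names,
       others = others, other_off = offs[1 + seq_along(others)],
       other_sets = sets[1 + seq_along(others)], i = i)
}

.excl_cache <- new.env(parent = emptyenv())

# exclusion pairs (candidate side-chain atom, environment atom) for one
# candidate amino acid: bonded-path exclusions to the own backbone and to
# bonded neighbour residues. Cached on (candidate aa, pivot, pose
# composition) -- the pairs depend only on topology, not coordinates.
candidate_env_exclusions <- function(pose, envinfo, aa) {
  key <- paste(aa, envinfo$i,
               paste(vapply(pose$residues, `[[`, character(1), "aa"),
                     collapse = ""),
               length(envinfo$bb_names), sep = "|")
  hit <- .excl_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- envinfo$i
  has_h <- "H" %in% envinfo$bb_names
  gd <- residue_graph_dist(aa, has_h)
  tpl <- sidechain_template(aa)
  if (tpl$m == 0L) return(.empty_excl)
  sc_names <- tpl$atoms
  excl <- intra_exclusions(gd, sc_names, envinfo$bb_names)  # own backbone at offset 0
  for (k in seq_along(envinfo$others)) {
    j <- envinfo$others[k]
    if (!.bonded(pose, i, j)) next
    dir <- if (pose$residues[[j]]$seqpos > pose$residues[[i]]$seqpos) 1L else -1L
    rs_j <- residue_sets(pose, j)
    names_j <- envinfo$other_sets[[k]]$names
    d_self <- if (dir == 1L) gd[sc_names, "C"] else gd[sc_names, "N"]
    d_j <- if (dir == 1L) rs_j$gd["N", names_j] else rs_j$gd["C", names_j]
    sep <- outer(d_self, d_j, `+`) + 1
    idx <- which(sep <= 3, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      excl <- rbind(excl, cbind(idx[, 1] - 1L,
                                idx[, 2] - 1L + envinfo$other_off[k]))
    }
  }
  assign(key, excl, envir = .excl_cache)
  excl
}

# reference-score energy of every candidate in `rotset` at residue i
# (side-chain-dependent terms only; constant backbone terms cancel in the
# Boltzmann selection and in the accepted-move delta)
candidate_energies <- function(pose, i, rotset, config, envinfo = NULL) {
  if (is.null(envinfo)) envinfo <- build_candidate_env(pose, i, config)
  par <- kernel_params(config)
  groups <- rotamer_candidates(pose, i, rotset)
  E <- numeric(nrow(rotset))
  for (g in groups) {
    self_terms <- config$w_rot * (-log(rotset$prob[g$idx])) + config$ref[[g$aa]]
    if (g$m == 0L || is.null(g$xyz)) {
      E[g$idx] <- self_terms
      next
    }
    k <- length(g$idx)
    excl_env <- candidate_env_exclusions(pose, envinfo, g$aa)
    gd <- residue_graph_dist(g$aa, "H" %in% envinfo$bb_names)
    excl_self <- intra_exclusions(gd, g$tpl$atoms, g$tpl$atoms)
    comp <- cpp_score_rotamers(g$xyz, k, g$m, g$tpl$rad, g$tpl$eps, g$tpl$hb,
                               g$tpl$acc, envinfo$env$xyz, envinfo$env$rad,
                               envinfo$env$eps, envinfo$env$hb,
                               envinfo$env$acc, envinfo$wscale, excl_env,
                               excl_self, par)
    E[g$idx] <- config$w_attr * comp[, 1] + config$w_rep * comp[, 2] +
      config$w_hb * comp[, 3] + self_terms
  }
  E
}
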