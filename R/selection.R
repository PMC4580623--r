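# Design tasks: which positions may mutate (design) and which may only
# change conformation (repack), with distance-shell and clash-based
# auto-selection.

#' Construct a design task
#'
#' @param design Tibble/data frame with columns `chain`, `seqpos` and
#'   optionally `allowed` (list-column of one-letter codes; default all 20).
#' @param repack Tibble/data frame with columns `chain`, `seqpos`.
#' @param pose Optional pose; when given, every listed position is checked
#'   to exist.
#' @return Object of class `cm_design_task`.
#' @export
design_task <- function(design = NULL, repack = NULL, pose = NULL) {
  as_pos <- function(x, with_allowed) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) {
      out <- tibble::tibble(chain = character(0), seqpos = integer(0))
      if (with_allowed) out$allowed <- list()
      return(out)
    }
    out <- tibble::as_tibble(x)
    out$seqpos <- as.integer(out$seqpos)
    if (with_allowed && !"allowed" %in% names(out))
      out$allowed <- rep(list(AA1), nrow(out))
    out
  }
  design <- as_pos(design, TRUE)
  repack <- as_pos(repack, FALSE)
  keys_of <- function(x) {
    if (nrow(x) == 0) character(0) else paste0(x$chain, ":", x$seqpos)
  }
  dk <- keys_of(design)
  rk <- keys_of(repack)
  if (length(intersect(dk, rk)) > 0)
    stop("positions cannot be both design and repack: ",
         paste(intersect(dk, rk), collapse = ", "))
  if (!is.null(pose)) {
    missing <- setdiff(c(dk, rk), pose$keys)
    if (length(missing) > 0)
      stop("task positions not in pose: ", paste(missing, collapse = ", "))
  }
  structure(list(design = design, repack = repack), class = "cm_design_task")
}

#' @export
print.cm_design_task <- function(x, ...) {
  cat("<design task>", nrow(x$design), "design,", nrow(x$repack),
      "repack position(s)\n")
  invisible(x)
}

# side-chain heavy atoms used for shell membership; glycine contributes its
# C-alpha as a surrogate so small mutable positions remain selectable
.shell_atoms <- function(r) {
  if (!is.null(r$sidechain)) {
    tpl <- sidechain_template(r$aa)
    heavy <- tpl$elements != "H"
    if (any(heavy)) return(r$sidechain[heavy, , drop = FALSE])
  }
  r$backbone["CA", , drop = FALSE]
}

#' Select designable positions by a distance shell around ligand atoms
#'
#' A residue is designable when at least one side-chain heavy atom (the
#' C-alpha for glycine) lies within `shell` Angstrom of any target ligand
#' atom. All 20 amino acids are allowed at selected positions.
#'
#' @param pose A pose with a ligand.
#' @param target_atoms Integer indices of ligand atoms to measure to
#'   (default: all heavy ligand atoms).
#' @param shell Shell radius in Angstrom (> 0). The conventions used by this
#'   package's benchmarks are 4.5 (differing-substructure atoms) and 6
#'   (all heavy ligand atoms).
#' @return A [design_task()] with the design side filled and no repack
#'   positions.
#' @export
select_design_positions <- function(pose, target_atoms = NULL, shell = 6) {
  if (shell <= 0) stop("shell must be > 0")
  if (is.null(pose$ligand)) stop("pose has no ligand")
  xyz <- ligand_coords(pose$ligand)
  heavy <- toupper(pose$ligand$atoms$element) != "H"
  if (is.null(target_atoms)) target_atoms <- which(heavy)
  if (length(target_atoms) == 0) stop("target_atoms must be nonempty")
  target <- xyz[target_atoms, , drop = FALSE]
  sel <- vapply(pose$residues, function(r) {
    sc <- .shell_atoms(r)
    d2 <- outer(rowSums(sc^2), rowSums(target^2), `+`) - 2 * sc %*% t(target)
    sqrt(max(0, min(d2))) <= shell
  }, logical(1))
  design <- tibble::tibble(
    chain = vapply(pose$residues[sel], `[[`, character(1), "chain"),
    seqpos = vapply(pose$residues[sel], `[[`, integer(1), "seqpos"),
    allowed = rep(list(AA1), sum(sel)))
  design_task(design = design, pose = pose)
}

#' Select repackable neighbours of the design positions by the clash rule
#'
#' A non-design residue is repackable when its current side chain has a
#' pairwise repulsive energy above `clash_threshold` against at least one
#' rotamer of at least one design position (the repulsive component of the
#' reference score is the "clash" energy).
#'
#' @param pose A pose.
#' @param task A [design_task()] with design positions.
#' @param config An [energy_config()].
#' @param clash_threshold Repulsive-energy threshold (energy units;
#'   default 5).
#' @param library Rotamer-library handle.
#' @return The task with the repack side filled.
#' @export
select_repack_neighbors <- function(pose, task, config = energy_config(),
                                    clash_threshold = 5,
                                    library = default_rotamer_library()) {
  par <- kernel_params(config)
  design_keys <- paste0(task$design$chain, ":", task$design$seqpos)
  candidates_j <- setdiff(seq_along(pose$residues),
                          match(design_keys, pose$keys))
  clash_max <- stats::setNames(numeric(length(candidates_j)),
                               as.character(candidates_j))
  empty_env <- matrix(0, 0, 3)
  for (d in seq_len(nrow(task$design))) {
    i <- residue_index(pose, task$design$chain[d], task$design$seqpos[d])
    rotset <- get_rotamers(pose, list(chain = task$design$chain[d],
                                      seqpos = task$design$seqpos[d]),
                           allowed_aas = task$design$allowed[[d]],
                           library = library)
    groups <- rotamer_candidates(pose, i, rotset)
    # candidate-internal repulsion (identical in every pair score) is
    # subtracted so only the pairwise rotamer-vs-residue clash remains
    internal <- lapply(groups, function(g) {
      if (g$m == 0L || is.null(g$xyz)) return(NULL)
      cpp_score_rotamers(g$xyz, length(g$idx), g$m, g$tpl$rad, g$tpl$eps,
                         g$tpl$hb, g$tpl$acc, empty_env, numeric(0),
                         numeric(0), integer(0), integer(0), numeric(0),
                         .empty_excl, .empty_excl, par)
    })
    for (j in candidates_j) {
      rs_j <- residue_sets(pose, j)
      if (is.null(rs_j$sc)) next
      for (g in groups) {
        if (g$m == 0L || is.null(g$xyz)) next
        excl <- .empty_excl
        if (.bonded(pose, i, j)) {
          gd <- residue_graph_dist(g$aa, FALSE)
          dir <- if (pose$residues[[j]]$seqpos > pose$residues[[i]]$seqpos) 1L else -1L
          d_self <- if (dir == 1L) gd[g$tpl$atoms, "C"] else gd[g$tpl$atoms, "N"]
          d_j <- if (dir == 1L) rs_j$gd["N", rs_j$sc$names] else
            rs_j$gd["C", rs_j$sc$names]
          sep <- outer(d_self, d_j, `+`) + 1
          idx <- which(sep <= 3, arr.ind = TRUE)
          if (nrow(idx) > 0) excl <- cbind(idx[, 1] - 1L, idx[, 2] - 1L)
        }
        comp <- cpp_score_rotamers(g$xyz, length(g$idx), g$m, g$tpl$rad,
                                   g$tpl$eps, g$tpl$hb, g$tpl$acc,
                                   rs_j$sc$xyz, rs_j$sc$rad, rs_j$sc$eps,
                                   rs_j$sc$hb, rs_j$sc$acc, numeric(0),
                                   excl, .empty_excl, par)
        rep_max <- config$w_rep * max(comp[, 2] - internal[[g$aa]][, 2])
        key <- as.character(j)
        if (rep_max > clash_max[key]) clash_max[key] <- rep_max
      }
    }
  }
  sel <- candidates_j[clash_max[as.character(candidates_j)] > clash_threshold]
  repack <- tibble::tibble(
    chain = vapply(pose$residues[sel], `[[`, character(1), "chain"),
    seqpos = vapply(pose$residues[sel], `[[`, integer(1), "seqpos"))
  design_task(design = task$design, repack = repack, pose = pose)
}

#' Read a design task file
#'
#' Plain text, one line per position: `CHAIN SEQPOS MODE [AAS]` with MODE
#' `DESIGN` or `REPACK` and AAS an optional string of allowed one-letter
#' codes for design lines. Blank lines and lines starting `#` are skipped.
#'
#' @param path File path.
#' @param pose Optional pose for validation.
#' @return A [design_task()].
#' @export
read_task_file <- function(path, pose = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  design <- list(); repack <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 3) stop("malformed task line: ", ln)
    mode <- toupper(f[3])
    if (mode == "DESIGN") {
      allowed <- if (length(f) >= 4) strsplit(toupper(f[4]), "")[[1]] else AA1
      if (!all(allowed %in% AA1)) stop("unknown amino acids in task line: ", ln)
      design[[length(design) + 1]] <- tibble::tibble(
        chain = f[1], seqpos = as.integer(f[2]), allowed = list(allowed))
    } else if (mode == "REPACK") {
      repack[[length(repack) + 1]] <- tibble::tibble(
        chain = f[1], seqpos = as.integer(f[2]))
    } else {
      stop("unknown task mode: ", mode)
    }
  }
  design_task(design = dplyr::bind_rows(design),
              repack = dplyr::bind_rows(repack), pose = pose)
}

#' Write a design task file
#'
#' @param task A [design_task()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_task_file <- function(task, path) {
  lines <- character(0)
  for (d in seq_len(nrow(task$design))) {
    aas <- task$design$allowed[[d]]
    lines <- c(lines, paste(task$design$chain[d], task$design$seqpos[d],
                            "DESIGN", paste0(aas, collapse = "")))
  }
  for (r in seq_len(nrow(task$repack))) {
    lines <- c(lines, paste(task$repack$chain[r], task$repack$seqpos[r], "REPACK"))
  }
  writeLines(lines, path)
  invisible(path)
}
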