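# Backbone-dependent discrete side-chain states. The packaged default is a
# synthetic generative library: canonical chi wells per dihedral class with
# deterministic, smoothly (phi, psi)-bin-dependent weights, truncated at 95%
# cumulative probability. It is a pure function of (aa, phi bin, psi bin) on
# a 10-degree grid -- the structural contract the sampler needs -- but its
# probabilities are not survey statistics. Table-backed libraries in a
# documented TSV format (and the standard backbone-dependent text format)
# can be loaded instead.

# chi-well classes: sp3 chi1 prefers gauche-; sp3 chis further out prefer
# trans (avoids the coiled syn-pentane-like combinations that real rotamer
# statistics also disfavour)
.sp3_wells <- c(-60, 180, 60)
.sp3_w <- c(0.50, 0.33, 0.17)
.sp3t_wells <- c(180, -60, 60)
.sp3t_w <- c(0.55, 0.28, 0.17)
.arom_wells <- c(90, -90)
.arom_w <- c(0.5, 0.5)
.carb_wells <- c(0, 90, -90)
.carb_w <- c(0.40, 0.30, 0.30)

.CHI_CLASSES <- list(
  S = "sp3", C = "sp3", T = "sp3", V = "sp3",
  L = c("sp3", "sp3t"), I = c("sp3", "sp3t"), M = c("sp3", "sp3t", "sp3t"),
  F = c("sp3", "arom"), Y = c("sp3", "arom"), W = c("sp3", "arom"),
  H = c("sp3", "arom"), D = c("sp3", "carb"), E = c("sp3", "sp3t", "carb"),
  N = c("sp3", "carb"), Q = c("sp3", "sp3t", "carb"),
  K = c("sp3", "sp3t", "sp3t", "sp3t"), R = c("sp3", "sp3t", "sp3t", "sp3t")
)

.well_table <- function(class) {
  switch(class,
         sp3 = list(wells = .sp3_wells, w = .sp3_w),
         sp3t = list(wells = .sp3t_wells, w = .sp3t_w),
         arom = list(wells = .arom_wells, w = .arom_w),
         carb = list(wells = .carb_wells, w = .carb_w))
}

# deterministic smooth weight modulation by (phi, psi) bin; keeps the library
# a pure function of the bin while giving every bin distinct statistics
.bin_modulation <- function(w, phi_bin, psi_bin, aa_idx, chi_k) {
  phase <- (phi_bin + 0.5 * psi_bin) * pi / 180 + aa_idx + 2 * chi_k
  mod <- 1 + 0.25 * cos(phase + 2 * pi * (seq_along(w) - 1) / length(w))
  w2 <- w * mod
  w2 / sum(w2)
}

.rotlib_cache <- new.env(parent = emptyenv())

# generate the synthetic rotamer list for one (aa, phi_bin, psi_bin)
.synthetic_bin <- function(aa, phi_bin, psi_bin) {
  n_chi <- CHI_COUNTS[[aa]]
  if (aa == "P") {
    return(tibble::tibble(prob = 1, chis = list(c(-26.5, 39.0))))
  }
  if (n_chi == 0L) {
    return(tibble::tibble(prob = 1, chis = list(numeric(0))))
  }
  classes <- .CHI_CLASSES[[aa]]
  aa_idx <- match(aa, AA1)
  per_chi <- lapply(seq_len(n_chi), function(k) {
    wt <- .well_table(classes[k])
    w <- .bin_modulation(wt$w, phi_bin, psi_bin, aa_idx, k)
    list(wells = wt$wells, w = w)
  })
  grid <- do.call(expand.grid, lapply(per_chi, function(p) seq_along(p$wells)))
  prob <- apply(grid, 1, function(idx) {
    prod(vapply(seq_len(n_chi), function(k) per_chi[[k]]$w[idx[k]], numeric(1)))
  })
  chis <- lapply(seq_len(nrow(grid)), function(r) {
    vapply(seq_len(n_chi), function(k) per_chi[[k]]$wells[grid[r, k]], numeric(1))
  })
  ord <- order(prob, decreasing = TRUE)
  prob <- prob[ord]; chis <- chis[ord]
  keep <- which(cumsum(prob) - prob < 0.95)
  keep <- keep[seq_len(min(length(keep), 12L))]
  tibble::tibble(prob = prob[keep], chis = chis[keep])
}

#' The packaged synthetic backbone-dependent rotamer library
#'
#' A deterministic generative library: for each amino acid and 10-degree
#' (phi, psi) bin it returns canonical chi-well rotamers whose probabilities
#' vary smoothly with the bin, truncated at 95% cumulative probability.
#' Lookup is a pure function of (aa, phi bin, psi bin).
#'
#' @return A rotamer-library handle (class `cm_rotlib`).
#' @export
default_rotamer_library <- function() {
  structure(list(kind = "synthetic", lookup = .synthetic_bin),
            class = "cm_rotlib")
}

#' Read a rotamer library from the package TSV format
#'
#' Whitespace-separated columns `AA PHI_BIN PSI_BIN PROB CHI1 CHI2 CHI3 CHI4`
#' (unused chi columns `NA` or absent). Queries for a bin absent from the
#' table fall back to the nearest tabulated bin of that amino acid.
#'
#' @param path TSV path.
#' @return A rotamer-library handle (class `cm_rotlib`).
#' @export
read_rotamer_library <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- toupper(names(tab))
  stopifnot(all(c("AA", "PHI_BIN", "PSI_BIN", "PROB") %in% names(tab)))
  chi_cols <- intersect(paste0("CHI", 1:4), names(tab))
  lookup <- function(aa, phi_bin, psi_bin) {
    rows <- tab[tab$AA == aa, , drop = FALSE]
    if (nrow(rows) == 0) stop("no rotamers for amino acid ", aa, " in table")
    d <- abs(rows$PHI_BIN - phi_bin) + abs(rows$PSI_BIN - psi_bin)
    sel <- rows[d == min(d), , drop = FALSE]
    n_chi <- CHI_COUNTS[[aa]]
    chis <- lapply(seq_len(nrow(sel)), function(r) {
      v <- as.numeric(sel[r, chi_cols])
      v[seq_len(n_chi)]
    })
    ord <- order(sel$PROB, decreasing = TRUE)
    tibble::tibble(prob = sel$PROB[ord], chis = chis[ord])
  }
  structure(list(kind = "tsv", lookup = lookup), class = "cm_rotlib")
}

#' Read a library in the standard backbone-dependent rotamer text format
#'
#' Parses the whitespace-separated text format used by standard
#' backbone-dependent rotamer libraries (comment lines start with `#`;
#' columns: residue, phi, psi, count, r1-r4, probability, four chi means,
#' four chi standard deviations). Only the chi means and probabilities are
#' used.
#'
#' @param path Path to the text file.
#' @param min_prob Rotamers below this probability are dropped.
#' @return A rotamer-library handle (class `cm_rotlib`).
#' @export
read_dunbrack_library <- function(path, min_prob = 0.01) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  aa3 <- toupper(vapply(fields, `[[`, character(1), 1))
  aa <- unname(AA1_FROM_3[aa3])
  phi <- as.numeric(vapply(fields, `[[`, character(1), 2))
  psi <- as.numeric(vapply(fields, `[[`, character(1), 3))
  prob <- as.numeric(vapply(fields, `[[`, character(1), 9))
  chi <- t(vapply(fields, function(f) as.numeric(f[10:13]), numeric(4)))
  keep <- !is.na(aa) & prob >= min_prob
  tab <- data.frame(AA = aa[keep], PHI_BIN = phi[keep], PSI_BIN = psi[keep],
                    PROB = prob[keep], CHI1 = chi[keep, 1], CHI2 = chi[keep, 2],
                    CHI3 = chi[keep, 3], CHI4 = chi[keep, 4])
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(tab, tmp, row.names = FALSE, quote = FALSE)
  read_rotamer_library(tmp)
}

# cached bin lookup
.library_bin <- function(library, aa, phi_bin, psi_bin) {
  key <- paste(library$kind, aa, phi_bin, psi_bin, sep = "|")
  hit <- .rotlib_cache[[key]]
  if (!is.null(hit) && library$kind == "synthetic") return(hit)
  out <- library$lookup(aa, phi_bin, psi_bin)
  if (library$kind == "synthetic") assign(key, out, envir = .rotlib_cache)
  out
}

bin10 <- function(x) 10 * round(x / 10)

# backbone dihedrals at residue i; canonical helical fallback at termini
pose_phi_psi <- function(pose, i) {
  r <- pose$residues[[i]]
  phi <- NA_real_; psi <- NA_real_
  if (i > 1L) {
    prev <- pose$residues[[i - 1L]]
    if (prev$chain == r$chain) {
      phi <- dihedral_angle(prev$backbone["C", ], r$backbone["N", ],
                            r$backbone["CA", ], r$backbone["C", ])
    }
  }
  if (i < length(pose$residues)) {
    nxt <- pose$residues[[i + 1L]]
    if (nxt$chain == r$chain) {
      psi <- dihedral_angle(r$backbone["N", ], r$backbone["CA", ],
                            r$backbone["C", ], nxt$backbone["N", ])
    }
  }
  c(phi = if (is.na(phi)) -57 else phi, psi = if (is.na(psi)) -47 else psi)
}

.proton_wells <- c(-60, 60, 180)

#' Rotamer set at a position
#'
#' Looks up the backbone-dependent rotamers for every allowed amino acid at
#' the 10-degree (phi, psi) bin of the position, expands hydroxyl proton
#' chis (Ser/Thr/Tyr) over three positions, and appends the current
#' side-chain conformation as an extra rotamer so that a null move is always
#' available. The current rotamer keeps the library probability it was built
#' with; per-amino-acid probabilities are rescaled to sum to at most 1.
#'
#' @param pose A pose.
#' @param position List or vector with `chain` and `seqpos`.
#' @param allowed_aas Character vector of one-letter codes.
#' @param library Rotamer-library handle.
#' @return Tibble with columns `aa`, `prob`, `current`, `chis`
#'   (list-column), `proton_chi`; attributes `phi`, `psi`.
#' @export
get_rotamers <- function(pose, position, allowed_aas = AA1,
                         library = default_rotamer_library()) {
  if (length(allowed_aas) == 0) stop("allowed_aas must be nonempty")
  stopifnot(all(allowed_aas %in% AA1))
  i <- residue_index(pose, position[["chain"]], as.integer(position[["seqpos"]]))
  r <- pose$residues[[i]]
  pp <- pose_phi_psi(pose, i)
  phi_bin <- bin10(pp[["phi"]]); psi_bin <- bin10(pp[["psi"]])
  aas <- union(allowed_aas, r$aa)  # the current state is always a candidate
  part_key <- paste(library$kind, phi_bin, psi_bin,
                    paste(aas, collapse = ""), sep = "|")
  part <- if (library$kind == "synthetic") .rotlib_cache[[part_key]] else NULL
  if (is.null(part)) {
    parts <- lapply(aas, function(aa) {
      rot <- .library_bin(library, aa, phi_bin, psi_bin)
      n_pchi <- if (aa %in% names(PROTON_CHI)) 1L else 0L
      if (n_pchi > 0) {
        rot <- tibble::tibble(
          prob = rep(rot$prob / 3, each = 3),
          chis = rep(rot$chis, each = 3),
          proton_chi = rep(.proton_wells, times = nrow(rot)))
      } else {
        rot$proton_chi <- 180
      }
      tibble::tibble(aa = aa, prob = rot$prob, current = FALSE,
                     chis = rot$chis, proton_chi = rot$proton_chi)
    })
    part <- dplyr::bind_rows(parts)
    if (library$kind == "synthetic") assign(part_key, part, envir = .rotlib_cache)
  }
  out <- part
  # append the current conformation; it keeps the probability it was built
  # with so its self-energy matches the pose's stored state exactly
  cur_prob <- if (!is.null(r$rot_prob) && is.finite(r$rot_prob)) r$rot_prob else 1
  out <- dplyr::bind_rows(out, tibble::tibble(
    aa = r$aa, prob = cur_prob, current = TRUE, chis = list(r$chis),
    proton_chi = r$proton_chi))
  # probabilities are raw library values (a pure function of the rotamer):
  # they feed the -ln(prob) self-energy, so they must not depend on which
  # other rotamers happen to be in the set. Library rows per amino acid sum
  # to <= 1 by construction; the appended current rotamer may push the sum
  # slightly above 1.
  attr(out, "phi") <- pp[["phi"]]
  attr(out, "psi") <- pp[["psi"]]
  attr(out, "position") <- list(chain = r$chain, seqpos = r$seqpos)
  out
}

#' Realize a rotamer in coordinates
#'
#' Rebuilds the side chain at a position from ideal internal coordinates and
#' the rotamer's chi angles; the backbone is untouched and the previous side
#' chain is replaced atomically.
#'
#' @param pose A pose.
#' @param position List/vector with `chain` and `seqpos`.
#' @param rotamer A list or one-row tibble with `aa`, `chis`, `proton_chi`
#'   and `prob` (as returned by [get_rotamers()]).
#' @return The modified pose.
#' @export
build_sidechain <- function(pose, position, rotamer) {
  i <- residue_index(pose, position[["chain"]], as.integer(position[["seqpos"]]))
  aa <- if (is.character(rotamer$aa)) rotamer$aa[1] else rotamer$aa
  chis <- rotamer$chis
  if (is.list(chis)) chis <- chis[[1]]
  pchi <- if (!is.null(rotamer$proton_chi)) rotamer$proton_chi[1] else 180
  prob <- if (!is.null(rotamer$prob)) rotamer$prob[1] else 1
  r <- pose$residues[[i]]
  sc <- build_sidechain_matrix(aa, r$backbone["N", ], r$backbone["CA", ],
                               r$backbone["C", ], chis, pchi)
  set_sidechain(pose, i, aa, sc, chis, pchi, prob)
}
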