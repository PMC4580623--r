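# PDB input/output. Parsing is delegated to bio3d; the writer emits standard
# fixed-width ATOM/HETATM records (3-decimal coordinates, altloc column 17,
# occupancy columns 55-60). Hydrogens are never written: polar hydrogens are
# re-derived from ideal geometry on read, so the heavy-atom record is the
# complete state.

#' Read a protein-ligand complex from a PDB file
#'
#' Builds a pose from ATOM records (one residue per (chain, resno)) and,
#' optionally, a single-conformer ligand from HETATM records carrying
#' `ligand_code`. Side-chain chi angles are measured from the coordinates;
#' alternate-location records are retained in the raw atom table
#' (`pose$atoms`) with the first altloc used for the working coordinates.
#'
#' @param path PDB file path.
#' @param ligand_code HETATM residue code naming the ligand (user-declared;
#'   no automated cofactor detection). `NULL` reads the protein only.
#' @param model Ignored unless the file has multiple models, in which case
#'   the first model is used.
#' @return A pose.
#' @export
read_pdb <- function(path, ligand_code = NULL, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  element <- ifelse(is.na(at$elesy) | at$elesy == "",
                    substr(gsub("^[0-9]+", "", at$elety), 1, 1), at$elesy)
  atoms <- tibble::tibble(
    type = at$type, name = at$elety, altloc = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    seqpos = at$resno, x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o), element = toupper(element)
  )
  is_protein <- atoms$type == "ATOM" & atoms$resid %in% names(AA1_FROM_3)
  unknown <- atoms$type == "ATOM" & !is_protein
  if (any(unknown)) {
    warning("skipping ", length(unique(paste(atoms$resid[unknown],
            atoms$seqpos[unknown]))), " non-standard ATOM residue(s): ",
            paste(unique(atoms$resid[unknown]), collapse = ", "))
  }
  prot <- atoms[is_protein & atoms$element != "H", ]
  key <- paste(prot$chain, prot$seqpos)
  residues <- list()
  for (k in unique(key)) {
    rows <- prot[key == k, ]
    # working coordinates use the first altloc of each atom
    rows <- rows[!duplicated(rows$name), ]
    aa <- AA1_FROM_3[[rows$resid[1]]]
    bb_names <- c("N", "CA", "C", "O")
    if (!all(bb_names %in% rows$name)) {
      stop("missing backbone atom(s) in residue ", rows$resid[1], " ",
           rows$chain[1], ":", rows$seqpos[1])
    }
    backbone <- as.matrix(rows[match(bb_names, rows$name), c("x", "y", "z")])
    rownames(backbone) <- bb_names
    tpl <- sidechain_template(aa)
    heavy <- tpl$atoms[tpl$elements != "H"]
    sidechain <- NULL
    chis <- NULL
    if (length(heavy) > 0) {
      if (all(heavy %in% rows$name)) {
        sc_heavy <- as.matrix(rows[match(heavy, rows$name), c("x", "y", "z")])
        rownames(sc_heavy) <- heavy
        chis <- extract_chis(aa, backbone, sc_heavy)
        # re-derive polar hydrogens from ideal geometry at the measured chis
        rebuilt <- build_sidechain_matrix(aa, backbone["N", ], backbone["CA", ],
                                          backbone["C", ], chis)
        sidechain <- rebuilt
        sidechain[heavy, ] <- sc_heavy
      } else {
        warning("incomplete side chain at ", k, "; rebuilt from ideal geometry")
        sidechain <- build_sidechain_matrix(aa, backbone["N", ], backbone["CA", ],
                                            backbone["C", ],
                                            rep(180, CHI_COUNTS[[aa]]))
        chis <- extract_chis(aa, backbone, sidechain)
      }
    }
    residues[[length(residues) + 1L]] <- new_residue(
      rows$chain[1], rows$seqpos[1], aa, backbone, sidechain, chis)
  }
  ligand <- NULL
  if (!is.null(ligand_code)) {
    het <- atoms[atoms$type == "HETATM" & atoms$resid == ligand_code, ]
    if (nrow(het) == 0) stop("no HETATM records with residue code ", ligand_code)
    ligand <- new_ligand(
      tibble::tibble(name = het$name, element = het$element),
      bonds = NULL,
      conformers = list(as.matrix(het[, c("x", "y", "z")])),
      resname = ligand_code, chain = het$chain[1], seqpos = het$seqpos[1])
  }
  new_pose(residues, ligand = ligand, id = basename(path), atoms = atoms)
}

.pdb_line <- function(type, serial, name, resid, chain, seqpos, xyz, element,
                      altloc = "") {
  name_fmt <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, altloc, resid, chain, seqpos,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Write a pose to a PDB file
#'
#' Standard fixed-width ATOM records for the protein followed by a HETATM
#' block for the ligand (active conformer, frame applied). Hydrogens are not
#' written.
#'
#' @param pose A pose.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_pdb <- function(pose, path) {
  if (length(pose$residues) == 0) stop("cannot write an empty pose")
  lines <- character(0)
  serial <- 0L
  for (r in pose$residues) {
    resid <- AA3[[r$aa]]
    tpl <- sidechain_template(r$aa)
    names_out <- c("N", "CA", "C", "O", tpl$atoms[tpl$elements != "H"])
    for (nm in names_out) {
      xyz <- if (nm %in% rownames(r$backbone)) r$backbone[nm, ] else r$sidechain[nm, ]
      serial <- serial + 1L
      el <- if (nm %in% c("N", "CA", "C", "O")) substr(nm, 1, 1) else
        tpl$elements[match(nm, tpl$atoms)]
      lines <- c(lines, .pdb_line("ATOM", serial, nm, resid, r$chain,
                                  r$seqpos, xyz, el))
    }
  }
  if (!is.null(pose$ligand)) {
    lig <- pose$ligand
    xyz <- ligand_coords(lig)
    for (i in seq_len(nrow(lig$atoms))) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_line("HETATM", serial, lig$atoms$name[i],
                                  lig$resname, lig$chain, lig$seqpos,
                                  xyz[i, ], lig$atoms$element[i]))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
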