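# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fx_helix <- function(sequence = "AALSAVKDA") {
  key <- paste0("helix_", sequence)
  if (is.null(.fx[[key]])) .fx[[key]] <- make_helix_pose(sequence)
  .fx[[key]]
}

fx_toy <- function(shape = "two-atom-dumbbell", target_aa = "A", ...) {
  key <- paste("toy", shape, target_aa, sep = "_")
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- make_toy_complex(toy_complex_spec(
      ligand_shape = shape, target_aa = target_aa, ...))
  }
  .fx[[key]]
}

fx_crowded <- function() {
  if (is.null(.fx$crowded)) .fx$crowded <- make_crowded_complex(seed = 2)
  .fx$crowded
}

fx_pair <- function() {
  if (is.null(.fx$pair)) .fx$pair <- make_specificity_pair(seed = 1)
  .fx$pair
}

# all covalently bonded atom pairs of a pose backbone (for geometry checks)
backbone_bond_lengths <- function(pose) {
  out <- numeric(0)
  n <- length(pose$residues)
  for (i in seq_len(n)) {
    r <- pose$residues[[i]]
    out <- c(out,
             sqrt(sum((r$backbone["N", ] - r$backbone["CA", ])^2)),
             sqrt(sum((r$backbone["CA", ] - r$backbone["C", ])^2)),
             sqrt(sum((r$backbone["C", ] - r$backbone["O", ])^2)))
    if (!is.null(r$sidechain)) {
      out <- c(out, sqrt(sum((r$backbone["CA", ] - r$sidechain["CB", ])^2)))
    }
    if (i < n) {
      out <- c(out, sqrt(sum((r$backbone["C", ] -
                                pose$residues[[i + 1]]$backbone["N", ])^2)))
    }
  }
  out
}

max_backbone_displacement <- function(a, b) {
  max(vapply(seq_along(a$residues), function(i) {
    max(abs(a$residues[[i]]$backbone - b$residues[[i]]$backbone))
  }, numeric(1)))
}
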