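# Benchmark evaluation mathematics.
#
# Benchmark 1 (specificity): percent enrichment of a mutation is its percent
# occurrence among unique sequences designed for the non-native ligand minus
# its percent occurrence among sequences designed for the native ligand
# (sign flipped for the mutant-to-wild-type direction); candidates are
# ranked by descending enrichment and a prediction is "correct" when its
# enrichment is positive.
#
# Benchmark 2 (sequence tolerance): per-position amino-acid distributions of
# designed vs natural sequences are compared by profile similarity
# 1 - JS(p, q) (Jensen-Shannon divergence, equal mixture weights, base-2
# logarithms, so similarity spans [0, 1]); per-position sequence entropy
# uses base-20 logarithms so the uniform distribution scores 1.

.seq_matrix <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0) stop("empty sequence set")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences are not aligned (unequal lengths)")
  do.call(rbind, strsplit(seqs, ""))
}

#' Percent-enrichment analysis of two designed sequence sets
#'
#' For every (position, amino acid) observed in either set and differing
#' from the start residue, computes the percent occurrence in each set (over
#' unique sequences), the percent enrichment for the requested direction,
#' and the rank/percentile of each candidate over all positions pooled.
#' Ties in enrichment are broken by (position, amino acid) order for
#' determinism.
#'
#' @param native_seqs,nonnative_seqs Sequence sets (character vectors
#'   aligned over the same design positions, e.g. from [pool_sequences()]).
#' @param direction `"wt2mut"` (enrichment in the non-native set) or
#'   `"mut2wt"` (enrichment in the native set).
#' @param wt Start sequence over the design positions; default taken from
#'   the `wt` attribute of either set.
#' @return Tibble of class `cm_enrichment_table` with columns `position`,
#'   `from_aa`, `to_aa`, `pct_native`, `pct_nonnative`, `PE`, `rank`,
#'   `percentile`, `correct`.
#' @export
enrichment_analysis <- function(native_seqs, nonnative_seqs,
                                direction = c("wt2mut", "mut2wt"), wt = NULL) {
  direction <- match.arg(direction)
  if (is.null(wt)) {
    wt <- attr(native_seqs, "wt")
    if (is.null(wt)) wt <- attr(nonnative_seqs, "wt")
    if (is.null(wt)) stop("start sequence `wt` required")
  }
  nat <- .seq_matrix(unique(as.character(native_seqs)))
  non <- .seq_matrix(unique(as.character(nonnative_seqs)))
  if (ncol(nat) != ncol(non) || ncol(nat) != nchar(wt))
    stop("sequence sets and wt are not aligned over the same positions")
  wt_aa <- strsplit(wt, "")[[1]]
  pos_labels <- {
    dp <- attr(native_seqs, "positions")
    if (!is.null(dp) && nrow(dp) == ncol(nat)) {
      paste0(dp$chain, ":", dp$seqpos)
    } else {
      as.character(seq_len(ncol(nat)))
    }
  }
  rows <- list()
  for (p in seq_len(ncol(nat))) {
    aas <- sort(setdiff(unique(c(nat[, p], non[, p])), wt_aa[p]))
    for (aa in aas) {
      pct_nat <- 100 * mean(nat[, p] == aa)
      pct_non <- 100 * mean(non[, p] == aa)
      pe <- if (direction == "wt2mut") pct_non - pct_nat else pct_nat - pct_non
      rows[[length(rows) + 1]] <- tibble::tibble(
        position = pos_labels[p], from_aa = wt_aa[p], to_aa = aa,
        pct_native = pct_nat, pct_nonnative = pct_non, PE = pe)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(position = character(0), from_aa = character(0),
                          to_aa = character(0), pct_native = numeric(0),
                          pct_nonnative = numeric(0), PE = numeric(0),
                          rank = integer(0), percentile = numeric(0),
                          correct = logical(0))
  } else {
    ord <- order(-out$PE, out$position, out$to_aa)
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    N <- nrow(out)
    out$percentile <- 100 * (N - out$rank + 1) / N
    out$correct <- out$PE > 0
  }
  class(out) <- c("cm_enrichment_table", class(out))
  attr(out, "direction") <- direction
  out
}

#' Per-position amino-acid profiles of an aligned sequence set
#'
#' Columns containing gap characters (`-` or `.`) are dropped with a
#' warning; remaining profiles are normalized frequency distributions over
#' the 20 amino acids with an optional pseudocount.
#'
#' @param seqs Aligned sequences (character vector).
#' @param pseudocount Added to every amino-acid count before normalization
#'   (default 0).
#' @return Tibble with columns `position` (original column index),
#'   `entropy` (base-20) and `p` (list-column of named 20-vectors).
#' @export
build_profiles <- function(seqs, pseudocount = 0) {
  m <- .seq_matrix(seqs)
  has_gap <- apply(m, 2, function(col) any(col %in% c("-", ".")))
  if (any(has_gap)) {
    warning("dropping ", sum(has_gap), " alignment column(s) containing gaps")
  }
  keep <- which(!has_gap)
  profs <- lapply(keep, function(p) {
    counts <- table(factor(m[, p], levels = AA1))
    pr <- as.numeric(counts) + pseudocount
    pr <- pr / sum(pr)
    stats::setNames(pr, AA1)
  })
  tibble::tibble(position = keep,
                 entropy = vapply(profs, sequence_entropy, numeric(1)),
                 p = profs)
}

.js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  (kl(p) + kl(q)) / 2
}

#' Profile similarity: 1 minus the Jensen-Shannon divergence
#'
#' Equal mixture weights and base-2 logarithms, so the similarity spans
#' [0, 1]: 1 for identical distributions, 0 for disjoint point masses.
#' Symmetric in its arguments; 0 log 0 is taken as 0.
#'
#' @param p,q Probability vectors over the same support (named 20-vectors
#'   as produced by [build_profiles()]).
#' @return Similarity in [0, 1].
#' @export
profile_similarity <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == length(q))
  1 - .js_divergence(p / sum(p), q / sum(q))
}

#' Base-20 sequence entropy of an amino-acid distribution
#'
#' H = -sum_x P_x log20 P_x, so a point mass scores 0 and the uniform
#' distribution over the 20 amino acids scores 1.
#'
#' @param p Probability vector (normalized internally).
#' @return Entropy in [0, 1].
#' @export
sequence_entropy <- function(p) {
  p <- as.numeric(p)
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]) / log(20))
}

#' Per-position similarity between designed and natural profiles
#'
#' @param designed,natural Profile tibbles from [build_profiles()] over the
#'   same positions (matched by row order).
#' @return Tibble of class `cm_profile_similarity` with columns `position`,
#'   `natural_entropy`, `similarity`.
#' @export
profile_similarity_table <- function(designed, natural) {
  if (nrow(designed) != nrow(natural))
    stop("designed and natural profiles cover different numbers of positions")
  out <- tibble::tibble(
    position = natural$position,
    natural_entropy = natural$entropy,
    similarity = vapply(seq_len(nrow(designed)), function(i) {
      profile_similarity(designed$p[[i]], natural$p[[i]])
    }, numeric(1)))
  class(out) <- c("cm_profile_similarity", class(out))
  out
}

#' Split positions into entropy tertiles
#'
#' Positions are sorted by natural-sequence entropy and split into three
#' groups (high = top third); when the count is not divisible by three the
#' extra positions go to the lower-entropy groups. Ties are resolved by
#' stable sort order, so the grouping is deterministic.
#'
#' @param natural Profile tibble from [build_profiles()] (columns `position`
#'   and `entropy`).
#' @param values Optional per-position metric (same order as `natural`) to
#'   carry along, e.g. profile similarity.
#' @return Tibble with columns `position`, `entropy`, `tertile`
#'   (`high`/`medium`/`low`) and optionally `value`.
#' @export
entropy_tertiles <- function(natural, values = NULL) {
  n <- nrow(natural)
  if (n < 3) stop("need at least 3 positions for tertiles")
  ord <- order(-natural$entropy)
  n_high <- n %/% 3L
  n_med <- (n - n_high) %/% 2L
  n_low <- n - n_high - n_med
  tertile <- character(n)
  tertile[ord] <- rep(c("high", "medium", "low"), times = c(n_high, n_med, n_low))
  out <- tibble::tibble(position = natural$position, entropy = natural$entropy,
                        tertile = factor(tertile, levels = c("high", "medium", "low")))
  if (!is.null(values)) out$value <- values
  out
}

#' Similarity of natural profiles to the uniform null model
#'
#' The null model assumes a uniform amino-acid distribution at every
#' position; the similarity of each natural profile to it bounds what
#' unbiased sequence diversity alone achieves.
#'
#' @param natural Profile tibble from [build_profiles()].
#' @return Tibble with columns `position`, `similarity`.
#' @export
uniform_null_similarity <- function(natural) {
  unif <- rep(1 / 20, 20)
  tibble::tibble(
    position = natural$position,
    similarity = vapply(natural$p, profile_similarity, numeric(1), q = unif))
}

#' Glycine fraction and acceptance ratio of a design trace
#'
#' Glycine fraction is the fraction of design-position residues that are
#' glycine over the unique accepted sequences; the acceptance ratio is
#' accepted moves over total moves.
#'
#' @param trace A design trace.
#' @return One-row tibble with `glycine_fraction`, `acceptance_ratio`,
#'   `n_unique_sequences`, `n_moves`.
#' @export
design_diagnostics <- function(trace) {
  chars <- unlist(strsplit(trace$sequences, ""))
  gly <- if (length(chars) > 0) mean(chars == "G") else NA_real_
  tibble::tibble(glycine_fraction = gly,
                 acceptance_ratio = trace$acceptance_ratio,
                 n_unique_sequences = length(trace$sequences),
                 n_moves = nrow(trace$ledger))
}

#' Significance tests for the two benchmarks
#'
#' Correct/incorrect prediction counts are compared with a two-sided
#' Fisher's exact test; per-position profile-similarity vectors are compared
#' with a paired two-tailed t-test. Degenerate inputs (a zero margin, or
#' identical paired vectors with zero difference variance) return p = 1 with
#' a warning.
#'
#' @param counts Optional 2x2 matrix of correct/incorrect counts for two
#'   methods.
#' @param paired_a,paired_b Optional equal-length numeric vectors of paired
#'   per-position values.
#' @return Tibble with columns `test` and `p_value`.
#' @export
significance_tests <- function(counts = NULL, paired_a = NULL,
                               paired_b = NULL) {
  out <- list()
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == c(2, 2)))
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
      warning("degenerate 2x2 table (zero margin); Fisher p set to 1")
      p <- 1
    } else {
      p <- stats::fisher.test(counts)$p.value
    }
    out[[length(out) + 1]] <- tibble::tibble(test = "fisher_exact", p_value = p)
  }
  if (!is.null(paired_a)) {
    stopifnot(length(paired_a) == length(paired_b))
    d <- paired_a - paired_b
    if (stats::sd(d) < 1e-15) {
      warning("paired differences have zero variance; t-test p set to 1")
      p <- 1
    } else {
      p <- stats::t.test(paired_a, paired_b, paired = TRUE,
                         alternative = "two.sided")$p.value
    }
    out[[length(out) + 1]] <- tibble::tibble(test = "paired_t", p_value = p)
  }
  if (length(out) == 0) stop("provide `counts` and/or paired vectors")
  dplyr::bind_rows(out)
}

#' Side-chain RMSD report after backbone superposition
#'
#' Superposes the model onto the reference using the backbone atoms of the
#' residues NOT in `positions`, then reports the heavy-atom side-chain RMSD
#' of each selected position. When the amino acids differ at a compared
#' position the common atoms are compared with a warning.
#'
#' @param model,reference Poses with matching residue numbering.
#' @param positions Tibble with `chain`, `seqpos` of the residues to report.
#' @return Tibble with columns `position`, `aa_model`, `aa_reference`,
#'   `rmsd`, `n_atoms`.
#' @export
rmsd_report <- function(model, reference, positions) {
  sel_keys <- paste0(positions$chain, ":", positions$seqpos)
  frame_keys <- setdiff(reference$keys, sel_keys)
  bb_coords <- function(pose, keys) {
    do.call(rbind, lapply(keys, function(k) {
      r <- pose$residues[[match(k, pose$keys)]]
      r$backbone[c("N", "CA", "C", "O"), ]
    }))
  }
  fit <- superpose_by_mapping(bb_coords(model, frame_keys),
                              bb_coords(reference, frame_keys))
  rows <- lapply(sel_keys, function(k) {
    rm_ <- model$residues[[match(k, model$keys)]]
    rr <- reference$residues[[match(k, reference$keys)]]
    heavy <- function(r) {
      tpl <- sidechain_template(r$aa)
      nm <- tpl$atoms[tpl$elements != "H"]
      if (length(nm) == 0) return(NULL)
      r$sidechain[nm, , drop = FALSE]
    }
    a <- heavy(rm_); b <- heavy(rr)
    if (rm_$aa != rr$aa) {
      warning("residue identity mismatch at ", k, " (", rm_$aa, " vs ", rr$aa,
              "); comparing common atoms")
      common <- intersect(rownames(a), rownames(b))
      a <- a[common, , drop = FALSE]; b <- b[common, , drop = FALSE]
    }
    n <- if (is.null(a)) 0L else nrow(a)
    rmsd <- if (n == 0) NA_real_ else coord_rmsd(fit$transform(a), b)
    tibble::tibble(position = k, aa_model = rm_$aa, aa_reference = rr$aa,
                   rmsd = rmsd, n_atoms = n)
  })
  dplyr::bind_rows(rows)
}
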