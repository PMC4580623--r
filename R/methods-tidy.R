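# Broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a design trace into its per-move ledger
#'
#' @param x A design trace.
#' @param ... Unused.
#' @return The per-move ledger tibble (move, type, position, dE, accepted,
#'   sequence).
#' @export
tidy.cm_design_trace <- function(x, ...) {
  x$ledger
}

#' One-row summary of a design trace
#'
#' @param x A design trace.
#' @param ... Unused.
#' @return Tibble with `n_moves`, `acceptance_ratio`, `n_unique_sequences`,
#'   `best_energy` (over all sequences) and `start_seq`.
#' @export
glance.cm_design_trace <- function(x, ...) {
  tibble::tibble(n_moves = nrow(x$ledger),
                 acceptance_ratio = x$acceptance_ratio,
                 n_unique_sequences = length(x$sequences),
                 best_energy = min(x$best_energy),
                 start_seq = x$start_seq)
}

#' Tidy an energy breakdown into a long term table
#'
#' @param x An energy breakdown from [score_pose()].
#' @param ... Unused.
#' @return Tibble with columns `term` (`one_body`, `two_body`,
#'   `protein_ligand`), `position` and `energy`.
#' @export
tidy.cm_energy_breakdown <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "one_body", position = names(x$one_body),
                   energy = unname(x$one_body)),
    tibble::tibble(term = "two_body", position = names(x$two_body),
                   energy = unname(x$two_body)),
    tibble::tibble(term = "protein_ligand", position = "LIG",
                   energy = x$protein_ligand))
}

#' One-row summary of an energy breakdown
#'
#' @param x An energy breakdown.
#' @param ... Unused.
#' @return Tibble with `total`, `protein_ligand` and the one-/two-body sums.
#' @export
glance.cm_energy_breakdown <- function(x, ...) {
  tibble::tibble(total = x$total, one_body = sum(x$one_body),
                 two_body = sum(x$two_body),
                 protein_ligand = x$protein_ligand)
}

#' Plot a percent-enrichment table
#'
#' Candidates ordered by rank; the enrichment of each candidate mutation,
#' coloured by whether it is a correct (positive-enrichment) prediction.
#'
#' @param object A `cm_enrichment_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_enrichment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mutation <- paste0(df$from_aa, df$position, df$to_aa)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$mutation, .data$rank),
                                   y = .data$PE, fill = .data$correct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "candidate mutation (by rank)",
                  y = "percent enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-position profile similarity against natural entropy
#'
#' @param object A `cm_profile_similarity` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_profile_similarity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$natural_entropy, y = .data$similarity)) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "natural sequence entropy (log20)",
                  y = "profile similarity (1 - JS)") +
    ggplot2::theme_minimal()
}

#' Plot the energy trajectory of a design trace
#'
#' Cumulative energy change over accepted moves.
#'
#' @param object A design trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_design_trace <- function(object, ...) {
  df <- object$ledger
  df$energy <- cumsum(ifelse(df$accepted, df$dE, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$move, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "move", y = "energy change from start") +
    ggplot2::theme_minimal()
}

#' Amino-acid frequency matrix of a sequence set
#'
#' Long-format per-position frequencies suitable for sequence-logo style
#' rendering or export.
#'
#' @param seqs Aligned sequences.
#' @return Tibble with columns `position`, `aa`, `freq`.
#' @export
frequency_matrix <- function(seqs) {
  prof <- build_profiles(seqs)
  dplyr::bind_rows(lapply(seq_len(nrow(prof)), function(i) {
    tibble::tibble(position = prof$position[i], aa = names(prof$p[[i]]),
                   freq = unname(prof$p[[i]]))
  }))
}
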