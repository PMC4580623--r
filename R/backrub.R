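# Backrub backbone moves. A three-residue backrub rotates everything
# strictly between the flanking C-alpha atoms -- C and O of residue i-1, all
# of residue i, and N (with its amide hydrogen) of residue i+1 -- about the
# axis through CA(i-1) and CA(i+1). Two follow-up rotations of the flanking
# peptide groups about their own CA-CA axes minimize the displacement of the
# C=O and N-H groups; both are exact rigid rotations, so covalent geometry
# is preserved to machine precision.

#' Backrub sampling parameters
#'
#' @param sigma_theta Gaussian standard deviation of the rotation angle in
#'   degrees. The default 4.57 is the width fitted to backrub-like motions
#'   observed between alternate conformations in high-resolution crystal
#'   structures.
#' @return Object of class `cm_backrub_params`.
#' @export
backrub_params <- function(sigma_theta = 4.57) {
  if (sigma_theta <= 0) stop("sigma_theta must be > 0")
  structure(list(sigma_theta = sigma_theta), class = "cm_backrub_params")
}

#' Draw a backrub rotation angle
#'
#' theta ~ N(0, sigma_theta^2), in degrees, from R's global random stream
#' (reproducible under set.seed()).
#'
#' @param params A [backrub_params()].
#' @param n Number of draws.
#' @return Numeric vector of angles in degrees.
#' @export
sample_backrub_angle <- function(params = backrub_params(), n = 1L) {
  stats::rnorm(n, mean = 0, sd = params$sigma_theta)
}

#' Construct a backrub move
#'
#' @param pose A pose.
#' @param pivot List/vector with `chain` and `seqpos` of the central residue.
#' @param theta Signed rotation angle in degrees, |theta| < 90.
#' @param corrections Apply the two peptide-bond follow-up rotations.
#' @return Object of class `cm_backrub_move`.
#' @export
backrub_move <- function(pose, pivot, theta, corrections = TRUE) {
  i <- residue_index(pose, pivot[["chain"]], as.integer(pivot[["seqpos"]]))
  if (i == 1L || i == length(pose$residues))
    stop("backrub pivot must have both flanking residues")
  prev <- pose$residues[[i - 1L]]
  nxt <- pose$residues[[i + 1L]]
  r <- pose$residues[[i]]
  if (prev$chain != r$chain || nxt$chain != r$chain ||
      prev$seqpos != r$seqpos - 1L || nxt$seqpos != r$seqpos + 1L)
    stop("backrub pivot must have bonded flanking residues in the same chain")
  if (abs(theta) >= 90) stop("pathological backrub angle |theta| >= 90 degrees")
  axis <- unit_vector(nxt$backbone["CA", ] - prev$backbone["CA", ])
  structure(list(pivot = list(chain = r$chain, seqpos = r$seqpos),
                 theta = theta, axis = axis, corrections = corrections),
            class = "cm_backrub_move")
}

# squared displacement of a peptide group after rotating by ang about
# (origin, axis), relative to reference positions
.peptide_obj <- function(ang, xyz, origin, axis, ref) {
  moved <- rotate_about_axis(xyz, origin, axis, ang)
  sum((moved - ref)^2)
}

#' Apply a backrub move to a pose
#'
#' Rotates the backrub segment about the CA(i-1) -> CA(i+1) axis by theta,
#' then (unless disabled on the move) counter-rotates the two flanking
#' peptide groups about their CA-CA axes by the angles minimizing the summed
#' squared displacement of the C=O and N-H group atoms from their pre-move
#' positions (1-D golden-section minimization to 1e-6 degrees). The flanking
#' C-alpha atoms are exact fixed points and all bond lengths are preserved.
#'
#' @param pose A pose.
#' @param move A [backrub_move()].
#' @return The moved pose, with the two correction angles (degrees) in
#'   attribute `"correction_angles"`.
#' @export
apply_backrub <- function(pose, move) {
  i <- residue_index(pose, move$pivot$chain, move$pivot$seqpos)
  prev <- pose$residues[[i - 1L]]
  r <- pose$residues[[i]]
  nxt <- pose$residues[[i + 1L]]
  origin <- prev$backbone["CA", ]
  axis <- unit_vector(nxt$backbone["CA", ] - origin)
  rot <- function(xyz) rotate_about_axis(xyz, origin, axis, move$theta)
  # pre-move reference positions of the two peptide groups
  pep1_ref <- rbind(prev$backbone["C", ], prev$backbone["O", ], r$backbone["N", ])
  pep2_ref <- rbind(r$backbone["C", ], r$backbone["O", ], nxt$backbone["N", ])
  # primary rotation: C,O of i-1; all of i; N of i+1
  prev$backbone[c("C", "O"), ] <- rot(prev$backbone[c("C", "O"), , drop = FALSE])
  r$backbone <- rot(r$backbone)
  if (!is.null(r$sidechain)) r$sidechain <- rot(r$sidechain)
  nxt$backbone["N", ] <- rot(nxt$backbone["N", , drop = FALSE])
  corr <- c(0, 0)
  if (isTRUE(move$corrections) && abs(move$theta) > 1e-12) {
    # peptide group i-1 -> i rotates about CA(i-1) -> CA(i)
    ax1 <- unit_vector(r$backbone["CA", ] - origin)
    pep1 <- rbind(prev$backbone["C", ], prev$backbone["O", ], r$backbone["N", ])
    o1 <- stats::optimize(.peptide_obj, c(-abs(move$theta) - 5, abs(move$theta) + 5),
                          xyz = pep1, origin = origin, axis = ax1,
                          ref = pep1_ref, tol = 1e-6)
    pep1 <- rotate_about_axis(pep1, origin, ax1, o1$minimum)
    prev$backbone["C", ] <- pep1[1, ]; prev$backbone["O", ] <- pep1[2, ]
    r$backbone["N", ] <- pep1[3, ]
    # peptide group i -> i+1 rotates about CA(i) -> CA(i+1)
    o2_origin <- r$backbone["CA", ]
    ax2 <- unit_vector(nxt$backbone["CA", ] - o2_origin)
    pep2 <- rbind(r$backbone["C", ], r$backbone["O", ], nxt$backbone["N", ])
    o2 <- stats::optimize(.peptide_obj, c(-abs(move$theta) - 5, abs(move$theta) + 5),
                          xyz = pep2, origin = o2_origin, axis = ax2,
                          ref = pep2_ref, tol = 1e-6)
    pep2 <- rotate_about_axis(pep2, o2_origin, ax2, o2$minimum)
    r$backbone["C", ] <- pep2[1, ]; r$backbone["O", ] <- pep2[2, ]
    nxt$backbone["N", ] <- pep2[3, ]
    corr <- c(o1$minimum, o2$minimum)
  }
  # the corrections move N(i) and C(i) but not the side chains, so the
  # chi values measured against the backbone shift slightly; re-measure
  for (res in list(prev, r, nxt)) {
    if (length(res$chis) > 0) {
      res$chis <- extract_chis(res$aa, res$backbone, res$sidechain)
    }
    pose$residues[[residue_index(pose, res$chain, res$seqpos)]] <- res
  }
  attr(pose, "correction_angles") <- corr
  pose
}

#' Measure backrub-like angles from alternate-location coordinates
#'
#' Scans every three-residue window of the raw atom table for C-alpha atoms
#' with two alternate locations. Windows where the central C-alpha moves by
#' more than `d_center` while both flanking C-alphas move by less than
#' `d_flank` are interpreted as backrub-like motions; the reported angle is
#' the signed rotation about the CA(i-1) -> CA(i+1) axis that best maps the
#' first altloc of the central C-alpha onto the second (projected-angle
#' computation).
#'
#' @param pose A pose whose `$atoms` table retains altloc records (as read
#'   by [read_pdb()]).
#' @param d_center Minimum central C-alpha displacement (Angstrom).
#' @param d_flank Maximum flanking C-alpha displacement (Angstrom).
#' @return Tibble with columns `chain`, `seqpos`, `theta` (degrees); zero
#'   rows when the pose has no alternate locations.
#' @export
measure_altloc_backrub_angles <- function(pose, d_center = 0.2, d_flank = 0.2) {
  empty <- tibble::tibble(chain = character(0), seqpos = integer(0),
                          theta = numeric(0))
  at <- pose$atoms
  if (is.null(at)) return(empty)
  ca <- at[at$name == "CA" & at$type == "ATOM", ]
  if (nrow(ca) == 0 || all(ca$altloc %in% "")) return(empty)
  # per-residue A/B C-alpha positions (single-altloc atoms count as both)
  ca_ab <- function(chain, seqpos) {
    rows <- ca[ca$chain == chain & ca$seqpos == seqpos, ]
    if (nrow(rows) == 0) return(NULL)
    a <- rows[rows$altloc %in% c("", "A"), ][1, ]
    b_rows <- rows[rows$altloc == "B", ]
    b <- if (nrow(b_rows) > 0) b_rows[1, ] else a
    if (any(is.na(a$x))) return(NULL)
    list(A = c(a$x, a$y, a$z), B = c(b$x, b$y, b$z))
  }
  out <- empty
  keys <- unique(ca[, c("chain", "seqpos")])
  for (k in seq_len(nrow(keys))) {
    ch <- keys$chain[k]; sp <- keys$seqpos[k]
    ctr <- ca_ab(ch, sp)
    lo <- ca_ab(ch, sp - 1L)
    hi <- ca_ab(ch, sp + 1L)
    if (is.null(ctr) || is.null(lo) || is.null(hi)) next
    if (vnorm(ctr$A - ctr$B) <= d_center) next
    if (vnorm(lo$A - lo$B) >= d_flank || vnorm(hi$A - hi$B) >= d_flank) next
    axis <- unit_vector(hi$A - lo$A)
    p1 <- ctr$A - lo$A; p2 <- ctr$B - lo$A
    p1 <- p1 - sum(p1 * axis) * axis
    p2 <- p2 - sum(p2 * axis) * axis
    if (vnorm(p1) < 1e-9 || vnorm(p2) < 1e-9) next
    theta <- atan2(sum(cross3(p1, p2) * axis), sum(p1 * p2)) * .rad2deg
    out <- dplyr::bind_rows(out, tibble::tibble(chain = ch, seqpos = sp,
                                                theta = theta))
  }
  out
}
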