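par0 <- coupledmoves:::kernel_params(energy_config())

set1 <- function(xyz, el = "C", hb = -1L, acc = 0L) {
  xyz <- matrix(xyz, ncol = 3)
  list(xyz = xyz, rad = coupledmoves:::lj_radius(rep(el, nrow(xyz))),
       eps = coupledmoves:::lj_eps(rep(el, nrow(xyz))),
       hb = rep(as.integer(hb), nrow(xyz)), acc = rep(as.integer(acc), nrow(xyz)))
}

pair_comp <- function(s1, s2) {
  coupledmoves:::cpp_score_sets(s1$xyz, s1$rad, s1$eps, s1$hb, s1$acc,
                                s2$xyz, s2$rad, s2$eps, s2$hb, s2$acc,
                                numeric(0), matrix(0L, 0, 2), par0)
}

test_that("the Lennard-Jones well depth is exact at the pair minimum", {
  sigma <- 2 * coupledmoves:::lj_radius("C")
  eps <- coupledmoves:::lj_eps("C")
  comp <- pair_comp(set1(c(0, 0, 0)), set1(c(sigma, 0, 0)))
  expect_equal(unname(comp[["attr"]] + comp[["rep"]]), -eps, tolerance = 1e-12)
  expect_equal(unname(comp[["rep"]]), 0, tolerance = 1e-12)
})

test_that("overlapping atoms stay finite under the linearized repulsion", {
  comp <- pair_comp(set1(c(0, 0, 0)), set1(c(1e-9, 0, 0)))
  expect_true(all(is.finite(comp)))
  expect_gt(comp[["rep"]], 100)
})

test_that("an ideal linear hydrogen bond at optimum distance scores -well depth", {
  # donor D at origin with H on the x axis, acceptor A collinear at d0
  d0 <- energy_config()$hb_d0
  donor <- list(xyz = rbind(c(0, 0, 0), c(0.96, 0, 0)),
                rad = c(1.5, 0.9), eps = c(0.16, 0.02),
                hb = c(-1L, 0L), acc = c(0L, 0L))
  accpt <- set1(c(d0, 0, 0), el = "O", acc = 1L)
  comp <- pair_comp(donor, accpt)
  expect_equal(unname(comp[["hb"]]), -energy_config()$hb_depth, tolerance = 1e-12)
  # bent geometry scores less
  accpt_bent <- set1(c(d0 / sqrt(2), d0 / sqrt(2), 0), el = "O", acc = 1L)
  comp_bent <- pair_comp(donor, accpt_bent)
  expect_gt(comp_bent[["hb"]], comp[["hb"]])
  # outside the distance window there is no hydrogen bond
  accpt_far <- set1(c(3.5, 0, 0), el = "O", acc = 1L)
  expect_equal(unname(pair_comp(donor, accpt_far)[["hb"]]), 0)
})

test_that("the decomposition identity and ligand-weight linearity hold exactly", {
  fix <- fx_toy()
  b1 <- score_pose(fix$pose, energy_config(w_lig = 1, hb_depth = 6))
  expect_equal(b1$total,
               sum(b1$one_body) + sum(b1$two_body) + 1 * b1$protein_ligand,
               tolerance = 1e-8)
  b2 <- score_pose(fix$pose, energy_config(w_lig = 2, hb_depth = 6))
  expect_equal(b2$total - b1$total, b1$protein_ligand, tolerance = 1e-8)
  expect_equal(b2$protein_ligand, b1$protein_ligand, tolerance = 1e-10)
  expect_error(energy_config(w_lig = 0), "w_lig")
})

test_that("the total energy is invariant under rigid transforms of the whole pose", {
  fix <- fx_toy()
  pose <- fix$pose
  e0 <- score_pose(pose, fix$config)$total
  R <- coupledmoves:::rotation_matrix(c(1, 2, 3), 37)
  t0 <- c(5, -3, 11)
  moved <- pose
  for (i in seq_along(moved$residues)) {
    r <- moved$residues[[i]]
    r$backbone <- sweep(r$backbone %*% t(R), 2, t0, FUN = "+")
    if (!is.null(r$sidechain))
      r$sidechain <- sweep(r$sidechain %*% t(R), 2, t0, FUN = "+")
    moved$residues[[i]] <- r
  }
  lig <- moved$ligand
  lig$frame <- list(R = R %*% lig$frame$R,
                    t = as.numeric(R %*% lig$frame$t) + t0)
  moved$ligand <- lig
  expect_equal(score_pose(moved, fix$config)$total, e0, tolerance = 1e-8)
})

test_that("incremental deltas equal full rescoring and are antisymmetric", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  pose <- fix$pose
  cfg <- fix$config
  set.seed(71)
  rotset <- get_rotamers(pose, list(chain = "A", seqpos = 5),
                         allowed_aas = c("A", "S", "V", "L"))
  for (k in sample(nrow(rotset), 5)) {
    ch <- list(type = "rotamer", position = list(chain = "A", seqpos = 5),
               rotamer = rotset[k, ])
    dE <- delta_energy(pose, ch, cfg)
    after <- attr(dE, "pose")
    full <- score_pose(after, cfg)$total - score_pose(pose, cfg)$total
    expect_equal(as.numeric(dE), full, tolerance = 1e-6)
    # reverting is exactly antisymmetric
    r0 <- pose$residues[[5]]
    back <- list(type = "rotamer", position = list(chain = "A", seqpos = 5),
                 rotamer = list(aa = r0$aa, chis = list(r0$chis),
                                proton_chi = r0$proton_chi, prob = r0$rot_prob))
    dE_rev <- delta_energy(after, back, cfg)
    expect_equal(as.numeric(dE), -as.numeric(dE_rev), tolerance = 1e-8)
  }
  # null change is exactly zero
  r0 <- pose$residues[[5]]
  null_ch <- list(type = "rotamer", position = list(chain = "A", seqpos = 5),
                  rotamer = list(aa = r0$aa, chis = list(r0$chis),
                                 proton_chi = r0$proton_chi, prob = r0$rot_prob))
  expect_equal(as.numeric(delta_energy(pose, null_ch, cfg)), 0, tolerance = 1e-9)
})

test_that("backrub and ligand deltas match full rescoring", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  pose <- fix$pose; cfg <- fix$config
  mv <- backrub_move(pose, list(chain = "A", seqpos = 4), 3.7)
  dE <- delta_energy(pose, list(type = "backrub", move = mv), cfg)
  expect_equal(as.numeric(dE),
               score_pose(attr(dE, "pose"), cfg)$total - score_pose(pose, cfg)$total,
               tolerance = 1e-6)
  fr <- coupledmoves:::compose_frame(
    pose$ligand$frame, coupledmoves:::rotation_matrix(c(0, 1, 0), 1.4),
    c(0.04, -0.02, 0.05), colMeans(ligand_coords(pose$ligand)))
  dE2 <- delta_energy(pose, list(type = "ligand", frame = fr, conformer = 1L), cfg)
  expect_equal(as.numeric(dE2),
               score_pose(attr(dE2, "pose"), cfg)$total - score_pose(pose, cfg)$total,
               tolerance = 1e-6)
})
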