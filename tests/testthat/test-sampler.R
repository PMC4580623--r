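test_that("Boltzmann selection matches closed forms and never overflows", {
  set.seed(81)
  expect_equal(boltzmann_select(c(0, 0), 0.6)$probs, c(0.5, 0.5))
  # energies [0, 0.6 ln 2] at kT 0.6 give exactly [2/3, 1/3]
  p <- boltzmann_select(c(0, 0.6 * log(2)), 0.6)$probs
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # extreme energies: no overflow, certain selection
  p2 <- boltzmann_select(c(0, 1e9), 0.6)$probs
  expect_equal(p2, c(1, 0))
  expect_error(boltzmann_select(numeric(0), 0.6), "empty")
  expect_error(boltzmann_select(c(0, Inf), 0.6), "finite")
})

test_that("Metropolis acceptance matches its closed form", {
  set.seed(82)
  expect_true(all(replicate(50, metropolis_accept(-5, 0.6))))
  n <- 1e4
  acc <- mean(replicate(n, metropolis_accept(0.6 * log(2), 0.6)))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
  expect_false(any(replicate(200, metropolis_accept(1e6, 0.6))))
  expect_error(metropolis_accept(NaN, 0.6), "finite")
})

test_that("repack-only moves keep the amino-acid identity", {
  fix <- fx_toy()
  task <- design_task(repack = tibble::tibble(chain = "A", seqpos = 5L),
                      pose = fix$pose)
  set.seed(83)
  for (k in 1:10) {
    prop <- coupled_protein_move(fix$pose, task, energy = fix$config)
    expect_equal(prop$aa_to, fix$pose$residues[[5]]$aa)
  }
})

test_that("strongly clashing amino acids are essentially never selected", {
  # analytic bound: with dE = +50 at kT 0.6 the Boltzmann weight is
  # exp(-50/0.6) ~ 1e-37, far below any sampling resolution
  p <- boltzmann_select(c(0, 50), 0.6)$probs
  expect_lt(p[2], 1e-10)
  fix <- fx_crowded()
  set.seed(84)
  task <- design_task(design = tibble::tibble(chain = "A", seqpos = 5L,
                                              allowed = list(c("A", "W"))),
                      pose = fix$pose)
  picks <- replicate(50, {
    prop <- coupled_protein_move(fix$pose, task, energy = fix$config,
                                 config = sampler_config(backbone = "fixed"))
    prop$aa_to
  })
  expect_false("W" %in% picks)  # tryptophan clashes into the dumbbell pocket
})

test_that("selection frequencies on a fixed backbone match the analytic Boltzmann law", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  task <- design_task(design = tibble::tibble(chain = "A", seqpos = 5L,
                                              allowed = list(c("A", "G"))),
                      pose = fix$pose)
  # analytic two-stage probabilities from the candidate energies
  rotset <- get_rotamers(fix$pose, list(chain = "A", seqpos = 5),
                         allowed_aas = c("A", "G"))
  E <- coupledmoves:::candidate_energies(fix$pose, 5L, rotset, fix$config)
  E_rel <- E - E[rotset$current][1]
  aas <- unique(rotset$aa)
  winner_E <- vapply(aas, function(a) min(E_rel[rotset$aa == a]), numeric(1))
  # single-rotamer groups make stage one deterministic, so stage two is the
  # plain Boltzmann distribution over the per-amino-acid energies
  p_aa <- exp(-winner_E / 0.6) / sum(exp(-winner_E / 0.6))
  set.seed(85)
  n <- 400
  picks <- replicate(n, coupled_protein_move(
    fix$pose, task, energy = fix$config,
    config = sampler_config(backbone = "fixed"))$aa_to)
  for (k in seq_along(aas)) {
    phat <- mean(picks == aas[k])
    expect_lt(abs(phat - p_aa[k]), 3 * sqrt(p_aa[k] * (1 - p_aa[k]) / n) + 1e-9)
  }
})

test_that("ligand moves follow the configured perturbation widths", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  pose <- fix$pose
  # zero-width perturbation with one conformer is the identity proposal
  set.seed(86)
  prop <- coupled_ligand_move(pose, fix$config,
                              sampler_config(sigma_rot = 0, sigma_trans = 0))
  expect_equal(as.numeric(prop$dE), 0, tolerance = 1e-9)
  expect_lt(max(abs(ligand_coords(prop$pose$ligand) - ligand_coords(pose$ligand))),
            1e-9)
  # translation displacement standard deviation matches sigma_trans
  set.seed(87)
  n <- 2000
  disp <- replicate(n, {
    p <- coupled_ligand_move(pose, fix$config,
                             sampler_config(sigma_rot = 0, sigma_trans = 0.1))
    sqrt(sum((colMeans(ligand_coords(p$pose$ligand)) -
                colMeans(ligand_coords(pose$ligand)))^2))
  })
  # |displacement| of an isotropic Gaussian with total sd 0.1: E|X|^2 = 0.01
  expect_lt(abs(sqrt(mean(disp^2)) - 0.1), 0.01)
  expect_error(coupled_ligand_move(fx_helix("AALSAVKDA"), fix$config),
               "no ligand")
})

test_that("conformer selection is Boltzmann over interaction energies", {
  # two-conformer ligand with a large energy split: the bad conformer is
  # chosen with frequency exp(-dE/kT)/(1+exp(-dE/kT))
  fix <- fx_toy("hbond-probe", target_aa = "S")
  pose <- fix$pose
  lig <- pose$ligand
  shifted <- lig$conformers[[1]]
  shifted[1, ] <- shifted[1, ] + c(8, 0, 0)  # breaks all contacts
  lig$conformers <- list(lig$conformers[[1]], shifted)
  pose$ligand <- lig
  E <- coupledmoves:::.ligand_conformer_energies(pose, lig$frame, fix$config)
  expect_equal(length(E), 2L)
  set.seed(88)
  picks <- replicate(300, coupled_ligand_move(
    pose, fix$config, sampler_config(sigma_rot = 0, sigma_trans = 0))$conformer)
  p2 <- exp(-(E[2] - E[1]) / 0.6) / (1 + exp(-(E[2] - E[1]) / 0.6))
  expect_lt(abs(mean(picks == 2L) - p2), 3 * sqrt(max(p2 * (1 - p2), 1e-4) / 300))
})

test_that("a task with no design positions never changes the sequence", {
  fix <- fx_toy()
  task <- design_task(repack = tibble::tibble(chain = "A", seqpos = c(4L, 5L)),
                      pose = fix$pose)
  tr <- run_coupled_moves(fix$pose, task, energy = fix$config,
                          config = sampler_config(n_moves = 40, seed = 3))
  expect_equal(length(tr$sequences), 1L)
})

test_that("traces are bit-reproducible under a fixed seed", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  cfg <- sampler_config(n_moves = 60, seed = 17)
  tr1 <- run_coupled_moves(fix$pose, fix$task, energy = fix$config, config = cfg)
  tr2 <- run_coupled_moves(fix$pose, fix$task, energy = fix$config, config = cfg)
  expect_identical(tr1$ledger, tr2$ledger)
  expect_identical(tr1$sequences, tr2$sequences)
  pk1 <- run_fixed_backbone_design(fix$pose, fix$task, energy = fix$config,
                                   config = cfg)
  pk2 <- run_fixed_backbone_design(fix$pose, fix$task, energy = fix$config,
                                   config = cfg)
  expect_identical(pk1$ledger, pk2$ledger)
})

test_that("incremental energy bookkeeping matches a full rescore after a run", {
  fix <- fx_crowded()
  tr <- run_coupled_moves(fix$pose, fix$task, energy = fix$config,
                          config = sampler_config(n_moves = 80, seed = 23))
  expect_equal(tr$final_energy, score_pose(tr$final_pose, fix$config)$total,
               tolerance = 1e-8)
})

test_that("a ligand-free pose runs as a pure protein simulation", {
  pose <- fx_helix("AALSAVKDA")
  task <- design_task(design = tibble::tibble(chain = "A", seqpos = 5L,
                                              allowed = list(c("A", "V", "S"))),
                      pose = pose)
  tr <- run_coupled_moves(pose, task, config = sampler_config(n_moves = 40,
                                                              seed = 5,
                                                              p_ligand = 0.5))
  expect_false(any(tr$ledger$type == "ligand"))
  expect_true(all(tr$ledger$type == "protein"))
})

test_that("the fixed-backbone packer freezes the backbone and cools greedily", {
  fix <- fx_crowded()
  tr <- run_fixed_backbone_design(fix$pose, fix$task, energy = fix$config,
                                  config = sampler_config(n_moves = 100, seed = 9))
  expect_equal(max_backbone_displacement(tr$final_pose, fix$pose), 0)
  expect_lt(max(abs(ligand_coords(tr$final_pose$ligand) -
                      ligand_coords(fix$pose$ligand))), 1e-12)
  # near-zero-temperature schedule on a single position is a deterministic
  # greedy descent to the minimum-energy amino acid
  task1 <- design_task(design = tibble::tibble(chain = "A", seqpos = 5L,
                                               allowed = list(c("A", "L", "V"))),
                       pose = fix$pose)
  rotset <- get_rotamers(fix$pose, list(chain = "A", seqpos = 5),
                         allowed_aas = c("A", "L", "V"))
  E <- coupledmoves:::candidate_energies(fix$pose, 5L, rotset, fix$config)
  best_aa <- rotset$aa[which.min(E)]
  for (s in 1:3) {
    trg <- run_fixed_backbone_design(
      fix$pose, task1, energy = fix$config,
      config = sampler_config(n_moves = 120, seed = 30 + s),
      schedule = rep(1e-6, 8))
    expect_equal(names(which.min(trg$best_energy)), best_aa)
  }
})

test_that("pooling sequences de-duplicates across traces and checks positions", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  trs <- lapply(1:3, function(s) run_coupled_moves(
    fix$pose, fix$task, energy = fix$config,
    config = sampler_config(n_moves = 50, seed = 40 + s), keep_poses = FALSE))
  pooled <- pool_sequences(trs)
  all_seqs <- unlist(lapply(trs, `[[`, "sequences"))
  expect_identical(as.character(pooled), unique(all_seqs))
  expect_identical(attr(pooled, "wt"), trs[[1]]$start_seq)
  # single trace: unchanged unique list
  expect_identical(as.character(pool_sequences(trs[1])), trs[[1]]$sequences)
  # inconsistent design positions are an error
  other_task <- design_task(design = tibble::tibble(chain = "A", seqpos = 4L),
                            pose = fix$pose)
  tr_other <- run_coupled_moves(fix$pose, other_task, energy = fix$config,
                                config = sampler_config(n_moves = 10, seed = 1),
                                keep_poses = FALSE)
  expect_error(pool_sequences(list(trs[[1]], tr_other)), "inconsistent")
  # FASTA round trip
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sequence_fasta(pooled, path)
  expect_identical(unname(read_sequence_fasta(path)), as.character(pooled))
})

test_that("tidy, glance and autoplot work on traces and breakdowns", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  tr <- run_coupled_moves(fix$pose, fix$task, energy = fix$config,
                          config = sampler_config(n_moves = 30, seed = 2))
  td <- generics::tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 30L)
  gl <- generics::glance(tr)
  expect_equal(gl$acceptance_ratio, tr$acceptance_ratio)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  bd <- score_pose(fix$pose, fix$config)
  expect_s3_class(generics::tidy(bd), "tbl_df")
  expect_equal(generics::glance(bd)$total, bd$total)
})
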