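test_that("toy complexes are seed-deterministic down to the written PDB", {
  a <- make_toy_complex(toy_complex_spec(seed = 4))
  b <- make_toy_complex(toy_complex_spec(seed = 4))
  fa <- withr::local_tempfile(fileext = ".pdb")
  fb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(a$pose, fa); write_pdb(b$pose, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$notes, b$notes)
})

test_that("the dumbbell fixture opens the engineered gap to the target mutation", {
  fix <- fx_toy("two-atom-dumbbell", target_aa = "A")
  e <- stats::setNames(fix$notes$E_best, fix$notes$aa)
  # brute-force enumeration: the target relieves the wild-type clash
  expect_lt(e[["A"]] - e[["L"]], -3)
  expect_lt(e[["A"]], 1)
})

test_that("the hydrogen-bond fixture makes the target the global winner", {
  fix <- fx_toy("hbond-probe", target_aa = "S")
  e <- stats::setNames(fix$notes$E_best, fix$notes$aa)
  others <- e[names(e) != "S"]
  expect_true(all(others - e[["S"]] >= 3))
})

test_that("a far-away probe produces no mutational signal", {
  near <- make_toy_complex(toy_complex_spec(ligand_shape = "sphere-probe",
                                            seed = 2))
  far <- make_toy_complex(toy_complex_spec(ligand_shape = "sphere-probe",
                                           offset = 30, seed = 2))
  # with the probe 30 A out, every candidate's energy equals its no-ligand
  # baseline; compare against an explicit ligand-free enumeration
  baseline <- near
  baseline$pose$ligand <- NULL
  nt <- coupledmoves:::.enumerate_best(baseline$pose, 5L,
                                       far$spec$candidate_aas, far$config)
  expect_lt(max(abs(far$notes$E_best - nt$E_best)), 0.1)
})

test_that("an unachievable fixture gap fails loudly", {
  # demanding an enormous gap cannot be satisfied by any placement
  expect_error(make_toy_complex(toy_complex_spec(min_gap = 500)), "failed")
})

test_that("discrete landscapes reproduce closed-form occupancies", {
  ls <- make_discrete_landscape(c(0, 0.6 * log(3)))
  r <- run_landscape(ls, kT = 0.6, n_moves = 2e4, proposal = "boltzmann",
                     acceptance = "hastings", seed = 51)
  se <- sqrt(0.75 * 0.25 / 2e4)
  expect_lt(abs(r$occupancy[1] - 0.75), 3 * se)
  # uniform proposals with Metropolis target the same Boltzmann distribution
  r2 <- run_landscape(ls, kT = 0.6, n_moves = 4e4, proposal = "uniform",
                      acceptance = "metropolis", seed = 52)
  expect_lt(abs(r2$occupancy[1] - 0.75), 6 * se)
  # single state: the chain never moves
  r1 <- run_landscape(make_discrete_landscape(0), n_moves = 100, seed = 53)
  expect_equal(r1$occupancy, 1)
  # permuting the states permutes the occupancy
  ls3 <- make_discrete_landscape(c(0.6 * log(3), 0))
  r3 <- run_landscape(ls3, kT = 0.6, n_moves = 2e4, proposal = "boltzmann",
                      acceptance = "hastings", seed = 51)
  expect_lt(abs(r3$occupancy[2] - 0.75), 3 * se)
})

test_that("plain Metropolis after Boltzmann selection over-occupies the ground state", {
  # the design protocol's chain double-counts the energy bias: on the
  # two-state landscape its stationary distribution is [0.9, 0.1], not the
  # Boltzmann [0.75, 0.25] (detailed-balance calculation in the vignette)
  ls <- make_discrete_landscape(c(0, 0.6 * log(3)))
  r <- run_landscape(ls, kT = 0.6, n_moves = 4e4, proposal = "boltzmann",
                     acceptance = "metropolis", seed = 54)
  expect_lt(abs(r$occupancy[1] - 0.9), 0.01)
})

test_that("synthetic alignments converge to their target profiles", {
  # point-mass profiles give identical sequences
  msa0 <- make_natural_msa(list(c(L = 1), c(A = 1)), 20, seed = 55)
  expect_true(all(msa0 == "LA"))
  # a uniform-over-two column matches 0.5 within 3 sigma
  n <- 1e4
  msa <- make_natural_msa(list(c(A = 0.5, V = 0.5)), n, seed = 56)
  phat <- mean(substr(msa, 1, 1) == "A")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
  # consistency: recovered profiles approach the target as n grows
  target <- c(A = 0.5, S = 0.3, V = 0.2)
  msa2 <- make_natural_msa(list(target, target), 5000, seed = 57)
  prof <- build_profiles(msa2)
  tvec <- stats::setNames(rep(0, 20), AA1)
  tvec[names(target)] <- target
  expect_gt(profile_similarity(prof$p[[1]], tvec), 0.995)
})

test_that("the crowded fixture and specificity pair build and self-validate", {
  fix <- fx_crowded()
  expect_equal(nrow(fix$task$design), 3L)
  expect_true(all(vapply(fix$task$design$allowed, length, integer(1)) == 20L))
  pair <- fx_pair()
  expect_identical(pair$target$to_aa, "S")
  # the non-native complex drives the target; the native complex does not
  e_nat <- stats::setNames(pair$native$notes$E_best, pair$native$notes$aa)
  e_non <- stats::setNames(pair$nonnative$notes$E_best, pair$nonnative$notes$aa)
  expect_lt(e_non[["S"]] - e_nat[["S"]], -2)
})
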