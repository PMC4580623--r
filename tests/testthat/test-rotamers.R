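test_that("chi-less residues get a single library rotamer plus the current state", {
  pose <- fx_helix("AALSAVKDA")
  rs <- get_rotamers(pose, list(chain = "A", seqpos = 1), allowed_aas = "A")
  expect_equal(nrow(rs), 2L)
  expect_equal(sum(rs$current), 1L)
  expect_equal(length(rs$chis[[1]]), 0L)
})

test_that("leucine at helical backbone has several rotamers with descending probabilities", {
  pose <- fx_helix("AALSAVKDA")
  rs <- get_rotamers(pose, list(chain = "A", seqpos = 3), allowed_aas = "L")
  lib <- rs[!rs$current, ]
  expect_gte(nrow(lib), 3L)
  expect_true(all(diff(lib$prob) <= 1e-12))
  expect_lte(sum(lib$prob), 1)
  expect_true(all(lib$prob > 0))
  expect_true(all(vapply(lib$chis, length, integer(1)) == 2L))
})

test_that("rotamer lookup is pure: repeated queries return identical sets", {
  pose <- fx_helix("AALSAVKDA")
  pos <- list(chain = "A", seqpos = 6)
  a <- get_rotamers(pose, pos, allowed_aas = c("V", "S", "F"))
  b <- get_rotamers(pose, pos, allowed_aas = c("V", "S", "F"))
  expect_identical(a, b)
})

test_that("hydroxyl amino acids expand three proton-chi positions per rotamer", {
  pose <- fx_helix("AALSAVKDA")
  rs <- get_rotamers(pose, list(chain = "A", seqpos = 4), allowed_aas = "S")
  lib <- rs[!rs$current, ]
  expect_equal(nrow(lib) %% 3, 0L)
  expect_setequal(unique(lib$proton_chi), c(-60, 60, 180))
})

test_that("building a rotamer equal to the current chis is idempotent", {
  pose <- fx_helix("AALSAVKDA")
  r <- pose$residues[[3]]
  rebuilt <- build_sidechain(pose, list(chain = "A", seqpos = 3),
                             list(aa = r$aa, chis = list(r$chis),
                                  proton_chi = r$proton_chi, prob = r$rot_prob))
  expect_lt(max(abs(rebuilt$residues[[3]]$sidechain - r$sidechain)), 1e-4)
})

test_that("mutations realize the expected atom sets and leave the backbone untouched", {
  pose <- fx_helix("AALSAVKDA")
  pos <- list(chain = "A", seqpos = 3)
  to_ala <- build_sidechain(pose, pos, list(aa = "A", chis = list(numeric(0)),
                                            proton_chi = 180, prob = 1))
  expect_identical(rownames(to_ala$residues[[3]]$sidechain), "CB")
  # G -> W -> G keeps the backbone bit-identical
  pose_g <- build_sidechain(pose, pos, list(aa = "G", chis = list(numeric(0)),
                                            proton_chi = 180, prob = 1))
  rs <- get_rotamers(pose_g, pos, allowed_aas = "W")
  pose_w <- build_sidechain(pose_g, pos, rs[1, ])
  pose_g2 <- build_sidechain(pose_w, pos, list(aa = "G", chis = list(numeric(0)),
                                               proton_chi = 180, prob = 1))
  expect_identical(pose_g2$residues[[3]]$backbone, pose$residues[[3]]$backbone)
  expect_null(pose_g2$residues[[3]]$sidechain)
  expect_error(get_rotamers(pose, pos, allowed_aas = character(0)), "nonempty")
})

test_that("the TSV library format round-trips and falls back to the nearest bin", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "AA PHI_BIN PSI_BIN PROB CHI1 CHI2 CHI3 CHI4",
    "L -60 -50 0.6 -65 175 NA NA",
    "L -60 -50 0.3 -170 65 NA NA",
    "S -60 -50 0.8 62 NA NA NA"), path)
  lib <- read_rotamer_library(path)
  rot <- lib$lookup("L", -60, -50)
  expect_equal(nrow(rot), 2L)
  expect_equal(rot$prob, c(0.6, 0.3))
  expect_equal(rot$chis[[1]], c(-65, 175))
  # nearest-bin fallback
  far <- lib$lookup("L", 100, 100)
  expect_equal(far$prob, c(0.6, 0.3))
  expect_error(lib$lookup("W", -60, -50), "no rotamers")
  # usable end-to-end
  pose <- fx_helix("AALSAVKDA")
  rs <- get_rotamers(pose, list(chain = "A", seqpos = 3),
                     allowed_aas = "L", library = lib)
  expect_equal(sort(unique(rs$current)), c(FALSE, TRUE))
})

test_that("the standard backbone-dependent text format can be read", {
  path <- withr::local_tempfile(fileext = ".lib")
  writeLines(c(
    "# residue phi psi count r1 r2 r3 r4 prob chi1 chi2 chi3 chi4 sd1 sd2 sd3 sd4",
    "LEU -60 -50 1000 2 2 0 0 0.55 -64.3 176.2 0 0 7 8 0 0",
    "LEU -60 -50 1000 1 2 0 0 0.30 -177.1 63.2 0 0 7 8 0 0",
    "LEU -60 -50 1000 2 1 0 0 0.005 55.0 80.0 0 0 7 8 0 0"), path)
  lib <- read_dunbrack_library(path)
  rot <- lib$lookup("L", -60, -50)
  expect_equal(nrow(rot), 2L)  # the 0.5% rotamer is dropped
  expect_equal(rot$chis[[1]], c(-64.3, 176.2))
})

test_that("ligand conformers behave as a uniform-prior rotamer set", {
  cs <- ligand_conformer_set(new_ligand(
    tibble::tibble(name = "C1", element = "C"), NULL,
    list(matrix(0, 1, 3))))
  expect_equal(cs$prob, 1)
  set.seed(61)
  # equal energies: selection frequencies are uniform within 3 sigma
  n <- 1e4
  draws <- replicate(n, boltzmann_select(rep(0, 5), 0.6)$index)
  freq <- tabulate(draws, 5) / n
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / n)))
  # permuting the conformer order permutes, but does not change, the
  # selection distribution
  E <- c(0, 0.3, 0.9)
  p1 <- boltzmann_select(E, 0.6)$probs
  p2 <- boltzmann_select(E[c(3, 1, 2)], 0.6)$probs
  expect_equal(p1, p2[c(2, 3, 1)], tolerance = 1e-12)
})

test_that("the packaged synthetic example table loads through the TSV reader", {
  path <- system.file("extdata", "rotamer_library_synthetic_example.tsv",
                      package = "coupledmoves")
  lib <- read_rotamer_library(path)
  rot <- lib$lookup("L", -60, -50)
  expect_equal(nrow(rot), 3L)
  expect_equal(rot$prob[1], 0.50)
  expect_equal(rot$chis[[1]], c(-65.2, 176.1))
})
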