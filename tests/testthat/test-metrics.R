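test_that("percent enrichment follows its defining arithmetic", {
  # the S mutation at position 1 is in 80% of non-native and 20% of native
  # unique sequences
  native <- c(paste0("A", c("A", "C", "D", "E", "F", "G", "H", "I")),
              paste0("S", c("A", "C")))
  nonnat <- c(paste0("A", c("A", "C")),
              paste0("S", c("A", "C", "D", "E", "F", "G", "H", "I")))
  et <- enrichment_analysis(native, nonnat, "wt2mut", wt = "AA")
  s1 <- et[et$position == "1" & et$to_aa == "S", ]
  expect_equal(s1$pct_native, 20)
  expect_equal(s1$pct_nonnative, 80)
  expect_equal(s1$PE, 60)
  expect_true(s1$correct)
  expect_equal(s1$rank, 1L)
  expect_equal(s1$percentile, 100)
})

test_that("identical sequence sets give zero enrichment and no correct calls", {
  seqs <- c("AV", "SV", "AT", "ST")
  et <- enrichment_analysis(seqs, seqs, "wt2mut", wt = "AV")
  expect_true(all(et$PE == 0))
  expect_false(any(et$correct))
})

test_that("the two enrichment directions are exactly antisymmetric", {
  set.seed(91)
  mk <- function(n) {
    unique(replicate(n, paste0(sample(c("A", "S", "V"), 3, replace = TRUE),
                               collapse = "")))
  }
  a <- mk(30); b <- mk(30)
  e1 <- enrichment_analysis(a, b, "wt2mut", wt = "AAA")
  e2 <- enrichment_analysis(a, b, "mut2wt", wt = "AAA")
  key <- function(e) paste(e$position, e$to_aa)
  m <- match(key(e1), key(e2))
  expect_equal(e1$PE, -e2$PE[m])
  # swapping the set arguments also flips the sign
  e3 <- enrichment_analysis(b, a, "wt2mut", wt = "AAA")
  m3 <- match(key(e1), key(e3))
  expect_equal(e1$PE, -e3$PE[m3])
})

test_that("ranks are a permutation and percentiles decrease with rank", {
  set.seed(92)
  a <- unique(replicate(40, paste0(sample(c("A", "S", "V", "L"), 3,
                                          replace = TRUE), collapse = "")))
  b <- unique(replicate(40, paste0(sample(c("A", "S", "V", "G"), 3,
                                          replace = TRUE), collapse = "")))
  et <- enrichment_analysis(a, b, "wt2mut", wt = "AAA")
  expect_setequal(et$rank, seq_len(nrow(et)))
  ord <- order(et$rank)
  expect_true(all(diff(et$percentile[ord]) < 0))
  expect_true(all(et$percentile > 0 & et$percentile <= 100))
  expect_error(enrichment_analysis(character(0), a, wt = "AAA"), "empty")
})

test_that("profiles are normalized frequencies with pseudocount support", {
  p1 <- build_profiles(rep("AL", 10))
  expect_equal(unname(p1$p[[1]]["A"]), 1)
  expect_equal(p1$entropy[1], 0)
  p2 <- build_profiles(c(rep("A", 5), rep("V", 5)))
  expect_equal(unname(p2$p[[1]][c("A", "V")]), c(0.5, 0.5))
  # pseudocount 1 on a single sequence: (counts + 1) / (1 + 20)
  p3 <- build_profiles("A", pseudocount = 1)
  expect_equal(unname(p3$p[[1]]["A"]), 2 / 21)
  expect_equal(unname(p3$p[[1]]["W"]), 1 / 21)
  expect_equal(sum(p3$p[[1]]), 1, tolerance = 1e-12)
  # gap columns are dropped with a warning
  expect_warning(pg <- build_profiles(c("A-V", "AAV")), "gap")
  expect_equal(pg$position, c(1L, 3L))
})

test_that("profile similarity has its closed-form extremes and symmetry", {
  p <- c(0.5, 0.5, rep(0, 18))
  expect_equal(profile_similarity(p, p), 1)
  q <- c(1, rep(0, 19))
  r <- c(0, 1, rep(0, 18))
  expect_equal(profile_similarity(q, r), 0, tolerance = 1e-12)
  # brute-force term-by-term oracle for p = (.5,.5,0,...), q = (1,0,...)
  m <- (p + q) / 2
  js <- 0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)) +
    0.5 * (1 * log2(1 / 0.75))
  expect_equal(profile_similarity(p, q), 1 - js, tolerance = 1e-12)
  expect_equal(profile_similarity(p, q), profile_similarity(q, p))
  expect_true(profile_similarity(p, q) >= 0 && profile_similarity(p, q) <= 1)
})

test_that("sequence entropy uses base-20 logarithms", {
  expect_equal(sequence_entropy(c(1, rep(0, 19))), 0)
  expect_equal(sequence_entropy(rep(1 / 20, 20)), 1, tolerance = 1e-12)
  expect_equal(sequence_entropy(c(0.5, 0.5, rep(0, 18))), log(2) / log(20),
               tolerance = 1e-12)
})

test_that("entropy is Schur-concave on random profiles", {
  set.seed(93)
  for (k in 1:20) {
    p <- as.numeric(rmultinom(1, 200, runif(20))) / 200
    i <- which.max(p)
    j <- which.min(replace(p, i, Inf))
    eps <- max(0, min(0.02, (p[i] - p[j]) / 2))
    q <- p; q[i] <- q[i] - eps; q[j] <- q[j] + eps
    expect_gte(sequence_entropy(q), sequence_entropy(p) - 1e-12)
  }
})

test_that("entropy tertiles split deterministically with the remainder rule", {
  prof9 <- tibble::tibble(position = 1:9, entropy = seq(0.1, 0.9, by = 0.1))
  t9 <- entropy_tertiles(prof9)
  expect_equal(as.integer(table(t9$tertile)[c("high", "medium", "low")]),
               c(3L, 3L, 3L))
  expect_true(all(t9$tertile[t9$entropy >= 0.7] == "high"))
  prof10 <- tibble::tibble(position = 1:10, entropy = seq(0.05, 0.95, by = 0.1))
  t10 <- entropy_tertiles(prof10)
  expect_equal(sort(as.integer(table(t10$tertile))), c(3L, 3L, 4L))
  expect_equal(sum(t10$tertile == "high"), 3L)  # the remainder goes low
  # all-equal entropies: stable order decides, deterministically
  profeq <- tibble::tibble(position = 1:6, entropy = rep(0.5, 6))
  a <- entropy_tertiles(profeq); b <- entropy_tertiles(profeq)
  expect_identical(a, b)
  expect_equal(as.character(a$tertile), rep(c("high", "medium", "low"), each = 2))
  expect_error(entropy_tertiles(tibble::tibble(position = 1:2, entropy = 1:2 / 3)),
               "at least 3")
})

test_that("the uniform null similarity has its closed forms and symmetry", {
  unif_prof <- tibble::tibble(position = 1L, entropy = 1,
                              p = list(stats::setNames(rep(1 / 20, 20), AA1)))
  expect_equal(uniform_null_similarity(unif_prof)$similarity, 1)
  pm <- stats::setNames(c(1, rep(0, 19)), AA1)
  point_prof <- tibble::tibble(position = 1L, entropy = 0, p = list(pm))
  # closed-form JS of point mass vs uniform over 20
  m1 <- (1 + 1 / 20) / 2; m0 <- (0 + 1 / 20) / 2
  js <- 0.5 * log2(1 / m1) + 0.5 * (m1 * 0 +
    (1 / 20) * log2((1 / 20) / m1) + 19 * (1 / 20) * log2((1 / 20) / m0))
  expect_equal(uniform_null_similarity(point_prof)$similarity, 1 - js,
               tolerance = 1e-12)
  # permuting amino-acid labels does not change the null similarity
  perm <- stats::setNames(pm[c(5:20, 1:4)], AA1)
  perm_prof <- tibble::tibble(position = 1L, entropy = 0, p = list(perm))
  expect_equal(uniform_null_similarity(perm_prof)$similarity,
               uniform_null_similarity(point_prof)$similarity)
})

test_that("design diagnostics compute glycine fraction and acceptance arithmetic", {
  tr <- structure(list(
    sequences = c("AG", "GG", "AA"),
    ledger = tibble::tibble(move = 1:1000, type = "protein", position = "A:1",
                            dE = 0, accepted = rep(c(TRUE, FALSE),
                                                   c(400, 600)),
                            sequence = "AG"),
    acceptance_ratio = 0.4, start_seq = "AG",
    design_positions = tibble::tibble(chain = "A", seqpos = 1:2)),
    class = "cm_design_trace")
  d <- design_diagnostics(tr)
  expect_equal(d$glycine_fraction, 3 / 6)
  expect_equal(d$acceptance_ratio, 0.4)
  # a trace that never accepted a mutation keeps the start glycine fraction
  tr$sequences <- "AG"
  expect_equal(design_diagnostics(tr)$glycine_fraction, 0.5)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  # two-sided Fisher by direct enumeration over the hypergeometric support
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  st <- significance_tests(counts = tab)
  expect_equal(st$p_value[st$test == "fisher_exact"], p_exact,
               tolerance = 1e-12)
  expect_equal(p_exact, 2 / choose(20, 10), tolerance = 1e-12)
  # no association
  expect_equal(significance_tests(counts = matrix(5, 2, 2))$p_value, 1)
  # degenerate margin warns and returns 1
  expect_warning(pz <- significance_tests(counts = matrix(c(0, 0, 5, 5), 2, 2)),
                 "degenerate")
  expect_equal(pz$p_value, 1)
})

test_that("the paired t-test handles identical vectors and real differences", {
  expect_warning(p1 <- significance_tests(paired_a = c(1, 2, 3),
                                          paired_b = c(1, 2, 3)), "variance")
  expect_equal(p1$p_value, 1)
  set.seed(94)
  a <- runif(30); b <- a + rnorm(30, 0.3, 0.05)
  p2 <- significance_tests(paired_a = a, paired_b = b)
  expect_equal(p2$p_value,
               t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_lt(p2$p_value, 1e-6)
})

test_that("the RMSD report has its closed forms and rigid invariance", {
  pose <- fx_helix("AALSAVKDA")
  sel <- tibble::tibble(chain = "A", seqpos = 3L)
  expect_equal(rmsd_report(pose, pose, sel)$rmsd, 0, tolerance = 1e-9)
  # one atom displaced by 1 A among n atoms: RMSD = 1/sqrt(n)
  moved <- pose
  n_at <- nrow(moved$residues[[3]]$sidechain[c("CB", "CG", "CD1", "CD2"), ])
  moved$residues[[3]]$sidechain["CD1", ] <-
    moved$residues[[3]]$sidechain["CD1", ] + c(1, 0, 0)
  r <- rmsd_report(moved, pose, sel)
  expect_equal(r$rmsd, 1 / sqrt(r$n_atoms), tolerance = 1e-9)
  # rigid transforms of the model do not change the report
  R <- coupledmoves:::rotation_matrix(c(1, 1, 0), 25)
  rigid <- moved
  for (i in seq_along(rigid$residues)) {
    rr <- rigid$residues[[i]]
    rr$backbone <- sweep(rr$backbone %*% t(R), 2, c(3, 2, 1), FUN = "+")
    if (!is.null(rr$sidechain))
      rr$sidechain <- sweep(rr$sidechain %*% t(R), 2, c(3, 2, 1), FUN = "+")
    rigid$residues[[i]] <- rr
  }
  expect_equal(rmsd_report(rigid, pose, sel)$rmsd, r$rmsd, tolerance = 1e-6)
  # identity mismatch compares common atoms with a warning
  mut <- build_sidechain(pose, list(chain = "A", seqpos = 3),
                         list(aa = "V", chis = list(-60), proton_chi = 180,
                              prob = 1))
  expect_warning(rm2 <- rmsd_report(mut, pose, sel), "mismatch")
  expect_true(is.finite(rm2$rmsd))
})

test_that("frequency matrices sum to one per position", {
  fm <- frequency_matrix(c("AV", "SV", "AV"))
  expect_equal(as.numeric(tapply(fm$freq, fm$position, sum)), c(1, 1),
               tolerance = 1e-12)
})
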