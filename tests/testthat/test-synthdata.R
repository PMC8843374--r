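# Synthetic family generator

test_that("ideal chains are deterministic and follow the plan", {
  m1 <- build_ideal_chain("H10 C5 E6", seed = 9)
  m2 <- build_ideal_chain("H10 C5 E6", seed = 9)
  expect_identical(m1$chains$A$atoms, m2$chains$A$atoms)
  expect_equal(nrow(m1$chains$A$residues), 21)
  m3 <- build_ideal_chain("H10 C5 E6", seed = 10)
  expect_false(identical(m1$chains$A$atoms$x, m3$chains$A$atoms$x))
  # consistency with the assignment module
  sse <- assign_sse(build_ideal_chain("H12", seed = 1)$chains$A)
  expect_true(all(sse$sse[3:10] == "H"))
})

test_that("plan validation enforces segment minima", {
  expect_error(sse_plan("H3"), "minimum")
  expect_error(sse_plan("E2 H4"), "minimum")
  expect_error(sse_plan("C4"), "8 residues")
  p <- sse_plan("H10 C5 E6")
  expect_equal(p$len, c(10L, 5L, 6L))
})

test_that("lysines carry NZ atoms and glycines no CB", {
  m <- build_ideal_chain("C10", sequence = "GKGKGKGKGK", seed = 1)
  A <- m$chains$A$atoms
  expect_equal(sum(A$elety == "NZ"), 5)
  expect_equal(sum(A$elety == "CB"), 5)
  expect_true(all(A$resid[A$elety == "NZ"] == "LYS"))
})

test_that("requested and realized identity agree within one point", {
  sp <- family_spec(plan = "H20 C8 E12 C8 H20 C8 E12 C8 H20",
                    sites = c(25, 60), n_homologs = 3,
                    identity = c(80, 60, 40), noise_sd = 0, seed = 41)
  fam <- generate_family(sp)
  expect_gte(sp$length, 100)
  expect_equal(fam$metadata$percent_identity, c(80, 60, 40),
               tolerance = 0.011)
})

test_that("unreachable identity errors with the achievable bound", {
  sp <- family_spec(n_homologs = 1, identity = 1, seed = 5)
  expect_error(generate_family(sp), "achievable")
})

test_that("hinge-rotated domains stay internally rigid", {
  sp <- family_spec(n_homologs = 1, identity = 100,
                    hinge = list(domain = 2, angle = 45), noise_sd = 0,
                    seed = 42)
  fam <- generate_family(sp)
  caT <- acsite3d:::chain_ca(fam$target$chains$A)
  caH <- acsite3d:::chain_ca(fam$homologs$syn01$chains$A)
  for (d in fam$spec$domains) {
    idx <- d[1]:d[2]
    expect_lt(kabsch_superpose(caT[idx, ], caH[idx, ])$rmsd, 1e-6)
  }
  # but the whole chain does not superpose rigidly
  expect_gt(kabsch_superpose(caT, caH)$rmsd, 1)
})

test_that("generation is fully deterministic under a fixed seed", {
  sp <- family_spec(n_homologs = 2, identity = 70, noise_sd = 0.3,
                    seed = 43)
  f1 <- generate_family(sp)
  f2 <- generate_family(sp)
  expect_identical(f1$homologs$syn01$chains$A$atoms,
                   f2$homologs$syn01$chains$A$atoms)
  expect_identical(f1$metadata, f2$metadata)
  expect_identical(f1$truth, f2$truth)
})

test_that("family outputs land on disk as standard text formats", {
  d <- tempfile()
  fam <- generate_family(family_spec(n_homologs = 2, seed = 44),
                         out_dir = d)
  expect_true(all(file.exists(file.path(
    d, c("target.pdb", "syn01.pdb", "syn02.pdb", "homologs.fasta",
         "metadata.tsv", "truth.tsv")))))
  reread <- parse_structure(file.path(d, "syn01.pdb"))
  expect_equal(reread$chains$A$atom_sequence,
               fam$homologs$syn01$chains$A$atom_sequence)
})

test_that("recovery evaluation counts matches exactly", {
  truth <- data.frame(homolog = rep(c("h1", "h2"), each = 10),
                      site_resno = rep(1:10, 2),
                      conserved_3d = rep(c(TRUE, FALSE), 10),
                      conserved_1d = TRUE,
                      discrepancy = rep(c("agree", "open_star"), 10))
  calls <- data.frame(homolog_id = truth$homolog,
                      site_resno = truth$site_resno,
                      conserved_3d = truth$conserved_3d,
                      conserved_1d = truth$conserved_1d,
                      discrepancy = truth$discrepancy)
  expect_equal(evaluate_recovery(calls, truth)$accuracy, 1.0)
  calls$conserved_3d[7] <- !calls$conserved_3d[7]
  calls$discrepancy[7] <- classify_discrepancy(calls$conserved_1d[7],
                                               calls$conserved_3d[7])
  expect_equal(evaluate_recovery(calls, truth)$accuracy, 0.95)
  expect_error(evaluate_recovery(calls[-1, ], truth), "grid")
})

test_that("random calls match truth at the analytically expected rate", {
  set.seed(55)
  n <- 1000
  truth <- data.frame(homolog = "h", site_resno = 1:n,
                      conserved_3d = runif(n) < 0.6,
                      conserved_1d = runif(n) < 0.7)
  truth$discrepancy <- mapply(classify_discrepancy, truth$conserved_1d,
                              truth$conserved_3d)
  calls <- data.frame(homolog_id = "h", site_resno = 1:n,
                      conserved_3d = runif(n) < 0.6,
                      conserved_1d = runif(n) < 0.7)
  calls$discrepancy <- mapply(classify_discrepancy, calls$conserved_1d,
                              calls$conserved_3d)
  ev <- evaluate_recovery(calls, truth)
  p3 <- mean(calls$conserved_3d); q3 <- mean(truth$conserved_3d)
  p1 <- mean(calls$conserved_1d); q1 <- mean(truth$conserved_1d)
  m3 <- p3 * q3 + (1 - p3) * (1 - q3)
  m1 <- p1 * q1 + (1 - p1) * (1 - q1)
  expected <- m3 * m1   # discrepancy matches whenever both verdicts do
  sd3 <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(ev$accuracy - expected), 3 * sd3 + 0.02)
})
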