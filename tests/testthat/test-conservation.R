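# Conservation calls, discrepancy classification, domain filtering and
# taxon summaries

test_that("aligned lysine is conserved without flags; substitution is not", {
  fam <- generate_family(family_spec(
    n_homologs = 2, identity = c(90, 80), noise_sd = 0,
    outcomes = list(NULL, list("14" = "substituted:R")), seed = 31))
  t <- fam$target$chains$A
  al1 <- flexible_align(t, fam$homologs$syn01$chains$A)
  c1 <- call_site_3d(14, al1)
  expect_true(c1$conserved_3d)
  expect_false(c1$rescue_flag || c1$disorder_flag)
  expect_equal(c1$aligned_aa, "K")

  al2 <- flexible_align(t, fam$homologs$syn02$chains$A)
  c2 <- call_site_3d(14, al2)
  expect_false(c2$conserved_3d)
  expect_equal(c2$aligned_aa, "R")
  expect_error(call_site_3d(9999, al1), "not in target")
})

test_that("rescue fires on a sequence-shifted, spatially conserved lysine", {
  fam <- generate_family(family_spec(
    n_homologs = 1, identity = 85, noise_sd = 0.1,
    outcomes = list(list("43" = "shifted:2")), seed = 32))
  t <- fam$target$chains$A
  al <- flexible_align(t, fam$homologs$syn01$chains$A)
  cc <- call_site_3d(43, al)
  expect_true(cc$conserved_3d)
  expect_true(cc$rescue_flag)
})

test_that("rescue never fires when the aligned residue is already lysine", {
  fam <- generate_family(family_spec(n_homologs = 3,
                                     identity = c(95, 75, 55),
                                     noise_sd = 0.2, seed = 33))
  t <- fam$target$chains$A
  for (h in fam$homologs) {
    al <- flexible_align(t, h$chains$A)
    for (s in fam$spec$sites) {
      cc <- call_site_3d(s, al)
      if (!is.na(cc$aligned_aa) && cc$aligned_aa == "K")
        expect_false(cc$rescue_flag)
    }
  }
})

test_that("a disordered loop lysine is conserved via the declared sequence", {
  fam <- generate_family(family_spec(
    n_homologs = 1, identity = 85, noise_sd = 0.1,
    outcomes = list(list("43" = "disordered")), seed = 34))
  t <- fam$target$chains$A
  hc <- fam$homologs$syn01$chains$A
  # the masked residues really are absent from coordinates
  expect_false(43 %in% hc$residues$resno)
  al <- flexible_align(t, hc)
  cc <- call_site_3d(43, al)
  expect_true(cc$conserved_3d)
  expect_true(cc$disorder_flag)
})

test_that("a displaced lysine is not conserved in 3D but is in 1D", {
  fam <- generate_family(family_spec(
    n_homologs = 1, identity = 85, noise_sd = 0.1,
    outcomes = list(list("43" = "displaced")), seed = 35))
  t <- fam$target$chains$A
  al <- flexible_align(t, fam$homologs$syn01$chains$A)
  cc <- call_site_3d(43, al)
  expect_false(cc$conserved_3d)
  m1d <- build_sequence_msa(t$atom_sequence,
                            c(syn01 = fam$homologs$syn01$chains$A$seqres_sequence))
  expect_true(call_site_1d(43, m1d, "syn01"))
  expect_equal(classify_discrepancy(TRUE, cc$conserved_3d), "open_star")
})

test_that("1D calls read the anchored MSA column", {
  t <- build_ideal_chain("C10", sequence = "AAKAAAAKAA", seed = 1)$chains$A
  h <- build_ideal_chain("C10", sequence = "AAKAAAARAA", seed = 2,
                         entry_id = "h1")$chains$A
  msa <- build_anchored_msa(t, list(mk_fake_alignment(t, h, 1:10, 1:10,
                                                      "h1")))
  expect_true(call_site_1d(3, msa, "h1_A"))
  expect_false(call_site_1d(8, msa, "h1_A"))
  expect_error(call_site_1d(99, msa, "h1_A"), "column")
})

test_that("discrepancy classification follows the star table", {
  expect_equal(classify_discrepancy(TRUE, FALSE), "open_star")
  expect_equal(classify_discrepancy(FALSE, TRUE), "filled_star")
  expect_equal(classify_discrepancy(TRUE, TRUE), "agree")
  expect_equal(classify_discrepancy(FALSE, FALSE), "agree")
  expect_error(classify_discrepancy(NA, TRUE), "required")
})

test_that("domain presence thresholds the aligned coverage", {
  t <- build_ideal_chain("C20", seed = 3)$chains$A
  h <- build_ideal_chain("C20", seed = 4)$chains$A
  full <- mk_fake_alignment(t, h, 1:20, 1:20)
  expect_true(domain_present(data.frame(start = 5, end = 14), full))
  none <- mk_fake_alignment(t, h, 15:20, 15:20)
  expect_false(domain_present(data.frame(start = 1, end = 10), none))
  # exactly 50% coverage: false at 0.7, true at 0.4
  half <- mk_fake_alignment(t, h, 1:5, 1:5)
  dom <- data.frame(start = 1, end = 10)
  expect_false(domain_present(dom, half, 0.7))
  expect_true(domain_present(dom, half, 0.4))
  expect_error(domain_present(data.frame(start = 100, end = 120), full),
               "empty domain")
})

test_that("taxon summary fractions are exact and domain-filtered", {
  calls <- data.frame(
    homolog_id = c("h1", "h2", "h3", "h4"),
    site_resno = 10,
    conserved_3d = c(TRUE, TRUE, FALSE, FALSE),
    conserved_1d = c(TRUE, TRUE, FALSE, FALSE),
    rescue_flag = FALSE, disorder_flag = FALSE,
    discrepancy = "agree",
    domain_present = c(TRUE, TRUE, TRUE, TRUE))
  meta <- data.frame(
    pdb_id = c("h1", "h2", "h3", "h4"),
    uniprot_id = paste0("U", 1:4),
    organism = paste0("o", 1:4),
    taxon_group = c("Gram-negative", "Gram-negative", "Gram-negative",
                    "Eukaryote"),
    resolution = 2, is_wildtype = TRUE,
    percent_identity = c(90, 80, 70, 60))
  s <- summarize_conservation(calls, meta)
  gn <- s$summary[s$summary$group == "Gram-negative", ]
  expect_equal(gn$fraction, 2 / 3)
  eu <- s$summary[s$summary$group == "Eukaryote", ]
  expect_equal(eu$fraction, 0)
  # failing the domain filter removes the homolog from the denominator
  calls$domain_present[3] <- FALSE
  s2 <- summarize_conservation(calls, meta)
  gn2 <- s2$summary[s2$summary$group == "Gram-negative", ]
  expect_equal(gn2$total, 2)
  expect_equal(gn2$fraction, 1)
  expect_equal(unname(s2$matrix["h3", "K10"]), "absent")
  # matrix rows are ordered by percent identity
  expect_equal(rownames(s$matrix), c("h1", "h2", "h3", "h4"))
  expect_error(summarize_conservation(
    transform(calls, homolog_id = "zz"), meta), "without metadata")
})

test_that("packaged site and domain tables load and validate", {
  sites <- default_site_annotations()
  expect_equal(sort(unique(sites$protein_id)),
               c("Adk", "Fmt", "Icd", "KatE", "YaaA"))
  expect_equal(sum(sites$protein_id == "Adk"), 6)
  doms <- default_domain_definitions()
  lid <- doms[doms$protein_id == "Adk" & doms$domain == "LID", ]
  expect_equal(c(lid$start, lid$end), c(122, 159))
  bad <- tempfile(); writeLines("protein_id\tresno", bad)
  expect_error(load_site_table(bad), "missing column")
})
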