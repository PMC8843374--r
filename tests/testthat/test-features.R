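# Structural feature annotation

test_that("ideal helix and strand fixtures get the right labels", {
  hs <- assign_sse(build_ideal_chain("H12", seed = 1)$chains$A)
  expect_true(all(hs$sse[3:10] == "H"))
  es <- assign_sse(build_ideal_chain("E8", seed = 1)$chains$A)
  expect_true(all(es$sse[3:6] == "E"))
  mix <- assign_sse(build_ideal_chain("H10 C6 E6 C4", seed = 2)$chains$A)
  expect_true(all(mix$sse[3:8] == "H"))
  expect_true(all(mix$sse[12:15] == "C"))
  expect_true(any(mix$sse[17:21] == "E"))
})

test_that("site classification reports class and end flag", {
  sse <- assign_sse(build_ideal_chain("C3 H10 C8", seed = 1)$chains$A)
  seg <- which(sse$sse == "H")
  interior <- seg[seg > min(seg) + 1 & seg < max(seg) - 1]
  cl <- classify_site_sse(interior[1], sse)
  expect_equal(cl$class, "H"); expect_false(cl$end_flag)
  first <- classify_site_sse(min(seg), sse)
  expect_equal(first$class, "H"); expect_true(first$end_flag)
  loop <- classify_site_sse(1, sse)
  expect_equal(loop$class, "C")
  expect_error(classify_site_sse(999, sse), "not in assignment")
})

test_that("single-atom SASA matches the closed form within 1%", {
  m <- mk_model(mk_atom("CA", "ALA", "A", 1, 0, 0, 0, elesy = "C"))
  s <- compute_sasa(m)
  expect_equal(s$atoms$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("an enclosed atom has zero SASA and disjoint twins are equal", {
  # shell of atoms around the origin atom
  pts <- acsite3d:::.sphere_points(60) * 2.5
  df <- mk_atom("CA", "ALA", "A", 1, 0, 0, 0, elesy = "C")
  for (i in seq_len(nrow(pts)))
    df <- rbind(df, mk_atom("CA", "ALA", "A", 1 + i, pts[i, 1], pts[i, 2],
                            pts[i, 3], elesy = "C"))
  s <- compute_sasa(mk_model(df))
  expect_equal(s$atoms$sasa[1], 0)

  two <- rbind(mk_atom("CA", "ALA", "A", 1, 0, 0, 0, elesy = "C"),
               mk_atom("CA", "ALA", "A", 2, 50, 0, 0, elesy = "C"))
  s2 <- compute_sasa(mk_model(two))
  expect_equal(s2$atoms$sasa[1], s2$atoms$sasa[2])
  expect_equal(s2$atoms$sasa[1], 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("assembly-context SASA never exceeds isolated-chain SASA", {
  m <- build_ideal_chain("H10 C4 E6", seed = 4)
  olig <- mk_oligomer(m, 2)
  # bring chain B close enough to occlude chain A
  olig$chains$B$atoms$x <- olig$chains$B$atoms$x - 55
  mono <- compute_sasa(olig, chains = "A")
  asm <- compute_sasa(olig, chains = c("A", "B"))
  a_mono <- mono$atoms$sasa
  a_asm <- asm$atoms$sasa[asm$atoms$chain_id == "A"]
  expect_true(all(a_asm <= a_mono + 1e-9))
})

test_that("relative accessibility is clipped and exposure thresholded", {
  m <- mk_model(mk_atom("NZ", "LYS", "A", 1, 0, 0, 0, elesy = "N"))
  s <- compute_sasa(m)
  expect_lte(max(s$residues$rel_accessibility), 1.2)
  expect_true(is_exposed(s, "A", 1))
})

test_that("direct H-bonds respect the distance cutoff", {
  base <- rbind(mk_atom("NZ", "LYS", "A", 1, 0, 0, 0, elesy = "N"),
                mk_atom("OD1", "ASP", "A", 5, 0, 2.9, 0, elesy = "O"))
  hb <- detect_hbonds(mk_model(base), "A", 1)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$partner_class, "side chain")
  expect_equal(hb$distance, 2.9)

  far <- rbind(mk_atom("NZ", "LYS", "A", 1, 0, 0, 0, elesy = "N"),
               mk_atom("OD1", "ASP", "A", 5, 0, 3.8, 0, elesy = "O"))
  expect_equal(nrow(detect_hbonds(mk_model(far), "A", 1)), 0)
  expect_error(detect_hbonds(mk_model(base), "A", 5, donor_atoms = "NZ"),
               "NZ")
})

test_that("water-mediated bonds require both legs in range", {
  df <- rbind(mk_atom("NZ", "LYS", "A", 1, 0, 0, 0, elesy = "N"),
              mk_atom("O", "GLY", "A", 9, 0, 6.0, 0, elesy = "O"))
  mod <- mk_model(df)
  mod$waters <- data.frame(type = "HETATM", elety = "O", resid = "HOH",
                           chain = "W", resno = 101, insert = "", x = 0,
                           y = 3.0, z = 0, o = 1, b = 0, alt = "",
                           elesy = "O", stringsAsFactors = FALSE)
  hb <- detect_hbonds(mod, "A", 1)
  wm <- hb[!is.na(hb$bridging_water), ]
  expect_equal(nrow(wm), 1)
  expect_equal(wm$partner_class, "backbone")
  expect_equal(wm$bridging_water, 101)
  # move the acceptor out of the second leg
  mod$chains$A$atoms$y[mod$chains$A$atoms$resno == 9] <- 7.5
  hb2 <- detect_hbonds(mod, "A", 1)
  expect_equal(sum(!is.na(hb2$bridging_water)), 0)
})

test_that("contact scan classifies interface partners by distance", {
  m <- build_ideal_chain("H10 C4", seed = 7)
  olig <- mk_oligomer(m, 2)   # 60 A apart: no contacts
  site <- olig$chains$A$residues$resno[5]
  expect_equal(nrow(contact_scan(olig, "A", site)), 0)

  # translate chain B so its first residue sits ~4 A from the site
  ca <- acsite3d:::chain_ca(olig$chains$A)[5, ]
  B <- olig$chains$B$atoms
  shift <- ca + c(4, 0, 0) - as.numeric(B[B$elety == "CA", c("x", "y", "z")][1, ])
  B$x <- B$x + shift[1]; B$y <- B$y + shift[2]; B$z <- B$z + shift[3]
  olig$chains$B <- acsite3d:::new_struct_chain("B", B, rep(TRUE, nrow(B)),
                                               NA)
  cs <- contact_scan(olig, "A", site)
  expect_true("inter-subunit" %in% cs$type)
  expect_lte(min(cs$min_distance), 5)
})

test_that("het groups appear as ligand contacts", {
  m <- build_ideal_chain("H10", seed = 2)
  ca <- acsite3d:::chain_ca(m$chains$A)[5, ]
  m$het <- data.frame(type = "HETATM", elety = "C1", resid = "LIG",
                      chain = "L", resno = 500, insert = "",
                      x = ca[1] + 3.5, y = ca[2], z = ca[3], o = 1, b = 0,
                      alt = "", elesy = "C", stringsAsFactors = FALSE)
  cs <- contact_scan(m, "A", m$chains$A$residues$resno[5])
  expect_equal(cs$type, "ligand")
})

test_that("site annotation combines features per site", {
  fam <- generate_family(family_spec(n_homologs = 1, seed = 3))
  rep_ <- annotate_sites(fam$target, "A", fam$spec$sites)
  expect_equal(nrow(rep_), 2)
  expect_true(all(c("sse_class", "rel_accessibility", "interface",
                    "exposed") %in% names(rep_)))
  expect_true(all(rep_$sse_class == "C"))  # planted sites sit on loops
})
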