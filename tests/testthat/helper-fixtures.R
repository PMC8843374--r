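# Fixture builders shared by the test files. Everything is generated in code;
# no binary fixtures.

# structure_model around a hand-built atom table
mk_model <- function(df, entry_id = "fix", seqres = NA) {
  ch_ids <- unique(df$chain)
  chains <- lapply(ch_ids, function(cid) {
    sub <- df[df$chain == cid, , drop = FALSE]
    acsite3d:::new_struct_chain(cid, sub, rep(TRUE, nrow(sub)), seqres)
  })
  structure(list(entry_id = entry_id, chains = setNames(chains, ch_ids),
                 resolution = NA_real_, het = NULL, waters = NULL),
            class = "structure_model")
}

mk_atom <- function(elety, resid, chain, resno, x, y, z, elesy = NULL,
                    insert = "", o = 1, alt = "") {
  if (is.null(elesy)) elesy <- substr(elety, 1, 1)
  data.frame(type = "ATOM", elety = elety, resid = resid, chain = chain,
             resno = resno, insert = insert, x = x, y = y, z = z, o = o,
             b = 0, alt = alt, elesy = elesy, stringsAsFactors = FALSE)
}

# 3-residue single-chain PDB text fixture (hand-built K-A-T backbone)
tiny_pdb_text <- function() {
  df <- NULL
  res <- c("LYS", "ALA", "THR")
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    df <- rbind(df,
                mk_atom("N", res[i], "A", i, x0, 0, 0, "N"),
                mk_atom("CA", res[i], "A", i, x0 + 1.2, 0.9, 0, "C"),
                mk_atom("C", res[i], "A", i, x0 + 2.5, 0.2, 0, "C"),
                mk_atom("O", res[i], "A", i, x0 + 2.6, -1.0, 0.3, "O"))
  }
  write_pdb_model(mk_model(df, entry_id = "tiny"))
}

# short irregular CA-only chain (random-walk geometry)
walk_chain <- function(n, seed, chain_id = "A") {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    st <- rnorm(3); st <- 3.8 * st / sqrt(sum(st^2))
    xyz[i, ] <- xyz[i - 1, ] + st
  }
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_atom("CA", "ALA", chain_id, i, xyz[i, 1], xyz[i, 2], xyz[i, 3])))
  acsite3d:::new_struct_chain(chain_id, df, rep(TRUE, nrow(df)), NA)
}

# minimal mmCIF text with one alanine residue
tiny_cif_text <- function() {
  paste(c(
    "data_test", "#", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 0.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 1.251 2.390 0.000 1.00 0.00 ? 1 ALA A O 1",
    "ATOM 5 N N . GLY A 1 2 ? 3.300 1.700 0.000 1.00 0.00 ? 2 GLY A N 1",
    "ATOM 6 C CA . GLY A 1 2 ? 4.000 3.000 0.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 7 C C . GLY A 1 2 ? 5.500 2.900 0.100 1.00 0.00 ? 2 GLY A C 1",
    "ATOM 8 O O . GLY A 1 2 ? 6.100 1.900 0.400 1.00 0.00 ? 2 GLY A O 1",
    "#"), collapse = "\n")
}

# n translated copies of a chain as one multi-chain model (oligomer stand-in)
mk_oligomer <- function(model, n = 4) {
  base <- model$chains[[1]]
  ids <- LETTERS[seq_len(n)]
  chains <- lapply(seq_len(n), function(k) {
    A <- base$atoms
    A$x <- A$x + 60 * (k - 1)
    A$chain <- ids[k]
    acsite3d:::new_struct_chain(ids[k], A, rep(TRUE, nrow(A)),
                                base$seqres_sequence)
  })
  structure(list(entry_id = paste0(model$entry_id, "_olig"),
                 chains = setNames(chains, ids), resolution = NA_real_,
                 het = NULL, waters = NULL), class = "structure_model")
}

# fabricate a pairwise_struct_alignment from an explicit correspondence
# (used to test the anchored MSA independently of the aligner)
mk_fake_alignment <- function(target, homolog, ia, ib, homolog_id = "fake") {
  corr <- data.frame(
    target_index = ia, homolog_index = ib,
    target_resno = target$residues$resno[ia],
    homolog_resno = homolog$residues$resno[ib],
    target_aa = strsplit(target$atom_sequence, "")[[1]][ia],
    homolog_aa = strsplit(homolog$atom_sequence, "")[[1]][ib],
    block = 1L, stringsAsFactors = FALSE)
  structure(list(target_id = "t", homolog_id = homolog_id,
                 target_chain = target, homolog_chain = homolog,
                 mode = "flexible", correspondence = corr, blocks = list(),
                 twists = 0L, rmsd = 0, opt_rmsd = 0, score = 1,
                 aligned_length = nrow(corr), empty = FALSE),
            class = "pairwise_struct_alignment")
}

# grid-search oracle for the Kabsch fit: nested Euler-angle refinement with
# centroid-matched translation (independent of the SVD route)
grid_rmsd_oracle <- function(a, b, levels = 4) {
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  rot <- function(al, be, ga) {
    cz <- cos(al); sz <- sin(al); cy <- cos(be); sy <- sin(be)
    cx <- cos(ga); sx <- sin(ga)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  eval_r <- function(al, be, ga) {
    sqrt(mean(rowSums((bc %*% t(rot(al, be, ga)) - ac)^2)))
  }
  ctr <- c(0, 0, 0); step <- pi / 12
  best <- c(ctr, eval_r(ctr[1], ctr[2], ctr[3]))
  grid0 <- expand.grid(al = seq(-pi, pi, by = step),
                       be = seq(-pi / 2, pi / 2, by = step),
                       ga = seq(-pi, pi, by = step))
  r0 <- mapply(eval_r, grid0$al, grid0$be, grid0$ga)
  k <- which.min(r0)
  best <- c(grid0$al[k], grid0$be[k], grid0$ga[k], r0[k])
  for (lv in seq_len(levels)) {
    step <- step / 4
    g <- expand.grid(al = best[1] + step * (-4:4),
                     be = best[2] + step * (-4:4),
                     ga = best[3] + step * (-4:4))
    r <- mapply(eval_r, g$al, g$be, g$ga)
    k <- which.min(r)
    best <- c(g$al[k], g$be[k], g$ga[k], r[k])
  }
  best[4]
}
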