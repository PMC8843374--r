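# Pairwise structural alignment: rigid, AFP scan, flexible chaining,
# all-chain comparison and chain selection

two_domain_plan <- "H12 C4 E8 C4 H12 C6 H12 C4 E8 C4 H12"

test_that("rigid alignment of a chain with itself is exact", {
  m <- build_ideal_chain(two_domain_plan, seed = 2)
  al <- rigid_align_chains(m$chains$A, m$chains$A)
  expect_lt(al$rmsd, 1e-6)
  expect_identical(al$twists, 0L)
  expect_equal(al$opt_rmsd, al$rmsd)
})

test_that("AFP scan finds the diagonal on an exact copy and nothing on
           scrambled geometry", {
  m <- build_ideal_chain("H20", seed = 3)
  ch <- m$chains$A
  af <- find_afps(ch, ch)
  d0 <- af[af$startA == 1 & af$startB == 1, ]
  expect_equal(nrow(d0), 1)
  expect_lt(d0$fragment_rmsd, 1e-6)

  # reverse the traversal order of an irregular chain: local geometry is
  # destroyed (a helix would not do, its Ca trace has a 2-fold axis)
  ch_w <- walk_chain(20, seed = 31)
  rev_atoms <- ch_w$atoms
  n <- nrow(ch_w$residues)
  rev_atoms$resno <- n + 1 - rev_atoms$resno
  rev_atoms <- rev_atoms[order(rev_atoms$resno), ]
  ch_rev <- acsite3d:::new_struct_chain("A", rev_atoms,
                                        rep(TRUE, nrow(rev_atoms)), NA)
  af2 <- find_afps(ch_w, ch_rev)
  diag2 <- af2[af2$startA == af2$startB & af2$fragment_rmsd < 1e-3, ]
  expect_equal(nrow(diag2), 0)
})

test_that("AFP set equals an exhaustive fragment scan on random chains", {
  set.seed(9)
  mkchain <- function(seed) {
    # random walk with realistic 3.8 A Ca steps
    n <- 30
    xyz <- matrix(0, n, 3)
    for (i in 2:n) {
      st <- rnorm(3); st <- 3.8 * st / sqrt(sum(st^2))
      xyz[i, ] <- xyz[i - 1, ] + st
    }
    df <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_atom("CA", "ALA", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3])))
    acsite3d:::new_struct_chain("A", df, rep(TRUE, nrow(df)), NA)
  }
  a <- mkchain(1); b <- mkchain(2)
  L <- 8; cutoff <- 3.0
  af <- find_afps(a, b, L, cutoff)
  caA <- acsite3d:::chain_ca(a); caB <- acsite3d:::chain_ca(b)
  expected <- list()
  for (i in 1:(30 - L + 1)) for (j in 1:(30 - L + 1)) {
    r <- kabsch_superpose(caA[i:(i + L - 1), ], caB[j:(j + L - 1), ])$rmsd
    if (r <= cutoff) expected[[length(expected) + 1]] <- c(i, j, r)
  }
  exp_df <- do.call(rbind, expected)
  expect_equal(nrow(af), if (is.null(exp_df)) 0L else nrow(exp_df))
  if (!is.null(exp_df)) {
    expect_equal(af$startA, exp_df[, 1])
    expect_equal(af$startB, exp_df[, 2])
    expect_equal(af$fragment_rmsd, exp_df[, 3], tolerance = 1e-6)
  }
})

test_that("flexible alignment of a rigid-body copy has no twists", {
  m <- build_ideal_chain(two_domain_plan, seed = 5)
  ch <- m$chains$A
  A <- ch$atoms
  th <- 0.8
  R0 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(A[, c("x", "y", "z")]) %*% t(R0)
  A$x <- xyz[, 1] + 4; A$y <- xyz[, 2] - 2; A$z <- xyz[, 3] + 1
  moved <- acsite3d:::new_struct_chain("A", A, rep(TRUE, nrow(A)), NA)
  al <- flexible_align(ch, moved)
  expect_identical(al$twists, 0L)
  expect_lt(al$opt_rmsd, 0.1)
})

test_that("a 30-degree hinge conformer yields one twist and low opt_rmsd", {
  sp <- family_spec(plan = two_domain_plan, n_homologs = 1, identity = 100,
                    hinge = list(domain = 2, angle = 30), noise_sd = 0,
                    seed = 6)
  fam <- generate_family(sp)
  t <- fam$target$chains$A
  h <- fam$homologs$syn01$chains$A
  fl <- flexible_align(t, h)
  expect_identical(fl$twists, 1L)
  expect_lt(fl$opt_rmsd, 0.5)
  # oracle: each domain superposes rigidly on its own
  caT <- acsite3d:::chain_ca(t); caH <- acsite3d:::chain_ca(h)
  d1 <- fam$spec$domains[[1]]; d2 <- fam$spec$domains[[2]]
  expect_lt(kabsch_superpose(caT[d1[1]:d1[2], ], caH[d1[1]:d1[2], ])$rmsd,
            1e-6)
  expect_lt(kabsch_superpose(caT[d2[1]:d2[2], ], caH[d2[1]:d2[2], ])$rmsd,
            1e-6)
  # rigid rmsd strictly exceeds flexible opt_rmsd for the same pair
  rg <- rigid_align_chains(t, h)
  expect_gt(rg$rmsd, fl$opt_rmsd)
})

test_that("flexible invariants hold across synthetic pairs", {
  sp <- family_spec(plan = two_domain_plan, n_homologs = 3,
                    identity = c(90, 70, 50), noise_sd = 0.3, seed = 8)
  fam <- generate_family(sp)
  t <- fam$target$chains$A
  for (h in fam$homologs) {
    hc <- h$chains$A
    fl <- flexible_align(t, hc)
    # opt_rmsd <= single-transform rmsd over the same correspondence
    expect_lte(fl$opt_rmsd, fl$rmsd + 1e-6)
    # rigid restricted to the flexible correspondence is never better than
    # the per-block fit
    caT <- acsite3d:::chain_ca(t); caH <- acsite3d:::chain_ca(hc)
    co <- fl$correspondence
    single <- kabsch_superpose(caT[co$target_index, ],
                               caH[co$homolog_index, ])$rmsd
    expect_lte(fl$opt_rmsd, single + 1e-6)
    # max_twists = 0 flexible agrees with rigid-style single-transform rmsd
    fl0 <- flexible_align(t, hc, max_twists = 0)
    expect_lt(abs(fl0$opt_rmsd - fl0$rmsd), 0.2)
  }
})

test_that("empty-alignment result is flagged when no AFP chains", {
  a <- walk_chain(6, seed = 32)   # shorter than the fragment length
  b <- build_ideal_chain("H12", seed = 2)$chains$A
  al <- flexible_align(a, b)
  expect_true(al$empty)
  expect_equal(al$score, 0)
  expect_equal(al$aligned_length, 0L)
})

test_that("all-chain comparison covers every polymer chain symmetrically", {
  m <- build_ideal_chain(two_domain_plan, seed = 10)
  olig <- mk_oligomer(m, 4)
  als <- align_all_chains(m$chains$A, olig)
  expect_length(als, 4)
  expect_equal(names(als), c("A", "B", "C", "D"))
  opt <- vapply(als, function(a) a$opt_rmsd, 0)
  expect_lt(max(opt) - min(opt), 1e-6)
  mono <- mk_oligomer(m, 1)
  expect_length(align_all_chains(m$chains$A, mono), 1)
  empty <- structure(list(entry_id = "e", chains = list()),
                     class = "structure_model")
  expect_error(align_all_chains(m$chains$A, empty), "no polymer")
})

mk_sel_alignment <- function(chain_id, opt_rmsd, len, score) {
  hc <- list(chain_id = chain_id,
             atom_sequence = paste(rep("A", len), collapse = ""))
  class(hc) <- "struct_chain"
  structure(list(homolog_id = "h", homolog_chain = hc, opt_rmsd = opt_rmsd,
                 score = score, empty = FALSE),
            class = "pairwise_struct_alignment")
}

test_that("best-chain selection follows the lexicographic rule", {
  a <- mk_sel_alignment("A", 1.2, 200, 280)
  b <- mk_sel_alignment("B", 1.5, 200, 300)
  s <- select_best_chain(list(a, b))
  expect_equal(s$chain_id, "A"); expect_equal(s$criterion, "opt_rmsd")

  a <- mk_sel_alignment("A", 1.2, 190, 280)
  b <- mk_sel_alignment("B", 1.2, 200, 280)
  s <- select_best_chain(list(a, b))
  expect_equal(s$chain_id, "B"); expect_equal(s$criterion, "length")

  a <- mk_sel_alignment("A", 1.2, 200, 280)
  b <- mk_sel_alignment("B", 1.2, 200, 300)
  s <- select_best_chain(list(a, b))
  expect_equal(s$chain_id, "B"); expect_equal(s$criterion, "score")

  a <- mk_sel_alignment("A", 1.2, 200, 300)
  b <- mk_sel_alignment("B", 1.2, 200, 300)
  s <- select_best_chain(list(a, b))
  expect_equal(s$chain_id, "A"); expect_equal(s$criterion, "chain_id")

  expect_error(select_best_chain(list()), "no alignments")
})

test_that("best-chain selection is invariant under input permutation", {
  set.seed(13)
  als <- list(mk_sel_alignment("A", 1.4, 180, 250),
              mk_sel_alignment("B", 1.2, 200, 300),
              mk_sel_alignment("C", 1.2, 200, 310),
              mk_sel_alignment("D", 2.0, 220, 400))
  ref <- select_best_chain(als)$chain_id
  for (k in 1:10) {
    p <- sample(als)
    expect_equal(select_best_chain(p)$chain_id, ref)
  }
})

test_that("alignments serialize to paired FASTA and JSON", {
  m <- build_ideal_chain("H12 C4 E8", seed = 2, entry_id = "t")
  al <- flexible_align(m$chains$A, m$chains$A)
  al$target_id <- "t"; al$homolog_id <- "t2"
  out <- serialize_alignment(al)
  recs <- read_fasta(out$fasta)
  expect_length(recs, 2)
  expect_equal(nchar(recs[[1]]), nchar(recs[[2]]))
  js <- jsonlite::fromJSON(out$json)
  expect_equal(js$twists, 0)
})
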