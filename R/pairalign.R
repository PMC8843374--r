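# Pairwise structural alignment: rigid (sequence correspondence + Kabsch) and
# flexible (aligned-fragment-pair chaining with twists), all-chain comparison
# and the best-chain selection rule.

new_struct_alignment <- function(target_chain, homolog_chain, mode,
                                 correspondence, blocks, twists, rmsd,
                                 opt_rmsd, score, target_id = NA,
                                 homolog_id = NA, empty = FALSE) {
  structure(list(target_id = target_id, homolog_id = homolog_id,
                 target_chain = target_chain, homolog_chain = homolog_chain,
                 mode = mode, correspondence = correspondence,
                 blocks = blocks, twists = twists, rmsd = rmsd,
                 opt_rmsd = opt_rmsd, score = score,
                 aligned_length = if (is.null(correspondence)) 0L
                                  else nrow(correspondence),
                 empty = empty),
            class = "pairwise_struct_alignment")
}

#' @export
print.pairwise_struct_alignment <- function(x, ...) {
  cat(sprintf(
    "%s structural alignment %s:%s vs %s:%s  len=%d rmsd=%.2f opt_rmsd=%.2f twists=%d score=%.1f\n",
    x$mode, x$target_id, x$target_chain$chain_id, x$homolog_id,
    x$homolog_chain$chain_id, x$aligned_length, x$rmsd, x$opt_rmsd,
    x$twists, x$score))
  invisible(x)
}

# correspondence data frame from paired residue indices
.make_corr <- function(target_chain, homolog_chain, ia, ib, block = 1L) {
  data.frame(
    target_index = ia, homolog_index = ib,
    target_resno = target_chain$residues$resno[ia],
    homolog_resno = homolog_chain$residues$resno[ib],
    target_aa = target_chain$residues$aa1[ia],
    homolog_aa = homolog_chain$residues$aa1[ib],
    block = block, stringsAsFactors = FALSE)
}

#' Rigid structural alignment of two chains
#'
#' The residue correspondence comes from an optimal global sequence alignment
#' of the resolved (atom) sequences, restricted to pairs where both residues
#' have a Calpha atom. A single Kabsch transform is fitted over all
#' corresponding Calpha, without outlier rejection, and the RMSD is reported
#' over all corresponding pairs. This reproduces the "superpose once, read
#' everything off one frame" strategy that flexible alignment improves upon
#' for hinged proteins.
#'
#' @param target,homolog `struct_chain` objects with Calpha atoms.
#' @param ... passed to [global_align()].
#' @return a `pairwise_struct_alignment` with `mode = "rigid"`, zero twists
#'   and `opt_rmsd == rmsd`.
#' @export
rigid_align_chains <- function(target, homolog, ...) {
  al <- global_align(target$atom_sequence, homolog$atom_sequence, ...)
  caT <- chain_ca(target); caH <- chain_ca(homolog)
  ok <- !is.na(caT[al$pairs[, 1], 1]) & !is.na(caH[al$pairs[, 2], 1])
  ia <- al$pairs[ok, 1]; ib <- al$pairs[ok, 2]
  if (length(ia) < 3) stop_data("fewer than 3 corresponding Calpha pairs")
  fit <- kabsch_superpose(caT[ia, , drop = FALSE], caH[ib, , drop = FALSE])
  corr <- .make_corr(target, homolog, ia, ib)
  blocks <- list(list(R = fit$R, t = fit$t, rmsd = fit$rmsd,
                      length = length(ia)))
  new_struct_alignment(target, homolog, "rigid", corr, blocks, twists = 0L,
                       rmsd = fit$rmsd, opt_rmsd = fit$rmsd,
                       score = al$score)
}

#' Find aligned fragment pairs (AFPs) between two chains
#'
#' Scans every gapless pair of length-`fragment_length` Calpha fragments and
#' keeps those whose optimally superposed RMSD is at or below the cutoff.
#' Fragments are restricted to runs of consecutive residues that all have
#' Calpha coordinates.
#'
#' @param target,homolog `struct_chain` objects.
#' @param fragment_length fragment length in residues (default 8).
#' @param fragment_rmsd_cutoff RMSD cutoff in angstroms (default 3.0).
#' @return data frame with `startA`, `startB` (1-based residue indices),
#'   `fragment_rmsd`, plus transform columns used by the chainer; sorted by
#'   `(startA, startB)`. Empty when a chain is shorter than the fragment.
#' @export
find_afps <- function(target, homolog, fragment_length = 8,
                      fragment_rmsd_cutoff = 3.0) {
  caT <- chain_ca(target); caH <- chain_ca(homolog)
  okT <- !is.na(caT[, 1]); okH <- !is.na(caH[, 1])
  # map from contiguous-CA index back to residue index; fragments must not
  # span missing residues, so scan per contiguous run
  res <- list()
  runsT <- .ca_runs(okT); runsH <- .ca_runs(okH)
  for (rt in runsT) {
    if (length(rt) < fragment_length) next
    for (rh in runsH) {
      if (length(rh) < fragment_length) next
      sc <- .afp_scan_cpp(caT[rt, , drop = FALSE], caH[rh, , drop = FALSE],
                          as.integer(fragment_length), fragment_rmsd_cutoff)
      if (length(sc$startA)) {
        res[[length(res) + 1]] <- data.frame(
          startA = rt[sc$startA], startB = rh[sc$startB],
          fragment_rmsd = sc$rmsd, R = I(asplit(sc$R, 1)),
          t = I(asplit(sc$t, 1)))
      }
    }
  }
  if (!length(res)) {
    return(data.frame(startA = integer(0), startB = integer(0),
                      fragment_rmsd = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$startA, out$startB), , drop = FALSE]
}

.ca_runs <- function(ok) {
  if (!any(ok)) return(list())
  idx <- which(ok)
  split(idx, cumsum(c(1, diff(idx) != 1)))
}

#' Flexible structural alignment by chaining AFPs with twists
#'
#' Chains AFPs by dynamic programming, monotone in both sequences. A twist is
#' charged whenever consecutive chained AFPs are incompatible with a single
#' rigid transform (rotation difference > `angle_max` degrees or translation
#' difference > `trans_max` angstroms); at most `max_twists` twists are
#' allowed. Blocks are maximal runs of compatible AFPs; each block gets its
#' own Kabsch transform, and `opt_rmsd` is the length-weighted mean of the
#' per-block Calpha RMSDs. `rmsd` is also reported from a single Kabsch over
#' the full correspondence. The chaining score is the sum over chained AFPs of
#' `fragment_length * (cutoff - fragment_rmsd)` minus affine gap costs and
#' `twist_penalty` per twist.
#'
#' @inheritParams find_afps
#' @param max_twists maximum number of transform changes (default 5).
#' @param twist_penalty score penalty per twist (default 15).
#' @param gap_open,gap_extend affine gap costs in the chaining score.
#' @param angle_max,trans_max rigid-compatibility thresholds between
#'   consecutive AFP transforms (default 15 degrees / 3 angstroms).
#' @return a `pairwise_struct_alignment` with `mode = "flexible"`. When no
#'   chainable AFP exists, an empty alignment with score 0 flagged via
#'   `$empty`.
#' @export
flexible_align <- function(target, homolog, fragment_length = 8,
                           fragment_rmsd_cutoff = 3.0, max_twists = 5,
                           twist_penalty = 15, gap_open = 5,
                           gap_extend = 0.5, angle_max = 15, trans_max = 3) {
  afps <- find_afps(target, homolog, fragment_length, fragment_rmsd_cutoff)
  if (nrow(afps) == 0) {
    return(new_struct_alignment(target, homolog, "flexible",
                                correspondence = NULL, blocks = list(),
                                twists = 0L, rmsd = NA_real_,
                                opt_rmsd = NA_real_, score = 0,
                                empty = TRUE))
  }
  Rmat <- do.call(rbind, afps$R)
  Tmat <- do.call(rbind, afps$t)
  ch <- .chain_afps_cpp(as.integer(afps$startA), as.integer(afps$startB),
                        afps$fragment_rmsd, Rmat, Tmat,
                        as.integer(fragment_length), fragment_rmsd_cutoff,
                        gap_open, gap_extend, twist_penalty,
                        as.integer(max_twists), angle_max, trans_max)
  sel <- ch$chain
  twist_in <- ch$twist
  L <- fragment_length
  # union of fragment cells; same-diagonal overlaps merge consistently
  ia <- integer(0); ib <- integer(0); blk <- integer(0)
  block_id <- cumsum(twist_in) + 1L
  for (k in seq_along(sel)) {
    q <- sel[k]
    cells_a <- afps$startA[q]:(afps$startA[q] + L - 1L)
    cells_b <- afps$startB[q]:(afps$startB[q] + L - 1L)
    new <- !(cells_a %in% ia)
    ia <- c(ia, cells_a[new]); ib <- c(ib, cells_b[new])
    blk <- c(blk, rep(block_id[k], sum(new)))
  }
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]; blk <- blk[ord]
  stopifnot(all(diff(ib) > 0))
  caT <- chain_ca(target); caH <- chain_ca(homolog)
  blocks <- lapply(sort(unique(blk)), function(b) {
    w <- blk == b
    fit <- kabsch_superpose(caT[ia[w], , drop = FALSE],
                            caH[ib[w], , drop = FALSE])
    list(R = fit$R, t = fit$t, rmsd = fit$rmsd, length = sum(w))
  })
  opt_rmsd <- sum(vapply(blocks, function(b) b$rmsd * b$length, 0)) /
    length(ia)
  full <- kabsch_superpose(caT[ia, , drop = FALSE], caH[ib, , drop = FALSE])
  corr <- .make_corr(target, homolog, ia, ib, block = blk)
  new_struct_alignment(target, homolog, "flexible", corr, blocks,
                       twists = length(blocks) - 1L, rmsd = full$rmsd,
                       opt_rmsd = opt_rmsd, score = ch$score)
}

#' Align one target chain against every polymer chain of a homolog structure
#'
#' One alignment per homolog polymer chain against the fixed target chain,
#' returned sorted by homolog chain id so the result does not depend on file
#' chain order. Comparing all chains matters because different chains of one
#' crystal can show different conformations, disorder or liganded states.
#'
#' @param target_chain a `struct_chain` (by convention chain A of the target
#'   entry).
#' @param homolog a `structure_model`.
#' @param mode `"flexible"` (default) or `"rigid"`.
#' @param ... passed to the chosen aligner.
#' @return named list of `pairwise_struct_alignment`, one per homolog chain.
#' @export
align_all_chains <- function(target_chain, homolog,
                             mode = c("flexible", "rigid"), ...) {
  mode <- match.arg(mode)
  if (!inherits(homolog, "structure_model") || length(homolog$chains) == 0)
    stop_data("homolog has no polymer chains")
  ids <- sort(names(homolog$chains))
  out <- lapply(ids, function(ch) {
    al <- if (mode == "flexible")
      flexible_align(target_chain, homolog$chains[[ch]], ...)
    else rigid_align_chains(target_chain, homolog$chains[[ch]], ...)
    al$homolog_id <- homolog$entry_id
    al
  })
  setNames(out, ids)
}

#' Select the best homolog chain from a set of alignments
#'
#' Lexicographic rule: lowest `opt_rmsd`; tie broken by the longest aligned
#' homolog sequence length; tie broken by the highest chaining score; final
#' tie broken by the smallest chain id. The returned trace records which
#' criterion decided.
#'
#' @param alignments list of `pairwise_struct_alignment` over the chains of
#'   one homolog structure.
#' @return list of class `chain_selection` with `entry_id`, `chain_id`,
#'   `criterion` and the winning `alignment`.
#' @export
select_best_chain <- function(alignments) {
  if (length(alignments) == 0) stop_data("no alignments to select from")
  alignments <- alignments[!vapply(alignments, function(a) a$empty, TRUE)]
  if (length(alignments) == 0) stop_data("all alignments empty")
  chain_ids <- vapply(alignments, function(a) a$homolog_chain$chain_id, "")
  opt <- vapply(alignments, function(a) a$opt_rmsd, 0)
  len <- vapply(alignments, function(a)
    nchar(a$homolog_chain$atom_sequence), 0L)
  sc <- vapply(alignments, function(a) a$score, 0)
  tol <- 1e-9
  cand <- which(opt <= min(opt) + tol)
  criterion <- "opt_rmsd"
  if (length(cand) > 1) {
    cand2 <- cand[len[cand] == max(len[cand])]
    if (length(cand2) < length(cand)) criterion <- "length"
    cand <- cand2
  }
  if (length(cand) > 1) {
    cand2 <- cand[sc[cand] >= max(sc[cand]) - tol]
    if (length(cand2) < length(cand)) criterion <- "score"
    cand <- cand2
  }
  if (length(cand) > 1) {
    cand <- cand[order(chain_ids[cand])][1]
    criterion <- "chain_id"
  }
  best <- alignments[[cand]]
  structure(list(entry_id = best$homolog_id,
                 chain_id = chain_ids[[cand]],
                 criterion = criterion, alignment = best),
            class = "chain_selection")
}

#' Serialize a structural alignment to a paired gapped FASTA and JSON
#'
#' @param alignment a `pairwise_struct_alignment`.
#' @return list with `fasta` (two gapped records over the union of aligned
#'   positions) and `json` (summary statistics document).
#' @export
serialize_alignment <- function(alignment) {
  co <- alignment$correspondence
  tA <- alignment$target_chain; tB <- alignment$homolog_chain
  # gapped rendering over the merged coordinate system
  ga <- character(0); gb <- character(0)
  pa <- 0L; pb <- 0L
  for (k in seq_len(nrow(co))) {
    while (pa + 1L < co$target_index[k]) {
      pa <- pa + 1L
      ga <- c(ga, substr(tA$atom_sequence, pa, pa)); gb <- c(gb, "-")
    }
    while (pb + 1L < co$homolog_index[k]) {
      pb <- pb + 1L
      ga <- c(ga, "-"); gb <- c(gb, substr(tB$atom_sequence, pb, pb))
    }
    pa <- co$target_index[k]; pb <- co$homolog_index[k]
    ga <- c(ga, substr(tA$atom_sequence, pa, pa))
    gb <- c(gb, substr(tB$atom_sequence, pb, pb))
  }
  recs <- setNames(c(paste(ga, collapse = ""), paste(gb, collapse = "")),
                   c(paste0(alignment$target_id, "_", tA$chain_id),
                     paste0(alignment$homolog_id, "_", tB$chain_id)))
  js <- jsonlite::toJSON(list(
    mode = alignment$mode, aligned_length = alignment$aligned_length,
    rmsd = alignment$rmsd, opt_rmsd = alignment$opt_rmsd,
    twists = alignment$twists, score = alignment$score), auto_unbox = TRUE,
    digits = NA)
  list(fasta = write_fasta(recs), json = js)
}

#' Write the two superposed structures as separate coordinate files
#'
#' Applies the alignment's first-block transform (rigid) or per-block
#' transforms (flexible) to the homolog chain and writes target and homolog as
#' two separate PDB files, decoupling the superposition for later viewing.
#'
#' @param alignment a `pairwise_struct_alignment`.
#' @param target_path,homolog_path output paths.
#' @export
write_superposed <- function(alignment, target_path, homolog_path) {
  tc <- alignment$target_chain
  hc <- alignment$homolog_chain
  co <- alignment$correspondence
  A <- hc$atoms
  xyz <- as.matrix(A[, c("x", "y", "z")])
  # per-residue block membership; residues outside the correspondence use the
  # nearest block by residue index
  blk_of <- rep(NA_integer_, nrow(hc$residues))
  blk_of[co$homolog_index] <- co$block
  if (anyNA(blk_of)) {
    filled <- which(!is.na(blk_of))
    blk_of[is.na(blk_of)] <- vapply(which(is.na(blk_of)), function(i)
      blk_of[filled[which.min(abs(filled - i))]], 0L)
  }
  rk <- paste(A$resno, A$insert, sep = "|")
  rkey <- paste(hc$residues$resno, hc$residues$insert, sep = "|")
  for (b in seq_along(alignment$blocks)) {
    bi <- which(blk_of == b)
    rows <- rk %in% rkey[bi]
    if (!any(rows)) next
    tr <- alignment$blocks[[b]]
    xyz[rows, ] <- apply_transform(xyz[rows, , drop = FALSE], tr$R, tr$t)
  }
  A$x <- xyz[, 1]; A$y <- xyz[, 2]; A$z <- xyz[, 3]
  hmod <- structure(list(entry_id = alignment$homolog_id,
                         chains = setNames(list(
                           new_struct_chain(hc$chain_id, A,
                                            rep(TRUE, nrow(A)),
                                            hc$seqres_sequence)),
                           hc$chain_id),
                         resolution = NA_real_, het = NULL, waters = NULL),
                    class = "structure_model")
  tmod <- structure(list(entry_id = alignment$target_id,
                         chains = setNames(list(tc), tc$chain_id),
                         resolution = NA_real_, het = NULL, waters = NULL),
                    class = "structure_model")
  write_pdb_model(tmod, target_path)
  write_pdb_model(hmod, homolog_path)
  invisible(c(target_path, homolog_path))
}
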