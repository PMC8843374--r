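# Synthetic homolog structure families with planted ground truth: ideal-
# geometry chains, controlled sequence identity, planted site outcomes,
# inter-domain hinge motions, disorder masks and coordinate noise.

# ideal covalent geometry constants (angstroms / degrees)
.GEO <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
             b_CACB = 1.521, a_CNCA = 121.7, a_NCAC = 111.2,
             a_CACN = 116.2, a_CACO = 120.8, a_NCACB = 110.5,
             omega = 180,
             phi_H = -57, psi_H = -47, phi_E = -120, psi_E = 120,
             # loop torsions chosen outside both the helix and strand
             # dihedral windows so planned loops are labeled C
             loop_set = list(c(-60, 140), c(-65, 150), c(60, 40),
                             c(-60, 120)))

# NeRF atom placement: position D from A, B, C with bond |CD|, angle BCD and
# torsion ABCD (degrees)
.place <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- -torsion * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c_ + bond * (-cos(ang) * bc + sin(ang) * cos(tor) * m +
                 sin(ang) * sin(tor) * n)
}

#' Parse a secondary-structure plan
#'
#' A plan is a string like `"H12 C5 E6"` (or a data frame with `type`,
#' `len`): segment types `H` (helix, >= 4 residues), `E` (strand, >= 3) and
#' `C` (loop, >= 1), total length >= 8.
#'
#' @param plan string or data frame.
#' @return data frame with `type`, `len`.
#' @export
sse_plan <- function(plan) {
  if (is.data.frame(plan)) {
    out <- data.frame(type = as.character(plan$type),
                      len = as.integer(plan$len))
  } else {
    m <- regmatches(plan, gregexpr("[HEC][0-9]+", plan))[[1]]
    if (!length(m)) stop_config("cannot parse SSE plan: ", plan)
    out <- data.frame(type = substr(m, 1, 1),
                      len = as.integer(substring(m, 2)))
  }
  mins <- c(H = 4L, E = 3L, C = 1L)
  bad <- out$len < mins[out$type]
  if (any(bad))
    stop_config("segment shorter than its SSE minimum: ",
                paste0(out$type[bad], out$len[bad], collapse = ", "))
  if (sum(out$len) < 8) stop_config("plan shorter than 8 residues")
  out
}

# backbone (+CB) coordinates for a plan; deterministic given seed
.ideal_backbone <- function(plan, seed) {
  plan <- sse_plan(plan)
  n <- sum(plan$len)
  types <- rep(plan$type, plan$len)
  rng <- .seeded_rng(seed)
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    if (types[i] == "H") { phi[i] <- .GEO$phi_H; psi[i] <- .GEO$psi_H }
    else if (types[i] == "E") { phi[i] <- .GEO$phi_E; psi[i] <- .GEO$psi_E }
    else {
      pp <- .GEO$loop_set[[rng(length(.GEO$loop_set))]]
      phi[i] <- pp[1]; psi[i] <- pp[2]
    }
  }
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.GEO$b_NCA, 0, 0)
  a <- .GEO$a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + .GEO$b_CAC * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .GEO$b_CN,
                       .GEO$a_CACN, psi[i - 1])
      CA[i, ] <- .place(CA[i - 1, ], C[i - 1, ], N[i, ], .GEO$b_NCA,
                        .GEO$a_CNCA, .GEO$omega)
      C[i, ] <- .place(C[i - 1, ], N[i, ], CA[i, ], .GEO$b_CAC,
                       .GEO$a_NCAC, phi[i])
    }
    O[i, ] <- .place(N[i, ], CA[i, ], C[i, ], .GEO$b_CO, .GEO$a_CACO,
                     psi[i] + 180)
    CB[i, ] <- .place(C[i, ], N[i, ], CA[i, ], .GEO$b_CACB, .GEO$a_NCACB,
                      122.6)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB, types = types,
       phi = phi, psi = psi)
}

# small deterministic RNG independent of the global stream (linear
# congruential); rng(k) draws an integer in 1..k
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function(k) {
    state <<- (state * 16807) %% 2147483647
    as.integer(state %% k) + 1L
  }
}

# atom table (structio layout) from a sequence and backbone coordinates;
# residues in `mask` get no atoms (disordered)
.atoms_from_bb <- function(sequence, bb, chain = "A", mask = integer(0)) {
  aa1to3 <- setNames(names(.AA3TO1)[1:20], unname(.AA3TO1[1:20]))
  sq <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(sq)) {
    if (i %in% mask) next
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    el <- c("N", "C", "C", "O")
    if (sq[i] != "G") {
      nm <- c(nm, "CB"); xyz <- rbind(xyz, bb$CB[i, ]); el <- c(el, "C")
    }
    if (sq[i] == "K") {
      dir <- bb$CB[i, ] - bb$CA[i, ]
      nz <- bb$CB[i, ] + 2.5 * dir / sqrt(sum(dir^2))
      nm <- c(nm, "NZ"); xyz <- rbind(xyz, nz); el <- c(el, "N")
    }
    rows[[length(rows) + 1]] <- data.frame(
      type = "ATOM", elety = nm, resid = unname(aa1to3[sq[i]]),
      chain = chain, resno = i, insert = "", x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], o = 1, b = 0, alt = "", elesy = el,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build an idealized protein chain from a secondary-structure plan
#'
#' Backbone N/CA/C/O plus CB (and an idealized NZ for lysines) placed with
#' ideal bond lengths and per-segment-type phi/psi (helix -57/-47, strand
#' -120/+120, loops drawn from a fixed small set with a seeded generator).
#' Deterministic: the same seed yields bit-identical coordinates.
#'
#' @param plan SSE plan (see [sse_plan()]).
#' @param sequence one-letter sequence (default: seeded random sequence of
#'   the plan's length).
#' @param seed integer seed.
#' @param entry_id model id.
#' @return a `structure_model` with a single chain A (SEQRES = full
#'   sequence).
#' @export
build_ideal_chain <- function(plan, sequence = NULL, seed = 1,
                              entry_id = "ideal") {
  bb <- .ideal_backbone(plan, seed)
  n <- nrow(bb$CA)
  if (is.null(sequence)) {
    rng <- .seeded_rng(seed + 7)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    sequence <- paste(aas[vapply(seq_len(n), function(i) rng(20L), 1L)],
                      collapse = "")
  }
  if (nchar(sequence) != n)
    stop_config("sequence length != plan length")
  atoms <- .atoms_from_bb(sequence, bb)
  ch <- new_struct_chain("A", atoms, rep(TRUE, nrow(atoms)), sequence)
  structure(list(entry_id = entry_id, chains = list(A = ch),
                 resolution = NA_real_, het = NULL, waters = NULL,
                 backbone = bb),
            class = "structure_model")
}

#' Specify a synthetic homolog family
#'
#' The generator's contract: a target chain defined by an SSE plan and
#' domains, and per-homolog controls for sequence identity, planted site
#' outcomes, hinge motion, disorder and coordinate noise.
#'
#' Site outcomes (per homolog, named by site residue number):
#' `"conserved"` (lysine kept), `"substituted:X"` (replaced by residue X),
#' `"shifted:k"` (lysine moved k positions along the sequence but kept at
#' the target site's spatial position: a 3D-only conservation case),
#' `"disordered"` (lysine kept in the declared sequence, coordinates of the
#' surrounding window removed), `"displaced"` (lysine kept at the sequence
#' position but its local loop moved away in space: a 1D-only case).
#'
#' @param plan target SSE plan string.
#' @param sites integer vector of planted lysine site positions.
#' @param domains list of domain residue ranges
#'   (`list(core = c(1, 60), lid = c(61, 120))`-style).
#' @param n_homologs number of homologs.
#' @param identity target percent identity per homolog (recycled).
#' @param outcomes list (length `n_homologs`) of named outcome vectors; NULL
#'   means all sites conserved.
#' @param hinge NULL, or `list(domain = <index>, angle = <degrees>)`
#'   applied to every homolog; or a list of such per homolog.
#' @param noise_sd Gaussian coordinate noise (angstroms, default 0.3,
#'   crystal-coordinate-scale).
#' @param taxon taxon labels per homolog (recycled; default cycles the
#'   bacterial/eukaryote groups).
#' @param seed integer seed controlling everything.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(plan = "H12 C4 E8 C4 H12 C6 H12 C4 E8 C4 H12",
                        sites = NULL, domains = NULL, n_homologs = 6,
                        identity = 60, outcomes = NULL, hinge = NULL,
                        noise_sd = 0.3, taxon = NULL, seed = 1) {
  pl <- sse_plan(plan)
  n <- sum(pl$len)
  # default sites sit on loops (position 14 in the first inter-domain loop,
  # 43 in the central linker), matching the observation that enzymatic
  # acetylation favors flexible loop residues
  if (is.null(sites)) sites <- c(14, 43)
  if (any(sites < 1 | sites > n)) stop_config("site outside chain")
  if (is.null(domains))
    domains <- list(domain1 = c(1, floor(n / 2)),
                    domain2 = c(floor(n / 2) + 1, n))
  identity <- rep_len(identity, n_homologs)
  if (any(identity < 0 | identity > 100))
    stop_config("identity must be in [0, 100]")
  if (is.null(taxon))
    taxon <- rep_len(c("Gram-negative", "Gram-positive", "Eukaryote",
                       "Archaea"), n_homologs)
  if (!all(taxon %in% taxon_groups())) stop_config("unknown taxon label")
  if (!is.null(hinge) && !is.null(hinge$angle)) hinge <- rep(list(hinge),
                                                             n_homologs)
  if (is.null(outcomes)) outcomes <- rep(list(NULL), n_homologs)
  if (!is.null(hinge) && any(vapply(hinge, function(h)
    !is.null(h) && (h$angle < 0 || h$angle > 180), TRUE)))
    stop_config("hinge angle must be in [0, 180] degrees")
  structure(list(plan = plan, sites = sites, domains = domains,
                 n_homologs = n_homologs, identity = identity,
                 outcomes = outcomes, hinge = hinge, noise_sd = noise_sd,
                 taxon = taxon, seed = seed, length = n),
            class = "family_spec")
}

# Rodrigues rotation of points about axis (unit) through pivot, by angle deg
.rotate_about <- function(xyz, pivot, axis, angle) {
  th <- angle * pi / 180
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(as.matrix(xyz), 2, pivot)
  kx <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
              k[3] * p[, 1] - k[1] * p[, 3],
              k[1] * p[, 2] - k[2] * p[, 1])
  rot <- p * cos(th) + kx * sin(th) +
    outer(as.vector(p %*% k) * (1 - cos(th)), k)
  sweep(rot, 2, pivot, `+`)
}

#' Generate a synthetic homolog family with known ground truth
#'
#' Builds the target chain from the spec's plan, then derives each homolog:
#' the sequence is mutated to the requested identity (site positions follow
#' their planted outcome; non-site positions are mutated uniformly at random
#' with the seeded generator, never to lysine so planted truth stays clean),
#' hinges rotate a domain's coordinates rigidly about an axis through the
#' domain boundary, disorder masks delete coordinates while keeping the
#' declared sequence, and Gaussian noise perturbs all remaining atoms.
#'
#' @param spec a `family_spec`.
#' @param out_dir optional directory; when given, writes the target and
#'   homolog PDB files, a homolog FASTA, a metadata TSV and the truth TSV.
#' @return list with `target` (structure_model), `homologs` (named list of
#'   structure_model), `metadata` (homolog table), `truth` (truth table:
#'   one row per homolog x site with expected 1D/3D verdicts and flags).
#' @export
generate_family <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  n <- spec$length
  rng <- .seeded_rng(spec$seed * 1000 + 17)
  aas <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]  # 19 letters, no K
  # target sequence: seeded random, lysine planted at the sites
  tseq <- aas[vapply(seq_len(n), function(i) rng(19L), 1L)]
  tseq[spec$sites] <- "K"
  target <- build_ideal_chain(spec$plan, paste(tseq, collapse = ""),
                              seed = spec$seed, entry_id = "target")
  bb <- target$backbone

  homologs <- list(); truth <- list(); meta <- list()
  for (h in seq_len(spec$n_homologs)) {
    hseq <- tseq
    coords <- lapply(bb[c("N", "CA", "C", "O", "CB")], identity)
    mask <- integer(0)
    oc <- spec$outcomes[[h]]
    fixed <- spec$sites
    site_truth <- list()
    for (s in spec$sites) {
      o <- if (!is.null(oc) && as.character(s) %in% names(oc))
        oc[[as.character(s)]] else "conserved"
      kind <- sub(":.*$", "", o)
      par <- sub("^[^:]*:?", "", o)
      t3 <- TRUE; t1 <- TRUE; rf <- FALSE; df <- FALSE
      if (kind == "substituted") {
        hseq[s] <- if (nzchar(par)) par else "R"
        t3 <- FALSE; t1 <- FALSE
      } else if (kind == "shifted") {
        k <- if (nzchar(par)) as.integer(par) else 2L
        s2 <- s + k
        if (s2 < 1 || s2 > n) stop_config("shift outside chain")
        hseq[s] <- "A"; hseq[s2] <- "K"
        # the lysine keeps the target site's spatial position while the
        # rest of the local loop rearranges, so the fragment aligner drops
        # the loop and only spatial inspection recovers the site
        for (f in names(coords)) {
          tmp <- coords[[f]][s, ]
          coords[[f]][s, ] <- coords[[f]][s2, ]
          coords[[f]][s2, ] <- tmp
        }
        win <- setdiff(min(s, s2):max(s, s2), s2)
        for (j in win) {
          kick <- c(2.5 * (-1)^j, 2.5, -2.5 * (-1)^j)
          for (f in names(coords))
            coords[[f]][j, ] <- coords[[f]][j, ] + kick
        }
        fixed <- union(fixed, s2)
        t1 <- FALSE; rf <- TRUE
      } else if (kind == "disordered") {
        mask <- union(mask, max(1, s - 2):min(n, s + 2))
        df <- TRUE
      } else if (kind == "displaced") {
        win <- max(1, s - 1):min(n, s + 1)
        for (f in names(coords))
          coords[[f]][win, ] <- sweep(coords[[f]][win, , drop = FALSE], 2,
                                      c(10, 10, 0), `+`)
        t3 <- FALSE
      } else if (kind != "conserved") {
        stop_config("unknown site outcome: ", o)
      }
      site_truth[[as.character(s)]] <- data.frame(
        homolog = sprintf("syn%02d", h), site_resno = s,
        conserved_3d = t3, conserved_1d = t1,
        discrepancy = classify_discrepancy(t1, t3),
        rescue_flag = rf, disorder_flag = df, stringsAsFactors = FALSE)
    }
    # mutate non-site positions down to the requested identity
    already <- sum(hseq != tseq)
    want_diff <- round(n * (1 - spec$identity[h] / 100))
    pool <- setdiff(which(hseq == tseq), fixed)
    need <- want_diff - already
    if (need > length(pool))
      stop_config(sprintf(
        "requested identity %.1f%% unreachable; achievable >= %.1f%%",
        spec$identity[h], 100 * (1 - (already + length(pool)) / n)))
    if (need > 0) {
      # seeded positions and replacement letters
      picks <- integer(0)
      avail <- pool
      for (q in seq_len(need)) {
        j <- rng(length(avail)); picks <- c(picks, avail[j])
        avail <- avail[-j]
      }
      for (p in picks) {
        repeat {
          r <- aas[rng(19L)]
          if (r != hseq[p]) { hseq[p] <- r; break }
        }
      }
    }
    # hinge: rigid rotation of a domain about the inter-domain boundary
    hg <- if (!is.null(spec$hinge)) spec$hinge[[h]] else NULL
    if (!is.null(hg)) {
      dom <- spec$domains[[hg$domain]]
      idx <- dom[1]:dom[2]
      pivot <- coords$CA[dom[1], ]
      w <- coords$CA[min(dom[2], n), ] - pivot
      axis <- c(w[2], -w[1], 0)
      if (sum(axis^2) < 1e-6) axis <- c(0, 0, 1)
      for (f in names(coords))
        coords[[f]][idx, ] <- .rotate_about(coords[[f]][idx, , drop = FALSE],
                                            pivot, axis, hg$angle)
    }
    # Gaussian coordinate noise (seeded, independent per homolog)
    if (spec$noise_sd > 0) {
      gr <- .seeded_rng(spec$seed * 131 + h)
      for (f in names(coords)) {
        m <- coords[[f]]
        # Box-Muller on the lattice rng for full determinism
        nv <- length(m)
        u1 <- vapply(seq_len(nv), function(i) gr(1e6) / 1e6, 0)
        u2 <- vapply(seq_len(nv), function(i) gr(1e6) / 1e6, 0)
        z <- sqrt(-2 * log(pmax(u1, 1e-9))) * cos(2 * pi * u2)
        coords[[f]] <- m + spec$noise_sd * z
      }
    }
    hbb <- c(coords, list(types = bb$types))
    atoms <- .atoms_from_bb(paste(hseq, collapse = ""), hbb, mask = mask)
    hid <- sprintf("syn%02d", h)
    hch <- new_struct_chain("A", atoms, rep(TRUE, nrow(atoms)),
                            paste(hseq, collapse = ""))
    homologs[[hid]] <- structure(
      list(entry_id = hid, chains = list(A = hch), resolution = NA_real_,
           het = NULL, waters = NULL), class = "structure_model")
    realized <- mean(hseq == tseq) * 100
    meta[[hid]] <- data.frame(
      pdb_id = hid, chain = "A", uniprot_id = sprintf("U%03d", h),
      organism = sprintf("synthetic organism %d", h),
      taxon_group = spec$taxon[h],
      resolution = 1.5 + 0.1 * (h %% 5), is_wildtype = TRUE,
      percent_identity = realized, stringsAsFactors = FALSE)
    truth[[hid]] <- do.call(rbind, site_truth)
  }
  metadata <- do.call(rbind, meta); rownames(metadata) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  fam <- list(target = target, homologs = homologs, metadata = metadata,
              truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb_model(target, file.path(out_dir, "target.pdb"))
    for (hid in names(homologs))
      write_pdb_model(homologs[[hid]], file.path(out_dir,
                                                 paste0(hid, ".pdb")))
    write_fasta(setNames(
      vapply(homologs, function(m) m$chains$A$seqres_sequence, ""),
      names(homologs)), file.path(out_dir, "homologs.fasta"))
    write.table(metadata, file.path(out_dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  fam
}

#' Compare pipeline conservation calls against planted truth
#'
#' @param calls data frame with `homolog_id`, `site_resno`, `conserved_3d`,
#'   `conserved_1d`, `discrepancy`.
#' @param truth truth table from [generate_family()].
#' @return list with `accuracy` (fraction of grid cells where all three
#'   fields match), per-field accuracies, and the 3D confusion counts.
#' @export
evaluate_recovery <- function(calls, truth) {
  key_c <- paste(calls$homolog_id, calls$site_resno)
  key_t <- paste(truth$homolog, truth$site_resno)
  if (!setequal(key_c, key_t) || anyDuplicated(key_c))
    stop_data("calls and truth do not cover the same homolog x site grid")
  t2 <- truth[match(key_c, key_t), ]
  ok3 <- calls$conserved_3d == t2$conserved_3d
  ok1 <- calls$conserved_1d == t2$conserved_1d
  okd <- calls$discrepancy == t2$discrepancy
  conf <- table(factor(calls$conserved_3d, c(FALSE, TRUE)),
                factor(t2$conserved_3d, c(FALSE, TRUE)),
                dnn = c("called", "truth"))
  list(accuracy = mean(ok3 & ok1 & okd),
       accuracy_3d = mean(ok3), accuracy_1d = mean(ok1),
       accuracy_discrepancy = mean(okd), confusion_3d = conf,
       n = nrow(calls))
}
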