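# Structural feature annotation of sites: secondary structure, solvent
# accessibility (Shrake-Rupley), hydrogen bonds, interface and ligand
# contacts.

# dihedral angle (degrees) for points p1-p2-p3-p4 (rows of a matrix)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# backbone atom coordinates per residue: list of N/CA/C matrices (NA rows
# when missing)
.backbone <- function(chain) {
  A <- chain$atoms
  rk <- paste(chain$residues$resno, chain$residues$insert, sep = "|")
  get <- function(name) {
    sub <- A[A$elety == name, , drop = FALSE]
    idx <- match(rk, paste(sub$resno, sub$insert, sep = "|"))
    cbind(sub$x[idx], sub$y[idx], sub$z[idx])
  }
  list(N = get("N"), CA = get("CA"), C = get("C"))
}

#' Assign 3-class secondary structure from backbone geometry
#'
#' Dihedral-window assignment in the style of P-SEA: a residue is a helix
#' candidate when (phi, psi) fall in the alpha window and the Calpha(i) to
#' Calpha(i+3) distance is helix-like; a strand candidate when (phi, psi)
#' fall in the beta window and the Calpha(i)-Calpha(i+3) distance is
#' extended. Helix segments require >= 4 consecutive candidates, strand
#' segments >= 3; everything else is loop (`C`). Residues with missing
#' backbone atoms are labeled `C` with a warning. Labels collapse to the
#' 3-class scheme (H/E/C) used for site classification.
#'
#' @param chain a `struct_chain` with backbone N, CA, C atoms.
#' @return object of class `sse_assignment`: data frame with `resno`,
#'   `insert`, `sse` (H/E/C), `end_flag` (within 2 residues of an H/E
#'   segment terminus).
#' @export
assign_sse <- function(chain) {
  bb <- .backbone(chain)
  n <- nrow(chain$residues)
  if (n < 4) stop_data("need >= 4 residues with backbone atoms")
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !anyNA(c(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])))
      phi[i] <- .dihedral(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < n && !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])))
      psi[i] <- .dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
  }
  if (anyNA(bb$CA) || anyNA(bb$N) || anyNA(bb$C))
    warning("residues with missing backbone atoms labeled C")
  d3 <- rep(NA_real_, n)
  for (i in seq_len(n - 3)) {
    if (!anyNA(c(bb$CA[i, ], bb$CA[i + 3, ])))
      d3[i] <- sqrt(sum((bb$CA[i, ] - bb$CA[i + 3, ])^2))
  }
  in_h <- !is.na(phi) & !is.na(psi) &
    phi >= -115 & phi <= -30 & psi >= -80 & psi <= -5
  in_e <- !is.na(phi) & !is.na(psi) &
    phi >= -170 & phi <= -70 & ((psi >= 80 & psi <= 180) | psi <= -170)
  # distance confirmation where available: helix d(i,i+3) ~ 5, strand ~ 10;
  # terminal residues of a run have no d3 of their own, so accept NA
  h_ok <- in_h & (is.na(d3) | (d3 > 4.2 & d3 < 6.5))
  e_ok <- in_e & (is.na(d3) | d3 > 7.5)
  lab <- rep("C", n)
  lab[.min_runs(h_ok, 4)] <- "H"
  lab[lab == "C" & seq_len(n) %in% .min_runs(e_ok, 3)] <- "E"
  # terminal residues of a dihedral run lack phi (first) / psi (last); grow
  # segments by one where the flanking residue is geometry-compatible
  end_flag <- rep(FALSE, n)
  r <- rle(lab)
  stop_ <- cumsum(r$lengths); start_ <- stop_ - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] %in% c("H", "E")) {
      seg <- start_[k]:stop_[k]
      end_flag[seg[seg <= start_[k] + 1 | seg >= stop_[k] - 1]] <- TRUE
    }
  }
  structure(data.frame(resno = chain$residues$resno,
                       insert = chain$residues$insert,
                       sse = lab, end_flag = end_flag,
                       phi = phi, psi = psi, stringsAsFactors = FALSE),
            class = c("sse_assignment", "data.frame"))
}

# indices belonging to runs of TRUE of at least min_len
.min_runs <- function(x, min_len) {
  r <- rle(x)
  stop_ <- cumsum(r$lengths); start_ <- stop_ - r$lengths + 1
  idx <- integer(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_len)
      idx <- c(idx, start_[k]:stop_[k])
  }
  idx
}

#' Secondary-structure class of one site residue
#'
#' Returns the residue's 3-class label and whether it sits within 2 residues
#' of its segment's terminus (the "end of element" flag used when summarizing
#' site locations).
#'
#' @param resno author residue number of the site.
#' @param sse an `sse_assignment`.
#' @param insert insertion code (default empty).
#' @return list with `class` (`H`/`E`/`C`) and `end_flag`.
#' @export
classify_site_sse <- function(resno, sse, insert = "") {
  i <- which(sse$resno == resno & sse$insert == insert)
  if (length(i) == 0) stop_data("residue ", resno, " not in assignment")
  list(class = sse$sse[i], end_flag = sse$end_flag[i])
}

# van der Waals radii by element (angstroms)
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
          SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73)

# theoretical Gly-X-Gly maximum accessible surface areas (angstrom^2),
# Tien et al. 2013 theoretical values
.MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174, X = 200)

# deterministic quasi-uniform sphere points (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.element_of <- function(atoms) {
  el <- toupper(atoms$elesy)
  bad <- is.na(el) | el == "" | !(el %in% names(.VDW))
  # fall back to first letter of the atom name
  el[bad] <- toupper(substr(gsub("[0-9]", "", atoms$elety[bad]), 1, 1))
  el
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical quadrature: each atom's sphere (van der Waals radius + probe) is
#' sampled with a deterministic quasi-uniform point set; points not buried in
#' any neighboring atom's sphere count as accessible. Chains are selectable,
#' so monomer-context and assembly-context SASA are both computable. Unknown
#' elements fall back to a 1.8 angstrom radius with a warning.
#'
#' @param model a `structure_model`.
#' @param chains chain ids to include (default all); atoms outside are
#'   ignored entirely, giving the isolated-context SASA of the selection.
#' @param probe probe radius in angstroms (default 1.4, water).
#' @param points_per_atom quadrature points per atom (default 960).
#' @param include_het include het-group atoms as occluders (default FALSE).
#' @return object of class `sasa_result`: list with `atoms` (per-atom table
#'   incl. `sasa`), `residues` (per-residue SASA, side-chain SASA and
#'   relative accessibility vs the tabulated Gly-X-Gly maximum, clipped to
#'   \[0, 1.2\]), `probe`, `points_per_atom`.
#' @export
compute_sasa <- function(model, chains = NULL, probe = 1.4,
                         points_per_atom = 960, include_het = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(chains)) chains <- names(model$chains)
  tabs <- lapply(model$chains[chains], function(ch)
    cbind(ch$atoms, chain_id = ch$chain_id))
  A <- do.call(rbind, tabs)
  if (include_het && !is.null(model$het) && nrow(model$het) > 0)
    A <- rbind(A, cbind(model$het, chain_id = model$het$chain))
  el <- .element_of(A)
  unknown <- !(el %in% names(.VDW))
  if (any(unknown))
    warning("unknown element(s) given default 1.8 A radius: ",
            paste(unique(el[unknown]), collapse = ", "))
  r <- unname(.VDW[el]); r[unknown] <- 1.8
  R <- r + probe
  xyz <- as.matrix(A[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .sphere_points(points_per_atom)
  sasa <- numeric(n)
  cutmax <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + cutmax)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        dj <- rowSums(sweep(p, 2, xyz[j, ])^2)
        free <- free & dj > R[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    sasa[i] <- frac * 4 * pi * R[i]^2
  }
  A$sasa <- sasa
  backbone <- A$elety %in% c("N", "CA", "C", "O", "OXT")
  key <- paste(A$chain_id, A$resno, A$insert, sep = "|")
  res <- aggregate(cbind(sasa = A$sasa), list(key = key), sum)
  sck <- aggregate(cbind(sc = ifelse(backbone, 0, A$sasa)),
                   list(key = key), sum)
  first <- !duplicated(key)
  info <- data.frame(key = key[first], chain_id = A$chain_id[first],
                     resno = A$resno[first], insert = A$insert[first],
                     resid = A$resid[first], stringsAsFactors = FALSE)
  res <- merge(merge(info, res, by = "key"), sck, by = "key")
  aa1 <- suppressWarnings(aa3to1(res$resid))
  res$rel_accessibility <- pmin(1.2, pmax(0, res$sasa /
                                            unname(.MAX_ASA[aa1])))
  res <- res[order(res$chain_id, res$resno, res$insert), -1]
  structure(list(atoms = A, residues = res, probe = probe,
                 points_per_atom = points_per_atom),
            class = "sasa_result")
}

#' Is a site surface-exposed?
#'
#' Codifies the visual exposure judgment: exposed iff the residue's relative
#' accessibility in monomer (single-chain) context is at least `threshold`
#' (default 0.20).
#'
#' @param sasa a `sasa_result` computed over the site's chain only.
#' @param chain_id,resno,insert residue address.
#' @param threshold relative-accessibility cutoff.
#' @export
is_exposed <- function(sasa, chain_id, resno, insert = "",
                       threshold = 0.20) {
  r <- sasa$residues
  i <- which(r$chain_id == chain_id & r$resno == resno & r$insert == insert)
  if (length(i) == 0) stop_data("residue not in SASA result")
  r$rel_accessibility[i] >= threshold
}

# all N/O heavy atoms of a model, with context labels
.polar_atoms <- function(model, include_het = TRUE, include_water = TRUE) {
  out <- list()
  for (ch in model$chains) {
    A <- ch$atoms
    el <- .element_of(A)
    k <- el %in% c("N", "O")
    if (any(k)) out[[length(out) + 1]] <-
        cbind(A[k, c("elety", "resid", "resno", "insert", "x", "y", "z")],
              chain_id = ch$chain_id, context = "polymer")
  }
  if (include_het && !is.null(model$het) && nrow(model$het)) {
    A <- model$het; el <- .element_of(A)
    k <- el %in% c("N", "O")
    if (any(k)) out[[length(out) + 1]] <-
        cbind(A[k, c("elety", "resid", "resno", "insert", "x", "y", "z")],
              chain_id = A$chain[k], context = "ligand")
  }
  if (include_water && !is.null(model$waters) && nrow(model$waters)) {
    A <- model$waters; el <- .element_of(A)
    k <- el == "O"
    if (any(k)) out[[length(out) + 1]] <-
        cbind(A[k, c("elety", "resid", "resno", "insert", "x", "y", "z")],
              chain_id = A$chain[k], context = "water")
  }
  do.call(rbind, out)
}

#' Detect direct and water-mediated hydrogen bonds of a site residue
#'
#' Distance-only criterion (crystal structures carry no hydrogens): a direct
#' bond is an N/O donor-acceptor pair within `d_max`; a water-mediated bond
#' requires both donor-water-oxygen and water-oxygen-acceptor legs within
#' `water_leg_max`. Partners are classified as side chain, backbone, ligand
#' or inter-subunit.
#'
#' @param model a `structure_model`.
#' @param chain_id,resno,insert the site residue.
#' @param donor_atoms atom names of the queried donors (default `"NZ"`, the
#'   lysine side-chain amine).
#' @param d_max donor-acceptor cutoff (default 3.5 angstroms).
#' @param water_leg_max per-leg cutoff for water-mediated bonds.
#' @return data frame of bonds: donor atom, partner atom/residue/chain,
#'   distance, `bridging_water` (NA for direct), `partner_class`.
#' @export
detect_hbonds <- function(model, chain_id, resno, insert = "",
                          donor_atoms = "NZ", d_max = 3.5,
                          water_leg_max = 3.5) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop_data("no chain ", chain_id)
  SA <- ch$atoms[ch$atoms$resno == resno & ch$atoms$insert == insert, ,
                 drop = FALSE]
  if (nrow(SA) == 0) stop_data("site residue ", resno, " not in chain")
  D <- SA[SA$elety %in% donor_atoms, , drop = FALSE]
  if (nrow(D) == 0)
    stop_data("site residue lacks donor atom(s): ",
              paste(donor_atoms, collapse = ","))
  P <- .polar_atoms(model)
  # drop the site's own atoms
  own <- P$chain_id == chain_id & P$resno == resno & P$insert == insert &
    P$context == "polymer"
  P <- P[!own, , drop = FALSE]
  classify <- function(p) {
    if (p$context == "ligand") return("ligand")
    if (p$chain_id != chain_id) return("inter-subunit")
    if (p$elety %in% c("N", "CA", "C", "O", "OXT")) return("backbone")
    "side chain"
  }
  bonds <- list()
  for (i in seq_len(nrow(D))) {
    dxyz <- as.numeric(D[i, c("x", "y", "z")])
    dist <- sqrt(rowSums(sweep(as.matrix(P[, c("x", "y", "z")]), 2,
                               dxyz)^2))
    # direct
    hit <- which(dist <= d_max & P$context != "water")
    for (j in hit) {
      bonds[[length(bonds) + 1]] <- data.frame(
        donor = D$elety[i], partner_atom = P$elety[j],
        partner_resid = P$resid[j], partner_resno = P$resno[j],
        partner_chain = P$chain_id[j], distance = dist[j],
        bridging_water = NA_integer_,
        partner_class = classify(P[j, ]), stringsAsFactors = FALSE)
    }
    # water-mediated
    wat <- which(dist <= water_leg_max & P$context == "water")
    for (w in wat) {
      wxyz <- as.numeric(P[w, c("x", "y", "z")])
      d2 <- sqrt(rowSums(sweep(as.matrix(P[, c("x", "y", "z")]), 2,
                               wxyz)^2))
      acc <- which(d2 <= water_leg_max & P$context != "water" &
                     seq_len(nrow(P)) != w)
      for (j in acc) {
        bonds[[length(bonds) + 1]] <- data.frame(
          donor = D$elety[i], partner_atom = P$elety[j],
          partner_resid = P$resid[j], partner_resno = P$resno[j],
          partner_chain = P$chain_id[j], distance = d2[j],
          bridging_water = P$resno[w],
          partner_class = classify(P[j, ]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(bonds)) {
    return(data.frame(donor = character(0), partner_atom = character(0),
                      partner_resid = character(0),
                      partner_resno = integer(0),
                      partner_chain = character(0), distance = numeric(0),
                      bridging_water = integer(0),
                      partner_class = character(0)))
  }
  do.call(rbind, bonds)
}

#' Heavy-atom contact scan of a site residue
#'
#' Scans the site's heavy atoms against other polymer chains, het groups and
#' nucleic-acid chains, returning one record per partner entity with the
#' minimum distance. Used to decide interface membership (any heavy atom of
#' another polymer chain within the cutoff) and ligand/nucleic-acid contacts.
#'
#' @param model a `structure_model`.
#' @param chain_id,resno,insert the site residue.
#' @param cutoff contact cutoff (default 5.0 angstroms).
#' @return data frame: partner id, `type` (`inter-subunit`, `ligand`,
#'   `nucleic acid`), `min_distance`. Empty when nothing is in range.
#' @export
contact_scan <- function(model, chain_id, resno, insert = "", cutoff = 5.0) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop_data("no chain ", chain_id)
  SA <- ch$atoms[ch$atoms$resno == resno & ch$atoms$insert == insert, ,
                 drop = FALSE]
  if (nrow(SA) == 0) stop_data("site residue not found")
  sxyz <- as.matrix(SA[, c("x", "y", "z")])
  nuc <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")
  recs <- list()
  mind <- function(xyz) {
    min(vapply(seq_len(nrow(xyz)), function(i)
      sqrt(min(rowSums(sweep(sxyz, 2, xyz[i, ])^2))), 0))
  }
  for (oc in model$chains) {
    if (oc$chain_id == chain_id) next
    d <- mind(as.matrix(oc$atoms[, c("x", "y", "z")]))
    if (d <= cutoff) recs[[length(recs) + 1]] <- data.frame(
      partner = oc$chain_id, type = "inter-subunit", min_distance = d,
      stringsAsFactors = FALSE)
  }
  if (!is.null(model$het) && nrow(model$het)) {
    H <- model$het
    # nucleic-acid residues recorded as ATOM end up polymer=FALSE here only
    # if unrecognized; classify het residues by name
    key <- paste(H$chain, H$resno, H$resid, sep = "|")
    for (k in unique(key)) {
      sub <- H[key == k, , drop = FALSE]
      d <- mind(as.matrix(sub[, c("x", "y", "z")]))
      if (d <= cutoff) recs[[length(recs) + 1]] <- data.frame(
        partner = paste0(sub$resid[1], sub$resno[1], ":", sub$chain[1]),
        type = if (sub$resid[1] %in% nuc) "nucleic acid" else "ligand",
        min_distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(partner = character(0), type = character(0),
                      min_distance = numeric(0)))
  }
  do.call(rbind, recs)
}

#' Per-site structural feature report
#'
#' Combines secondary-structure class, relative accessibility, interface
#' membership, hydrogen bonds and contacts for a set of site residues on one
#' chain of a model.
#'
#' @param model a `structure_model`.
#' @param chain_id target chain.
#' @param site_resnos author numbers of the site residues.
#' @param exposure_threshold relative-accessibility cutoff for the exposed
#'   flag.
#' @param contact_cutoff,hbond_dmax geometry cutoffs.
#' @return data frame, one row per site.
#' @export
annotate_sites <- function(model, chain_id, site_resnos,
                           exposure_threshold = 0.20, contact_cutoff = 5.0,
                           hbond_dmax = 3.5) {
  ch <- model$chains[[chain_id]]
  sse <- assign_sse(ch)
  sasa <- compute_sasa(model, chains = chain_id)
  rows <- lapply(site_resnos, function(rn) {
    cl <- classify_site_sse(rn, sse)
    i <- which(sasa$residues$resno == rn & sasa$residues$chain_id == chain_id)
    rel <- if (length(i)) sasa$residues$rel_accessibility[i] else NA_real_
    cs <- contact_scan(model, chain_id, rn, cutoff = contact_cutoff)
    hb <- tryCatch(detect_hbonds(model, chain_id, rn, d_max = hbond_dmax),
                   error = function(e) NULL)
    data.frame(resno = rn, sse_class = cl$class, end_flag = cl$end_flag,
               rel_accessibility = rel,
               exposed = !is.na(rel) & rel >= exposure_threshold,
               interface = any(cs$type == "inter-subunit"),
               interface_chains = paste(cs$partner[cs$type ==
                                                     "inter-subunit"],
                                        collapse = ","),
               n_hbonds = if (is.null(hb)) NA_integer_ else nrow(hb),
               ligand_contact = any(cs$type %in% c("ligand",
                                                   "nucleic acid")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
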