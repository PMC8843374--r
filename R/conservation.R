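# Conservation calls: 3D via structural alignment (with rescue and disorder
# fallbacks), 1D via MSA column, discrepancy classification, domain-presence
# filtering and taxon-stratified summaries.

#' Packaged acetylation-site annotations for the E. coli substrate proteins
#'
#' Site table for the five substrate proteins (author numbering on the
#' reference crystal structures): Adk (1ake) K136 by both YfiQ and YiaC and
#' K141/K145/K157/K192/K211 by acetyl phosphate; Icd (1ai2) K4 by YiaC and
#' AcP, K378 by YiaC, K12/K174/K177/K235/K265 by AcP; KatE (1cf9) K56 by
#' YfiQ and YiaC and K64 by YfiQ; Fmt (2fmt) K45/K46 by YfiQ and YiaC; YaaA
#' (5caj) K55 by YfiQ and YiaC.
#'
#' @return data frame with `protein_id`, `resno`, `mechanisms`
#'   (semicolon-separated subset of `KAT:YfiQ`, `KAT:YiaC`, `AcP`).
#' @export
default_site_annotations <- function() {
  load_site_table(system.file("extdata", "sites_ecoli.tsv",
                              package = "acsite3d"))
}

#' Packaged structural-domain definitions for the substrate proteins
#'
#' Residue ranges in author numbering: Adk CORE (1-29, 60-121, 160-214),
#' AMP-binding (30-59), ATP-binding LID (122-159); Icd large (1-124,
#' 321-416), small (125-162, 200-320), clasp (163-199); KatE N-terminal arm
#' (1-127), beta-barrel (128-390), wrapping loop (391-504), helical
#' (505-564), C-terminal (600-753); Fmt Rossmann (1-189), linker (190-208),
#' OB fold (209-314); YaaA HhH motif (35-66), beta-strand motif (187-202,
#' 239-258).
#'
#' @return data frame with `protein_id`, `domain`, `start`, `end`.
#' @export
default_domain_definitions <- function() {
  load_domain_table(system.file("extdata", "domains_ecoli.tsv",
                                package = "acsite3d"))
}

#' Load a site-annotation table
#'
#' @param path TSV with columns `protein_id`, `resno`, `mechanisms`
#'   (semicolon-separated over `KAT:YfiQ`, `KAT:YiaC`, `AcP`).
#' @return validated data frame.
#' @export
load_site_table <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "resno", "mechanisms")
  if (!all(need %in% names(t)))
    stop_data("site table missing column(s): ",
              paste(setdiff(need, names(t)), collapse = ", "))
  mech <- strsplit(t$mechanisms, ";")
  ok <- vapply(mech, function(m)
    length(m) > 0 && all(m %in% c("KAT:YfiQ", "KAT:YiaC", "AcP")), TRUE)
  if (!all(ok))
    stop_data("invalid mechanism set in rows: ",
              paste(which(!ok), collapse = ", "))
  if (anyDuplicated(paste(t$protein_id, t$resno)))
    stop_data("duplicate (protein, residue) site rows")
  t
}

#' Load a structural-domain definition table
#'
#' @param path TSV with columns `protein_id`, `domain`, `start`, `end`.
#' @return validated data frame; ranges must not overlap within a domain.
#' @export
load_domain_table <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(t)))
    stop_data("domain table missing column(s): ",
              paste(setdiff(need, names(t)), collapse = ", "))
  if (any(t$end < t$start)) stop_data("domain range with end < start")
  for (k in unique(paste(t$protein_id, t$domain))) {
    sub <- t[paste(t$protein_id, t$domain) == k, , drop = FALSE]
    if (nrow(sub) > 1) {
      sub <- sub[order(sub$start), ]
      if (any(sub$start[-1] <= sub$end[-nrow(sub)]))
        stop_data("overlapping ranges in domain ", k)
    }
  }
  t
}

# seqres position of an author-numbered residue (via the atom->seqres
# alignment); NA when the chain has no declared sequence
.seqres_pos <- function(chain, seq_index) {
  if (is.na(chain$seqres_sequence)) return(NA_integer_)
  cs <- chain_sequence(chain, "seqres")
  p <- which(cs$atom_index == seq_index)
  if (length(p)) p[1] else NA_integer_
}

#' Call 3D conservation of one site against one homolog
#'
#' Three-step rule. (1) If the site maps to an aligned homolog residue,
#' conserved iff that residue is lysine. (2) Rescue: if the site is unaligned
#' or maps to a non-lysine, unaligned homolog lysines are searched whose
#' Calpha lies within `rescue_cutoff` of the superposed target site Calpha
#' (using the containing block's transform); a hit is conserved with
#' `rescue_flag`. This codifies the manual correction applied when the
#' alignment's sequence output misses a lysine that is plainly present in the
#' structural overlay. (3) Disorder: if the site maps into a homolog
#' coordinate gap, the declared (SEQRES) sequence within
#' `disorder_window` of the gap-interpolated position is inspected; a lysine
#' there is conserved with `disorder_flag`.
#'
#' With `correspondence = "spatial"` the aligned residue is instead read off
#' geometrically: the homolog residue whose Calpha is nearest the superposed
#' target site Calpha (within `rescue_cutoff`) under the alignment's block
#' transforms. Applied to a rigid single-transform alignment this reproduces
#' the superpose-once visual read-off, which misplaces sites on hinged
#' domains.
#'
#' @param site_resno author number of the site on the target chain.
#' @param alignment a `pairwise_struct_alignment`.
#' @param rescue_cutoff Calpha-Calpha cutoff for the rescue rule (default
#'   5.0 angstroms).
#' @param disorder_window residues of declared sequence inspected either side
#'   of the gap-interpolated position (default 2).
#' @param correspondence `"alignment"` (default) or `"spatial"`.
#' @return list of class `conservation_call` with `conserved_3d`,
#'   `rescue_flag`, `disorder_flag`, `aligned_aa`, `aligned_resno`.
#' @export
call_site_3d <- function(site_resno, alignment, rescue_cutoff = 5.0,
                         disorder_window = 2,
                         correspondence = c("alignment", "spatial")) {
  correspondence <- match.arg(correspondence)
  tc <- alignment$target_chain; hc <- alignment$homolog_chain
  ti <- resno_to_index(tc, site_resno)
  if (is.na(ti)) stop_data("site residue ", site_resno,
                           " not in target chain")
  co <- alignment$correspondence
  caT <- chain_ca(tc); caH <- chain_ca(hc)
  out <- list(site_resno = site_resno, homolog_id = alignment$homolog_id,
              homolog_chain = hc$chain_id, aligned_aa = NA_character_,
              aligned_resno = NA_integer_, conserved_3d = FALSE,
              rescue_flag = FALSE, disorder_flag = FALSE)
  if (is.null(co) || nrow(co) == 0) {
    class(out) <- "conservation_call"
    return(out)
  }

  # block transform applicable at the site (containing block, else nearest)
  k <- match(ti, co$target_index)
  blk <- if (!is.na(k)) co$block[k] else
    co$block[which.min(abs(co$target_index - ti))]
  tr <- alignment$blocks[[blk]]

  if (correspondence == "spatial") {
    # superposed homolog Calphas in the target frame; nearest to the site
    okH <- which(!is.na(caH[, 1]))
    sup <- apply_transform(caH[okH, , drop = FALSE], tr$R, tr$t)
    d <- sqrt(rowSums(sweep(sup, 2, caT[ti, ])^2))
    j <- which.min(d)
    if (length(j) && d[j] <= rescue_cutoff) {
      hi <- okH[j]
      out$aligned_aa <- hc$residues$aa1[hi]
      out$aligned_resno <- hc$residues$resno[hi]
      out$conserved_3d <- out$aligned_aa == "K"
    }
    class(out) <- "conservation_call"
    return(out)
  }

  if (!is.na(k)) {
    hi <- co$homolog_index[k]
    out$aligned_aa <- hc$residues$aa1[hi]
    out$aligned_resno <- hc$residues$resno[hi]
    out$conserved_3d <- out$aligned_aa == "K"
    if (out$conserved_3d) {  # rescue never fires on an aligned lysine
      class(out) <- "conservation_call"
      return(out)
    }
  }

  # rescue: unaligned homolog lysines near the superposed site
  if (!is.na(caT[ti, 1])) {
    unaligned <- setdiff(which(hc$residues$aa1 == "K"), co$homolog_index)
    unaligned <- unaligned[!is.na(caH[unaligned, 1])]
    if (length(unaligned)) {
      sup <- apply_transform(caH[unaligned, , drop = FALSE], tr$R, tr$t)
      d <- sqrt(rowSums(sweep(sup, 2, caT[ti, ])^2))
      if (any(d <= rescue_cutoff)) {
        j <- unaligned[which.min(d)]
        out$conserved_3d <- TRUE
        out$rescue_flag <- TRUE
        out$aligned_aa <- "K"
        out$aligned_resno <- hc$residues$resno[j]
        class(out) <- "conservation_call"
        return(out)
      }
    }
  }

  # disorder: site maps into a homolog coordinate gap -> read the declared
  # sequence around the gap-interpolated position
  if (is.na(k) && !is.na(hc$seqres_sequence)) {
    before <- co[co$target_index < ti, , drop = FALSE]
    after <- co[co$target_index > ti, , drop = FALSE]
    anchor <- NULL
    if (nrow(before)) anchor <- before[nrow(before), ]
    else if (nrow(after)) anchor <- after[1, ]
    if (!is.null(anchor)) {
      sp_anchor <- .seqres_pos(hc, anchor$homolog_index)
      if (!is.na(sp_anchor)) {
        sp <- sp_anchor + (ti - anchor$target_index)
        cs <- chain_sequence(hc, "seqres")
        win <- max(1, sp - disorder_window):min(nchar(cs$sequence),
                                                sp + disorder_window)
        letters_ <- strsplit(cs$sequence, "")[[1]][win]
        hitK <- win[letters_ == "K" & !cs$resolved[win]]
        if (length(hitK)) {
          out$conserved_3d <- TRUE
          out$disorder_flag <- TRUE
          out$aligned_aa <- "K"
        }
      }
    }
  }
  class(out) <- "conservation_call"
  out
}

#' Call 1D conservation of one site from an MSA column
#'
#' Conserved iff the homolog row carries a lysine in the column holding the
#' target site. Accepts either an `anchored_msa` or a plain gapped character
#' matrix whose first row is the target (columns indexed by target residue
#' after removing target gaps).
#'
#' @param site_resno author number of the site on the target.
#' @param msa an `anchored_msa`, or a character matrix from
#'   [read_msa_matrix()].
#' @param homolog_id row id to call.
#' @param target_numbering for a plain matrix: author numbers of the target's
#'   non-gap positions (defaults to 1..n).
#' @return logical `conserved_1d`.
#' @export
call_site_1d <- function(site_resno, msa, homolog_id,
                         target_numbering = NULL) {
  if (inherits(msa, "anchored_msa")) {
    col <- which(msa$columns$resno == site_resno)
    if (length(col) == 0) stop_data("site column not found: ", site_resno)
    row <- msa$rows[[homolog_id]]
    if (is.null(row)) stop_data("no MSA row: ", homolog_id)
    return(row$aa[col] == "K")
  }
  m <- as.matrix(msa)
  if (is.null(target_numbering))
    target_numbering <- attr(msa, "target_numbering")
  tgt <- m[1, ]
  nz <- which(tgt != "-")
  if (is.null(target_numbering)) target_numbering <- seq_along(nz)
  col <- nz[match(site_resno, target_numbering)]
  if (is.na(col)) stop_data("site column not found: ", site_resno)
  if (!homolog_id %in% rownames(m)) stop_data("no MSA row: ", homolog_id)
  m[homolog_id, col] == "K"
}

#' Classify the 1D/3D discrepancy of a conservation call
#'
#' `open_star` when the site is conserved by sequence (1D) but not by
#' structure (3D); `filled_star` when conserved by structure but not
#' sequence; `agree` otherwise.
#'
#' @param conserved_1d,conserved_3d logical verdicts.
#' @return one of `"agree"`, `"open_star"`, `"filled_star"`.
#' @export
classify_discrepancy <- function(conserved_1d, conserved_3d) {
  if (is.na(conserved_1d) || is.na(conserved_3d))
    stop_data("both 1D and 3D verdicts required")
  if (conserved_1d && !conserved_3d) return("open_star")
  if (conserved_3d && !conserved_1d) return("filled_star")
  "agree"
}

#' Is a target structural domain present in a homolog?
#'
#' True iff the fraction of target residues of the domain that have an
#' aligned homolog residue reaches `coverage_threshold`. Used to exclude
#' homologs that simply lack the domain from conservation denominators,
#' which would otherwise skew conclusions.
#'
#' @param ranges data frame of author-number ranges (`start`, `end`) for one
#'   domain.
#' @param alignment a `pairwise_struct_alignment`.
#' @param coverage_threshold default 0.7.
#' @export
domain_present <- function(ranges, alignment, coverage_threshold = 0.7) {
  tc <- alignment$target_chain
  resnos <- unlist(mapply(seq, ranges$start, ranges$end, SIMPLIFY = FALSE))
  resnos <- resnos[resnos %in% tc$residues$resno]
  if (length(resnos) == 0) stop_data("empty domain on target chain")
  co <- alignment$correspondence
  if (is.null(co)) return(FALSE)
  mean(resnos %in% co$target_resno) >= coverage_threshold
}

#' Load a homolog metadata table
#'
#' @param path TSV with columns `pdb_id`, `uniprot_id`, `organism`,
#'   `taxon_group`, `resolution`, `is_wildtype`; optional `chain`,
#'   `percent_identity`.
#' @return validated data frame. Unknown taxon labels and duplicate
#'   `pdb_id` rows are errors naming the offenders.
#' @export
load_homolog_table <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "uniprot_id", "organism", "taxon_group", "resolution",
            "is_wildtype")
  if (!all(need %in% names(t)))
    stop_data("homolog table missing column(s): ",
              paste(setdiff(need, names(t)), collapse = ", "))
  ok <- t$taxon_group %in% taxon_groups()
  if (!all(ok))
    stop_data("unknown taxon group(s): ",
              paste(unique(t$taxon_group[!ok]), collapse = ", "))
  if (anyDuplicated(t$pdb_id))
    stop_data("duplicate pdb_id rows: ",
              paste(unique(t$pdb_id[duplicated(t$pdb_id)]), collapse = ", "))
  if (!is.logical(t$is_wildtype)) t$is_wildtype <- t$is_wildtype %in%
      c("TRUE", "true", "1", "yes", "WT", TRUE)
  t
}

#' The closed set of taxon group labels
#' @export
taxon_groups <- function() {
  c("Gram-negative", "Gram-positive", "Gram-variable", "Eukaryote",
    "Archaea", "synthetic")
}

#' Summarize conservation calls by taxon group with domain filtering
#'
#' Per site and taxon group: conserved homologs over homologs passing the
#' site's domain filter. Also renders the per-homolog matrix, ordered by
#' percent identity to the target (descending): `dot` for a site conserved in
#' both 1D and 3D, `open_circle` when the 3D call needed the rescue or
#' disorder fallback, `open_star`/`filled_star` for discrepancies, `blank`
#' when not conserved, `absent` when the domain filter excludes the homolog.
#'
#' @param calls data frame with one row per homolog x site: `homolog_id`,
#'   `site_resno`, `conserved_1d`, `conserved_3d`, `rescue_flag`,
#'   `disorder_flag`, `discrepancy`, `domain_present`.
#' @param metadata homolog metadata from [load_homolog_table()]; must cover
#'   every `homolog_id` (joined on `pdb_id`) and carry `percent_identity`.
#' @param group_by metadata column for stratification (default
#'   `"taxon_group"`).
#' @return list with `summary` (site x group fractions) and `matrix`
#'   (homolog x site symbols, identity-ordered).
#' @export
summarize_conservation <- function(calls, metadata,
                                   group_by = "taxon_group") {
  miss <- setdiff(unique(calls$homolog_id), metadata$pdb_id)
  if (length(miss))
    stop_data("calls without metadata: ", paste(miss, collapse = ", "))
  m <- metadata[match(calls$homolog_id, metadata$pdb_id), ]
  calls$group <- m[[group_by]]
  kept <- calls[calls$domain_present, , drop = FALSE]
  agg <- aggregate(cbind(conserved = kept$conserved_3d,
                         total = rep(1, nrow(kept))),
                   by = list(site_resno = kept$site_resno,
                             group = kept$group), sum)
  agg$fraction <- agg$conserved / agg$total

  symbol <- function(row) {
    if (!row$domain_present) return("absent")
    if (row$discrepancy == "open_star") return("open_star")
    if (row$discrepancy == "filled_star") return("filled_star")
    if (row$conserved_3d && (row$rescue_flag || row$disorder_flag))
      return("open_circle")
    if (row$conserved_3d) return("dot")
    "blank"
  }
  calls$symbol <- vapply(seq_len(nrow(calls)), function(i)
    symbol(calls[i, ]), "")
  ids <- unique(calls$homolog_id)
  pid <- metadata$percent_identity[match(ids, metadata$pdb_id)]
  ids <- ids[order(-pid)]
  sites <- sort(unique(calls$site_resno))
  mat <- matrix("absent", nrow = length(ids), ncol = length(sites),
                dimnames = list(ids, paste0("K", sites)))
  for (i in seq_len(nrow(calls))) {
    mat[calls$homolog_id[i], paste0("K", calls$site_resno[i])] <-
      calls$symbol[i]
  }
  list(summary = agg, matrix = mat)
}
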