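# Homolog metadata management: representative-structure selection, identity
# filtering, and taxon tallies.

#' Select one representative structure per UniProt accession
#'
#' Wild-type records are preferred; among them the best (numerically lowest)
#' resolution wins; ties break to the lexicographically smallest PDB id.
#' Records without a resolution compete last. Groups with no wild-type entry
#' fall back to the best-resolution non-wild-type record with a warning. The
#' selection is deterministic and invariant to input order.
#'
#' @param records homolog metadata data frame (see [load_homolog_table()]).
#' @return data frame with one row per `uniprot_id`.
#' @export
select_representative <- function(records) {
  if (nrow(records) == 0) return(records)
  pick <- function(sub) {
    wt <- sub[sub$is_wildtype, , drop = FALSE]
    if (nrow(wt) == 0) {
      warning("no wild-type structure for ", sub$uniprot_id[1],
              "; using best-resolution non-WT")
      wt <- sub
    }
    res <- wt$resolution
    res[is.na(res)] <- Inf
    wt <- wt[order(res, wt$pdb_id), , drop = FALSE]
    wt[1, , drop = FALSE]
  }
  groups <- split(records, records$uniprot_id)
  out <- do.call(rbind, lapply(groups[sort(names(groups))], pick))
  rownames(out) <- NULL
  out
}

#' Filter homologs by percent identity to the target
#'
#' Retains records with `percent_identity >= threshold` (boundary inclusive:
#' "30% or greater"). Missing identities are computed from sequences via
#' [global_align()] when `sequences` is supplied.
#'
#' @param records homolog metadata with a `percent_identity` column (may be
#'   NA).
#' @param threshold identity threshold in percent (default 30).
#' @param target_sequence,sequences optional: target sequence and named
#'   vector of homolog sequences (by `pdb_id`) used to fill missing
#'   identities.
#' @return filtered data frame.
#' @export
identity_filter <- function(records, threshold = 30,
                            target_sequence = NULL, sequences = NULL) {
  if (nrow(records) == 0) return(records)
  if (!"percent_identity" %in% names(records))
    records$percent_identity <- NA_real_
  na <- is.na(records$percent_identity)
  if (any(na) && !is.null(sequences) && !is.null(target_sequence)) {
    for (i in which(na)) {
      s <- sequences[[records$pdb_id[i]]]
      if (!is.null(s))
        records$percent_identity[i] <- percent_identity(target_sequence, s)
    }
  }
  records[!is.na(records$percent_identity) &
            records$percent_identity >= threshold, , drop = FALSE]
}

#' Tally structures by taxon group
#'
#' Counts structures and distinct organisms per taxon group, mirroring a
#' dataset-overview table (one column per protein when `by_protein` names a
#' column).
#'
#' @param records homolog metadata.
#' @param by_protein optional column name splitting the tally by target
#'   protein.
#' @return data frame with `taxon_group`, `n_structures`, `n_organisms`
#'   (distinct organism strings), plus `protein` when split.
#' @export
tally_by_taxon <- function(records, by_protein = NULL) {
  one <- function(sub, label = NULL) {
    agg <- lapply(split(sub, sub$taxon_group), function(g)
      data.frame(taxon_group = g$taxon_group[1],
                 n_structures = nrow(g),
                 n_organisms = length(unique(g$organism)),
                 stringsAsFactors = FALSE))
    out <- do.call(rbind, agg)
    total <- data.frame(taxon_group = "Total", n_structures = nrow(sub),
                        n_organisms = length(unique(sub$organism)))
    out <- rbind(out, total)
    if (!is.null(label)) out$protein <- label
    rownames(out) <- NULL
    out
  }
  if (is.null(by_protein)) return(one(records))
  do.call(rbind, lapply(split(records, records[[by_protein]]), function(g)
    one(g, g[[by_protein]][1])))
}
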