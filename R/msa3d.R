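# Structure-anchored multiple sequence alignment: compile many pairwise
# target-homolog structural alignments into one MSA whose columns are the
# target chain's residues.

#' Build a target-anchored multiple alignment from pairwise structural
#' alignments
#'
#' One column per target residue, in target order. Each homolog's residues
#' aligned to a target residue occupy that column; homolog residues aligned
#' outside the target (insertions relative to the target) are dropped and
#' counted per homolog in `dropped_insertions`, so the information loss is
#' measurable. Adding or removing a homolog never changes existing rows: the
#' anchoring is target-only, with no progressive re-gapping.
#'
#' @param target a `struct_chain` shared by all alignments.
#' @param alignments list of `pairwise_struct_alignment`, one per homolog;
#'   names (or `homolog_id:chain`) are used as row ids.
#' @return object of class `anchored_msa` with `target_id`, `columns`
#'   (data frame: `resno`, `insert`, `aa`), `rows` (list of per-homolog
#'   `aa` and `resno` vectors over the columns) and `dropped_insertions`.
#' @export
build_anchored_msa <- function(target, alignments) {
  ncol_ <- nrow(target$residues)
  columns <- data.frame(resno = target$residues$resno,
                        insert = target$residues$insert,
                        aa = target$residues$aa1, stringsAsFactors = FALSE)
  rows <- list(); dropped <- integer(0)
  ids <- character(0)
  for (al in alignments) {
    if (!identical(al$target_chain$atom_sequence, target$atom_sequence) ||
        !identical(al$target_chain$chain_id, target$chain_id))
      stop_data("alignment does not share the anchored target chain")
    id <- paste0(al$homolog_id, "_", al$homolog_chain$chain_id)
    if (id %in% ids)
      stop_data("two alignments for the same homolog id: ", id)
    ids <- c(ids, id)
    aa <- rep("-", ncol_); num <- rep(NA_integer_, ncol_)
    co <- al$correspondence
    if (!is.null(co) && nrow(co)) {
      aa[co$target_index] <- co$homolog_aa
      num[co$target_index] <- co$homolog_resno
    }
    # insertions = homolog residues not aligned to any target column
    n_hom <- nrow(al$homolog_chain$residues)
    dropped[id] <- n_hom - sum(!is.na(num))
    rows[[id]] <- list(aa = aa, resno = num)
  }
  structure(list(target_id = paste0(
    if (length(alignments)) alignments[[1]]$target_id else "target",
    "_", target$chain_id),
    target = target, columns = columns, rows = rows,
    dropped_insertions = dropped), class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat("anchored_msa:", x$target_id, "-", nrow(x$columns), "columns,",
      length(x$rows), "homolog row(s)\n")
  invisible(x)
}

#' Recover one homolog's pairwise correspondence from an anchored MSA
#'
#' Round-trip accessor: reading a homolog row against the target row must
#' reproduce exactly that homolog's pairwise residue correspondence.
#'
#' @param msa an `anchored_msa`.
#' @param id homolog row id.
#' @return data frame with `target_resno`, `homolog_resno`, `homolog_aa`.
#' @export
msa_row_correspondence <- function(msa, id) {
  row <- msa$rows[[id]]
  if (is.null(row)) stop_data("no MSA row: ", id)
  k <- which(row$aa != "-")
  data.frame(target_resno = msa$columns$resno[k],
             homolog_resno = row$resno[k], homolog_aa = row$aa[k],
             stringsAsFactors = FALSE)
}

#' Export an anchored MSA as gapped FASTA plus a metadata table
#'
#' All rows have equal length (the target column count). The sidecar table
#' lists per-homolog coverage and dropped insertion counts.
#'
#' @param msa an `anchored_msa`.
#' @param fasta_path,meta_path optional output paths; when `NULL` the text
#'   and data frame are returned.
#' @return list with `fasta` (text or path) and `metadata` (data frame).
#' @export
export_msa <- function(msa, fasta_path = NULL, meta_path = NULL) {
  if (nrow(msa$columns) == 0) stop_data("empty MSA")
  recs <- c(setNames(paste(msa$columns$aa, collapse = ""), msa$target_id),
            vapply(msa$rows, function(r) paste(r$aa, collapse = ""), ""))
  if (length(msa$rows) == 0)
    warning("MSA has zero homolog rows; writing target row only")
  meta <- data.frame(
    id = names(msa$rows),
    coverage = vapply(msa$rows, function(r) mean(r$aa != "-"), 0),
    dropped_insertions = as.integer(msa$dropped_insertions[names(msa$rows)]),
    stringsAsFactors = FALSE, row.names = NULL)
  fa <- write_fasta(recs, fasta_path)
  if (!is.null(meta_path))
    write.table(meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(fasta = fa, metadata = meta)
}

#' Build a target-anchored multiple alignment from sequences alone
#'
#' The 1D counterpart of [build_anchored_msa()]: each homolog sequence is
#' globally aligned to the target sequence and projected onto the target's
#' positions (one column per target residue; homolog insertions dropped).
#' This is the sequence-only evidence that 3D calls are compared against
#' when classifying open- and filled-star discrepancies.
#'
#' @param target_seq target sequence (string).
#' @param homolog_seqs named character vector of homolog sequences
#'   (declared/SEQRES sequences where available, so residues disordered in
#'   the coordinates still count).
#' @param target_id row name for the target (default `"target"`).
#' @param target_numbering author numbers of the target positions (default
#'   1..n), stored as an attribute consumed by [call_site_1d()].
#' @param ... passed to [global_align()].
#' @return character matrix (rows = target + homologs) with attribute
#'   `target_numbering`.
#' @export
build_sequence_msa <- function(target_seq, homolog_seqs,
                               target_id = "target",
                               target_numbering = NULL, ...) {
  n <- nchar(target_seq)
  if (is.null(target_numbering)) target_numbering <- seq_len(n)
  rows <- matrix("-", nrow = 1 + length(homolog_seqs), ncol = n,
                 dimnames = list(c(target_id, names(homolog_seqs)), NULL))
  rows[1, ] <- strsplit(target_seq, "")[[1]]
  for (id in names(homolog_seqs)) {
    al <- global_align(target_seq, homolog_seqs[[id]], ...)
    hs <- strsplit(homolog_seqs[[id]], "")[[1]]
    rows[id, al$pairs[, 1]] <- hs[al$pairs[, 2]]
  }
  attr(rows, "target_numbering") <- target_numbering
  rows
}

#' Rebuild anchored-MSA rows from an exported gapped FASTA
#'
#' @param fasta path or FASTA text from [export_msa()].
#' @return character matrix (rows = records, columns = MSA columns).
#' @export
read_msa_matrix <- function(fasta) {
  recs <- read_fasta(fasta)
  n <- unique(nchar(recs))
  if (length(n) != 1) stop_data("gapped FASTA rows have unequal lengths")
  do.call(rbind, lapply(recs, function(s) strsplit(s, "")[[1]]))
}
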