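# Structure input/output: hierarchical structure model on top of bio3d's
# PDB/mmCIF readers, plus FASTA handling and a minimal PDB serializer.

# 3-letter -> 1-letter amino acid code, including common modified residues
# mapped to their parent amino acid (the original 3-letter name is kept on the
# residue record).
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # modified residues -> parent
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", MLY = "K", ALY = "K", KCX = "K",
  CSO = "C", CME = "C", CSD = "C", HYP = "P", PCA = "E", FME = "M", M3L = "K"
)

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

aa3to1 <- function(resid) {
  out <- unname(.AA3TO1[resid])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown residue name(s) mapped to 'X': ",
            paste(unique(resid[unknown]), collapse = ", "))
    out[unknown] <- "X"
  }
  out
}

#' Parse a protein structure into a hierarchical model
#'
#' Reads PDB (fixed-column) or mmCIF content and returns a `structure_model`:
#' a list of chains, each holding per-atom and per-residue tables, the
#' one-letter sequence of resolved polymer residues (`atom_sequence`), the
#' declared SEQRES sequence when present, and a `numbering_map` from sequence
#' index to author residue number. Waters and het groups are separated from
#' polymer residues. For atoms with alternate locations only the
#' highest-occupancy conformer is kept (ties broken by alphabetically first
#' altloc); for multi-model files only model 1 is used. Author residue
#' numbering (with insertion codes) is preserved throughout, because
#' modification sites are cited in author numbering.
#'
#' @param input path to a structure file, or the file content as a single
#'   string (detected by the presence of newlines).
#' @param format_hint `"pdb"`, `"cif"`, or `"auto"` (extension/content based).
#' @param entry_id identifier stored on the model; defaults to the file stem.
#' @return an object of class `structure_model` with elements `entry_id`,
#'   `chains` (named list of `struct_chain`), `resolution` (angstroms or `NA`)
#'   and `het` (data frame of non-water, non-polymer residues).
#' @export
parse_structure <- function(input, format_hint = c("auto", "pdb", "cif"),
                            entry_id = NULL) {
  format_hint <- match.arg(format_hint)
  is_text <- grepl("\n", input, fixed = TRUE)
  if (is_text) {
    ext <- if (format_hint == "cif" ||
               (format_hint == "auto" && grepl("^data_|\\n_atom_site", input)))
      ".cif" else ".pdb"
    path <- tempfile(fileext = ext)
    writeLines(sub("\n$", "", input), path)
    on.exit(unlink(path))
  } else {
    path <- input
    if (!file.exists(path)) stop_data("structure file not found: ", path)
  }
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (is.null(entry_id)) {
    entry_id <- if (is_text) "model" else sub("\\.[^.]+$", "", basename(path))
  }

  pdb <- tryCatch(
    # bio3d warns when optional records (helix/sheet annotations) are
    # absent; those are recomputed here, so the warnings carry no signal
    if (fmt == "cif") suppressWarnings(bio3d::read.cif(path,
                                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          multi = FALSE)),
    error = function(e) stop_data("failed to parse ", fmt, " input: ",
                                  conditionMessage(e))
  )
  atoms <- pdb$atom
  if (nrow(atoms) == 0) stop_data("no atoms in input ", entry_id)

  # resolution: bio3d does not expose it uniformly; grep the raw text
  resolution <- NA_real_
  txt <- readLines(path, warn = FALSE)
  if (fmt == "pdb") {
    rl <- grep("^REMARK   2 RESOLUTION", txt, value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
  } else {
    rl <- grep("_reflns\\.d_resolution_high|_refine\\.ls_d_res_high", txt,
               value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
  }

  # altloc policy: per (chain, resno, insert, atom name) keep the
  # highest-occupancy conformer; tie -> alphabetically first altloc
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }

  is_water <- atoms$resid %in% .WATER_NAMES
  is_aa <- atoms$resid %in% names(.AA3TO1)
  # polymer: amino-acid residues recorded as ATOM (HETATM amino acids inside a
  # polymer chain, e.g. MSE, are also polymer)
  is_polymer <- is_aa & !is_water & (atoms$type == "ATOM" | is_aa)

  seqres <- pdb$seqres
  chains <- list()
  for (ch in sort(unique(atoms$chain[is_polymer | is_water | !is_polymer]))) {
    sel <- atoms$chain == ch
    ca <- atoms[sel, , drop = FALSE]
    pw <- is_polymer[sel]
    if (!any(pw)) next  # water/het-only chains live in $het
    sr <- if (!is.null(seqres) && any(names(seqres) == ch)) {
      paste(aa3to1(unname(seqres[names(seqres) == ch])), collapse = "")
    } else NA_character_
    chains[[ch]] <- new_struct_chain(ch, ca, pw, sr)
  }
  if (length(chains) == 0) stop_data("no polymer chains in input ", entry_id)

  het <- atoms[!is_polymer & !is_water, , drop = FALSE]
  structure(list(entry_id = entry_id, chains = chains,
                 resolution = resolution,
                 het = het, waters = atoms[is_water, , drop = FALSE]),
            class = "structure_model")
}

# Build a struct_chain from a per-chain atom table. `polymer` flags which
# atom rows belong to polymer residues.
new_struct_chain <- function(chain_id, atoms, polymer, seqres_sequence = NA) {
  pa <- atoms[polymer, , drop = FALSE]
  rk <- paste(pa$resno, pa$insert, sep = "|")
  first <- !duplicated(rk)
  residues <- data.frame(
    resno = pa$resno[first], insert = pa$insert[first],
    resid = pa$resid[first], stringsAsFactors = FALSE
  )
  residues$aa1 <- suppressWarnings(aa3to1(residues$resid))
  residues$is_water <- FALSE
  residues$is_polymer <- TRUE
  if (anyDuplicated(paste(residues$resno, residues$insert)))
    stop_data("duplicate (resno, insertion) in chain ", chain_id)
  atom_sequence <- paste(residues$aa1, collapse = "")
  numbering_map <- data.frame(seq_index = seq_len(nrow(residues)),
                              resno = residues$resno,
                              insert = residues$insert,
                              stringsAsFactors = FALSE)
  structure(list(chain_id = chain_id, atoms = pa, residues = residues,
                 atom_sequence = atom_sequence,
                 seqres_sequence = seqres_sequence,
                 numbering_map = numbering_map),
            class = "struct_chain")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$entry_id, "-", length(x$chains), "chain(s):",
      paste(names(x$chains), collapse = ","),
      if (!is.na(x$resolution)) sprintf("(%.2f A)", x$resolution) else "",
      "\n")
  invisible(x)
}

#' @export
print.struct_chain <- function(x, ...) {
  cat("chain", x$chain_id, "-", nrow(x$residues), "residues\n")
  invisible(x)
}

#' Extract a chain sequence with its numbering map
#'
#' With `source = "atom"` returns the sequence of resolved polymer residues
#' and the map from sequence position to author residue number (unresolved
#' residues are simply absent). With `source = "seqres"` returns the full
#' declared sequence with a `resolved` flag per position, obtained by aligning
#' the resolved sequence into the declared one; this is what lets a site that
#' is disordered in the coordinates still be read from the linear sequence.
#'
#' @param chain a `struct_chain`.
#' @param source `"atom"` or `"seqres"`.
#' @return list with `sequence` (string), and either `numbering_map`
#'   (atom source) or `resolved` + `atom_index` per position (seqres source).
#' @export
chain_sequence <- function(chain, source = c("atom", "seqres")) {
  source <- match.arg(source)
  if (!inherits(chain, "struct_chain")) stop_data("not a struct_chain")
  if (nrow(chain$residues) == 0) stop_data("chain has no polymer residues")
  if (source == "atom") {
    return(list(sequence = chain$atom_sequence,
                numbering_map = chain$numbering_map))
  }
  if (is.na(chain$seqres_sequence))
    stop_data("chain ", chain$chain_id, " has no declared sequence")
  sq <- chain$seqres_sequence
  al <- global_align(chain$atom_sequence, sq)
  resolved <- logical(nchar(sq))
  atom_index <- rep(NA_integer_, nchar(sq))
  resolved[al$pairs[, 2]] <- TRUE
  atom_index[al$pairs[, 2]] <- al$pairs[, 1]
  list(sequence = sq, resolved = resolved, atom_index = atom_index)
}

# author number -> sequence index helper
resno_to_index <- function(chain, resno, insert = "") {
  nm <- chain$numbering_map
  i <- which(nm$resno == resno & nm$insert == insert)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Read FASTA records
#'
#' @param input path or FASTA text (detected by a leading `>`). Lowercase
#'   letters are upper-cased with a warning; gap characters `-` are preserved.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(input) {
  if (grepl("^>", input)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", input), path)
    on.exit(unlink(path))
  } else path <- input
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop_data("duplicate FASTA ids: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(ss)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase letters in FASTA input upper-cased")
    seqs <- toupper(seqs)
  }
  setNames(seqs, ids)
}

#' Write FASTA records (60-column wrap)
#'
#' @param records named character vector; names must be non-empty and unique.
#' @param path output path; when `NULL` the FASTA text is returned invisibly.
#' @export
write_fasta <- function(records, path = NULL) {
  if (length(records) == 0 || is.null(names(records)) ||
      any(names(records) == ""))
    stop_data("FASTA records must be a non-empty named vector")
  if (anyDuplicated(names(records)))
    stop_data("duplicate FASTA ids on write")
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60),
                                              nchar(s))))
  }))
  if (is.null(path)) return(invisible(paste0(paste(lines, collapse = "\n"),
                                             "\n")))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a structure model to minimal PDB format
#'
#' Writes SEQRES (when declared sequences are present), ATOM/HETATM records
#' with author numbering, occupancies and altlocs, and a REMARK 2 resolution
#' line when known. Coordinates are written with 3 decimals, so a
#' serialize-parse round trip preserves them to 1e-3 A.
#'
#' @param model a `structure_model`.
#' @param path output path; when `NULL` returns the PDB text.
#' @export
write_pdb_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  out <- character(0)
  if (!is.na(model$resolution)) {
    out <- c(out, sprintf(
      "REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", model$resolution))
  }
  aa1to3 <- setNames(names(.AA3TO1)[1:20], unname(.AA3TO1[1:20]))
  for (ch in model$chains) {
    if (!is.na(ch$seqres_sequence)) {
      res3 <- aa1to3[strsplit(ch$seqres_sequence, "")[[1]]]
      res3[is.na(res3)] <- "UNK"
      n <- length(res3)
      for (k in seq_len(ceiling(n / 13))) {
        idx <- ((k - 1) * 13 + 1):min(k * 13, n)
        out <- c(out, sprintf("SEQRES %3d %s %4d  %s", k, ch$chain_id, n,
                              paste(sprintf("%-3s", res3[idx]),
                                    collapse = " ")))
      }
    }
  }
  serial <- 0L
  fmt_atom <- function(rec, a) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial,
            ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
            substr(a$alt, 1, 1), a$resid, a$chain, a$resno,
            substr(a$insert, 1, 1), a$x, a$y, a$z, a$o,
            if (is.null(a$b) || is.na(a$b)) 0 else a$b,
            if (is.null(a$elesy) || is.na(a$elesy)) "" else a$elesy)
  }
  for (ch in model$chains) {
    A <- ch$atoms
    for (i in seq_len(nrow(A))) out <- c(out, fmt_atom("ATOM", A[i, ]))
    out <- c(out, "TER")
  }
  for (tab in list(model$het, model$waters)) {
    if (!is.null(tab) && nrow(tab) > 0) {
      for (i in seq_len(nrow(tab))) out <- c(out, fmt_atom("HETATM",
                                                           tab[i, ]))
    }
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(path)
}

# Ca coordinate matrix for a chain (rows in residue order, NA rows for
# residues lacking Ca)
chain_ca <- function(chain) {
  A <- chain$atoms
  ca <- A[A$elety == "CA", , drop = FALSE]
  key <- paste(ca$resno, ca$insert, sep = "|")
  rk <- paste(chain$residues$resno, chain$residues$insert, sep = "|")
  idx <- match(rk, key)
  m <- cbind(ca$x[idx], ca$y[idx], ca$z[idx])
  rownames(m) <- rk
  m
}
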