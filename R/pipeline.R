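# End-to-end pipeline: load structures -> all-chain flexible alignments ->
# best-chain selection -> anchored MSA -> 3D + 1D conservation calls ->
# discrepancy classification -> domain filtering -> feature annotation ->
# taxon summaries -> report bundle on disk.

#' Assemble and validate a pipeline configuration
#'
#' Either pass a YAML file (`path`) or the fields directly. Thresholds must
#' be positive; referenced files must exist at run time.
#'
#' @param path optional YAML config file; explicit arguments override it.
#' @param target path to the target structure (PDB/mmCIF).
#' @param homolog_dir directory of homolog structures.
#' @param metadata,sites,domains paths to the homolog metadata, site
#'   annotation and domain definition TSVs (`domains` optional).
#' @param out output directory.
#' @param mode `"flexible"` or `"rigid"`.
#' @param target_protein protein_id selecting rows of the site/domain
#'   tables; defaults to the target file stem.
#' @param import_msa optional externally produced gapped FASTA used for the
#'   1D calls instead of the internal structure-anchored MSA.
#' @param fragment_length,max_twists,gap_open,gap_extend,twist_penalty
#'   aligner parameters.
#' @param rescue_cutoff,disorder_window,coverage_threshold conservation
#'   parameters.
#' @param exposure_threshold,hbond_dmax,contact_cutoff feature thresholds.
#' @param identity_threshold minimum percent identity for homolog inclusion.
#' @param seed integer seed recorded in the run log.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, target = NULL, homolog_dir = NULL,
                            metadata = NULL, sites = NULL, domains = NULL,
                            out = NULL, mode = "flexible",
                            target_protein = NULL, import_msa = NULL,
                            fragment_length = 8, max_twists = 5,
                            gap_open = 5, gap_extend = 0.5,
                            twist_penalty = 15, rescue_cutoff = 5.0,
                            disorder_window = 2, coverage_threshold = 0.7,
                            exposure_threshold = 0.20, hbond_dmax = 3.5,
                            contact_cutoff = 5.0, identity_threshold = 30,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$path <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    y <- yaml::read_yaml(path)
    for (k in names(y)) if (is.null(cfg[[k]]) ||
                            identical(cfg[[k]], formals(pipeline_config)[[k]]))
      cfg[[k]] <- y[[k]]
  }
  for (k in c("target", "homolog_dir", "metadata", "sites", "out"))
    if (is.null(cfg[[k]])) stop_config("missing config field: ", k)
  for (k in c("fragment_length", "max_twists", "rescue_cutoff",
              "coverage_threshold", "exposure_threshold", "hbond_dmax",
              "contact_cutoff"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop_config("threshold must be positive: ", k)
  if (!cfg$mode %in% c("flexible", "rigid"))
    stop_config("mode must be flexible or rigid")
  for (k in c("target", "metadata", "sites"))
    if (!file.exists(cfg[[k]])) stop_config("file not found: ", cfg[[k]])
  if (!is.null(cfg$domains) && !file.exists(cfg$domains))
    stop_config("file not found: ", cfg$domains)
  if (!dir.exists(cfg$homolog_dir))
    stop_config("homolog directory not found: ", cfg$homolog_dir)
  if (is.null(cfg$target_protein))
    cfg$target_protein <- sub("\\.[^.]+$", "", basename(cfg$target))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full conservation pipeline
#'
#' Executes the whole workflow and writes `calls.tsv`, `matrix.tsv`,
#' `taxon_summary.tsv`, `msa3d.fasta`, `features.tsv` and `run.json` (the
#' resolved parameter set, seed and per-stage tallies) into the output
#' directory. A run with zero homologs produces a target-only report with a
#' warning. Reruns with the same config and seed are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @return invisible list with the in-memory results (`selections`, `msa`,
#'   `calls`, `summary`, `features`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("not a pipeline_config")
  set.seed(config$seed)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  target <- parse_structure(config$target)
  # target chain is chain A by convention
  tchain <- target$chains[["A"]]
  if (is.null(tchain)) tchain <- target$chains[[1]]

  sites_tab <- load_site_table(config$sites)
  sites_tab <- sites_tab[sites_tab$protein_id == config$target_protein, ,
                         drop = FALSE]
  if (nrow(sites_tab) == 0)
    stop_data("no sites for protein ", config$target_protein)
  domains_tab <- NULL
  if (!is.null(config$domains)) {
    domains_tab <- load_domain_table(config$domains)
    domains_tab <- domains_tab[domains_tab$protein_id ==
                                 config$target_protein, , drop = FALSE]
  }
  metadata <- load_homolog_table(config$metadata)

  files <- list.files(config$homolog_dir,
                      pattern = "\\.(pdb|cif)$", full.names = TRUE)
  files <- files[sub("\\.[^.]+$", "", basename(files)) %in% metadata$pdb_id]

  # stage 1-2: all-chain alignment + best-chain selection
  selections <- list()
  for (f in sort(files)) {
    hid <- sub("\\.[^.]+$", "", basename(f))
    hom <- parse_structure(f)
    als <- align_all_chains(tchain, hom, mode = config$mode,
                            fragment_length = config$fragment_length,
                            max_twists = config$max_twists,
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend,
                            twist_penalty = config$twist_penalty)
    sel <- tryCatch(select_best_chain(als), error = function(e) NULL)
    if (!is.null(sel)) selections[[hid]] <- sel
  }
  # identity filter on the aligned sequences
  tseq <- tchain$atom_sequence
  metadata$percent_identity <- vapply(metadata$pdb_id, function(id) {
    if (!is.null(metadata$percent_identity) &&
        !is.na(metadata$percent_identity[metadata$pdb_id == id][1]))
      return(metadata$percent_identity[metadata$pdb_id == id][1])
    sel <- selections[[id]]
    if (is.null(sel)) return(NA_real_)
    percent_identity(tseq, sel$alignment$homolog_chain$atom_sequence)
  }, 0)
  keep <- metadata$pdb_id[!is.na(metadata$percent_identity) &
                            metadata$percent_identity >=
                            config$identity_threshold]
  selections <- selections[names(selections) %in% keep]
  if (length(selections) == 0)
    warning("zero homologs after filtering; target-only report")

  # stage 3: anchored MSA
  msa <- build_anchored_msa(tchain,
                            lapply(selections, function(s) s$alignment))
  ex <- export_msa(msa, file.path(config$out, "msa3d.fasta"),
                   file.path(config$out, "msa3d_meta.tsv"))

  # 1D path: imported external MSA when given, else an internally built
  # sequence MSA over the declared (SEQRES, falling back to atom) sequences
  if (!is.null(config$import_msa)) {
    msa_1d <- read_msa_matrix(config$import_msa)
    if (is.null(attr(msa_1d, "target_numbering")))
      attr(msa_1d, "target_numbering") <- tchain$residues$resno
  } else {
    hseqs <- vapply(selections, function(s) {
      hc <- s$alignment$homolog_chain
      if (!is.na(hc$seqres_sequence)) hc$seqres_sequence
      else hc$atom_sequence
    }, "")
    msa_1d <- build_sequence_msa(tchain$atom_sequence, hseqs,
                                 target_numbering =
                                   tchain$residues$resno)
  }

  # stage 4-6: conservation calls + discrepancies + domain filter
  calls <- list()
  for (hid in names(selections)) {
    al <- selections[[hid]]$alignment
    for (i in seq_len(nrow(sites_tab))) {
      s <- sites_tab$resno[i]
      c3 <- call_site_3d(s, al, rescue_cutoff = config$rescue_cutoff,
                         disorder_window = config$disorder_window,
                         correspondence = if (config$mode == "rigid")
                           "spatial" else "alignment")
      c1 <- call_site_1d(s, msa_1d, hid)
      dp <- if (!is.null(domains_tab) && nrow(domains_tab)) {
        dom <- .domain_of_site(domains_tab, s)
        if (is.null(dom)) TRUE
        else domain_present(dom, al, config$coverage_threshold)
      } else TRUE
      calls[[length(calls) + 1]] <- data.frame(
        homolog_id = hid, site_resno = s,
        aligned_aa = c3$aligned_aa, aligned_resno = c3$aligned_resno,
        conserved_3d = c3$conserved_3d, rescue_flag = c3$rescue_flag,
        disorder_flag = c3$disorder_flag, conserved_1d = c1,
        discrepancy = classify_discrepancy(c1, c3$conserved_3d),
        domain_present = dp, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(homolog_id = character(0), site_resno = integer(0),
               conserved_3d = logical(0), conserved_1d = logical(0),
               discrepancy = character(0), domain_present = logical(0))

  # stage 7: feature annotation of the target sites
  feats <- annotate_sites(target, tchain$chain_id, sites_tab$resno,
                          exposure_threshold = config$exposure_threshold,
                          contact_cutoff = config$contact_cutoff,
                          hbond_dmax = config$hbond_dmax)
  feats <- cbind(protein_id = config$target_protein, feats,
                 mechanisms = sites_tab$mechanisms[match(feats$resno,
                                                         sites_tab$resno)])

  # stage 8: taxon summaries
  summ <- if (nrow(calls)) summarize_conservation(calls, metadata) else
    list(summary = data.frame(), matrix = matrix(nrow = 0, ncol = 0))

  .write_tsv <- function(x, f) write.table(
    x, file.path(config$out, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .write_tsv(calls, "calls.tsv")
  .write_tsv(feats, "features.tsv")
  if (nrow(calls)) {
    .write_tsv(summ$summary, "taxon_summary.tsv")
    write.table(summ$matrix, file.path(config$out, "matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  run <- list(config = unclass(config), seed = config$seed,
              n_homolog_files = length(files),
              n_selected = length(selections),
              n_calls = nrow(calls),
              selections = lapply(selections, function(s)
                list(entry_id = s$entry_id, chain_id = s$chain_id,
                     criterion = s$criterion,
                     opt_rmsd = s$alignment$opt_rmsd,
                     rmsd = s$alignment$rmsd,
                     twists = s$alignment$twists)))
  jsonlite::write_json(run, file.path(config$out, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(selections = selections, msa = msa, calls = calls,
                 summary = summ, features = feats, metadata = metadata))
}

# domain ranges containing a site (as a start/end data frame), or NULL
.domain_of_site <- function(domains_tab, resno) {
  hit <- domains_tab[domains_tab$start <= resno &
                       domains_tab$end >= resno, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  dom <- hit$domain[1]
  domains_tab[domains_tab$domain == dom, c("start", "end"), drop = FALSE]
}
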