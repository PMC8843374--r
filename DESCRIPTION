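Package: acsite3d
Title: Structural Conservation Analysis of Lysine Acetylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether post-translationally modified lysine
    residues of a target protein are conserved in its homologs using 3D
    structure rather than linear sequence alone. Provides PDB/mmCIF structure
    input, rigid (Kabsch) and flexible (aligned-fragment-pair chaining with
    twists) pairwise structural alignment with all-chain comparison and
    best-chain selection, structure-anchored multiple sequence alignment,
    per-site structural feature annotation (secondary structure, solvent
    accessibility, hydrogen bonds, interface and ligand contacts), 1D-versus-3D
    conservation calls with discrepancy classification and rescue/disorder
    fallbacks, domain- and taxon-stratified summaries, and a synthetic
    structure-family simulator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
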