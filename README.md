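# acsite3d

Structure-based conservation analysis of lysine acetylation sites.

## The problem

N&epsilon;-lysine acetylation is a widespread post-translational
modification in bacteria, deposited either enzymatically by lysine
acetyltransferases (KATs such as YfiQ and YiaC in *E. coli*) or chemically
by acetyl phosphate (AcP). Whether a modified lysine is *conserved* in a
homolog is usually judged from a linear sequence alignment — but a lysine
that moves two positions along the sequence can still occupy the same
spatial pocket, a lysine in a disordered loop can be invisible to the
crystal structure while present in the sequence, and hinged multi-domain
proteins defeat single-superposition comparisons altogether. `acsite3d`
implements the full 3D-aware workflow for deciding site conservation:

1. **Pairwise structural alignment.** A rigid route (sequence
   correspondence + Kabsch superposition, one transform) and a flexible
   route that chains aligned fragment pairs (AFPs, gapless length-*L*
   fragment pairs with superposed C&alpha; RMSD &le; a cutoff) by dynamic
   programming, charging a *twist* whenever consecutive fragments are
   incompatible with one rigid-body transform. The flexible alignment
   reports both the single-transform `rmsd` and the length-weighted
   per-block `opt_rmsd`.
2. **All-chain comparison and best-chain selection.** Every homolog chain
   is aligned against the target chain; one chain is selected per
   structure by the lexicographic rule: lowest `opt_rmsd`, then longest
   homolog sequence, then highest chaining score.
3. **Structure-anchored MSA.** Pairwise alignments are compiled into a
   multiple alignment whose columns are the target's residues (homolog
   insertions are dropped but counted).
4. **Conservation calls.** 3D: the site's aligned homolog residue must be
   lysine, with a *rescue* rule (an unaligned homolog lysine whose
   C&alpha; lies within 5 &Aring; of the superposed site counts) and a
   *disorder* rule (a lysine in the declared SEQRES sequence at the
   gap-interpolated position counts, flagged). 1D: the homolog must have
   lysine in the site's column of a sequence-only alignment. Disagreements
   are classified as **open stars** (1D-only) or **filled stars**
   (3D-only).
5. **Stratified summaries.** Conserved fractions per site and taxon group
   (Gram-negative/positive/variable bacteria, Eukaryotes, Archaea,
   synthetic constructs), counting only homologs in which the site's
   structural domain is actually present (&ge; 70% aligned coverage).
6. **Site feature annotation.** Secondary-structure class (P-SEA-style
   dihedral + C&alpha;-distance assignment), Shrake–Rupley solvent
   accessibility, hydrogen bonds (direct and water-mediated),
   inter-subunit interface membership and ligand/nucleic-acid contacts.

A synthetic structure-family generator (`family_spec()` /
`generate_family()`) builds ideal-geometry homolog families with planted
site outcomes — conserved, substituted, sequence-shifted-but-spatially
conserved, disordered, spatially displaced — plus inter-domain hinge
rotations, disorder masks and coordinate noise, together with the ground
truth table, so the whole pipeline is testable without downloading
anything.

The package ships the site annotations and structural domain definitions
for the five *E. coli* KAT substrate proteins (Adk, Icd, KatE, Fmt, YaaA)
in `inst/extdata/`; `default_site_annotations()` and
`default_domain_definitions()` load them.

## Worked example

Generate a 4-homolog synthetic family with one substitution, one
sequence-shifted lysine and one spatially displaced lysine, then run the
pipeline:

```r
library(acsite3d)

spec <- family_spec(n_homologs = 4, identity = c(90, 70, 55, 45),
                    noise_sd = 0.2,
                    outcomes = list(NULL, list("14" = "substituted:R"),
                                    list("43" = "shifted:2"),
                                    list("43" = "displaced")),
                    seed = 3)
d <- tempfile()
fam <- generate_family(spec, out_dir = file.path(d, "family"))
writeLines(c("protein_id\tresno\tmechanisms",
             "target\t14\tKAT:YiaC", "target\t43\tAcP"),
           file.path(d, "sites.tsv"))
cfg <- pipeline_config(target = file.path(d, "family", "target.pdb"),
                       homolog_dir = file.path(d, "family"),
                       metadata = file.path(d, "family", "metadata.tsv"),
                       sites = file.path(d, "sites.tsv"),
                       out = file.path(d, "out"), seed = 7)
res <- run_pipeline(cfg)
res$calls[, c("homolog_id", "site_resno", "aligned_aa",
              "conserved_3d", "conserved_1d", "discrepancy")]
evaluate_recovery(res$calls, fam$truth)$accuracy
```

which prints

```
 homolog_id site_resno aligned_aa conserved_3d conserved_1d discrepancy
      syn01         14          K         TRUE         TRUE       agree
      syn01         43          K         TRUE         TRUE       agree
      syn02         14          R        FALSE        FALSE       agree
      syn02         43          K         TRUE         TRUE       agree
      syn03         14          K         TRUE         TRUE       agree
      syn03         43          K         TRUE        FALSE filled_star
      syn04         14          K         TRUE         TRUE       agree
      syn04         43       <NA>        FALSE         TRUE   open_star
recovery accuracy: 1
```

Reading the discrepancies: in `syn03` the lysine moved two positions in
sequence but stayed in the target site's spatial pocket — the 3D call
(via the rescue rule) finds it while the 1D column does not, a *filled
star*. In `syn04` the sequence still has a lysine at the position but its
loop moved away in space — conserved in 1D only, an *open star*. The
recovery accuracy of 1.0 means every call matched the planted truth. The
output directory additionally holds `calls.tsv`, the star/dot matrix
(`matrix.tsv`), per-taxon conserved fractions (`taxon_summary.tsv`), the
anchored MSA (`msa3d.fasta`), site features (`features.tsv`) and the run
log (`run.json`).

For hinged conformers the flexible aligner is what makes the 3D call
work: a 30° inter-domain hinge gives a rigid single-transform RMSD of
several &Aring;ngstr&ouml;m but a flexible `opt_rmsd` of ~0.2 &Aring; with
exactly one twist, and the spatial read-off under a single rigid
transform misplaces sites on the moving domain while the flexible calls
match the truth.

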