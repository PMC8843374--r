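---
title: "Deciding lysine-site conservation from 3D structure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding lysine-site conservation from 3D structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsite3d)
```

## Scope and model

`acsite3d` answers one question per homolog and site: *is the acetylated
lysine of the target protein conserved*, judged two ways — from the linear
sequence (1D) and from the 3D structure — and how do the two verdicts
disagree. The scientific motivation is that lysine acetylation sites
(enzymatic, via acetyltransferases, and chemical, via acetyl phosphate)
concentrate on flexible, surface-exposed regions, exactly the regions where
sequence alignment and structural superposition are least reliable: loops
rearrange, lysines slide a few positions while keeping their spatial pocket,
loops go disordered in crystals, and whole domains hinge between open and
closed conformations.

## The flexible aligner

The pairwise aligner follows the aligned-fragment-pair (AFP) chaining
paradigm. An AFP is a gapless pair of length-`fragment_length` C&alpha;
fragments whose least-squares superposed RMSD is at or below
`fragment_rmsd_cutoff`. AFPs are chained by dynamic programming, monotone in
both sequences; consecutive chained AFPs whose transforms differ by more
than `angle_max` degrees of rotation or `trans_max` &Aring; of translation
cannot share a rigid block, and each such block boundary is a *twist*,
charged `twist_penalty` in the chaining score and capped at `max_twists`.
The chaining score is $\sum_{\text{AFPs}} L \,(c - r_i)$ minus affine gap
costs ($g_o + g_e (g-1)$ for a gap of $g$ residues) minus the twist
penalties, where $L$ is the fragment length, $c$ the cutoff and $r_i$ the
fragment RMSD. Per block, a Kabsch fit gives the block transform and RMSD;
`opt_rmsd` is the length-weighted mean of block RMSDs, and by the
Cauchy–Schwarz inequality it never exceeds the single-transform `rmsd`
reported over the same correspondence.

Defaults — `fragment_length = 8`, `fragment_rmsd_cutoff = 3.0` &Aring;,
`max_twists = 5`, compatibility `15°`/`3` &Aring;, `twist_penalty = 15`,
gaps `5`/`0.5` — were chosen once as a plain, documented parameterization of
this family of aligners: fragments of 8 residues span two helical turns, a
3 &Aring; fragment cutoff separates conserved local structure from
rearranged loops, and the twist penalty is large enough that a twist is only
bought when it rescues a whole domain's worth of fragment score. The aligner
is deliberately a *simplified* fragment-chaining method: no
sequence-order-independent alignment, no simultaneous multiple
superposition, and no attempt at bit-compatibility with any particular
published implementation. The AFP scan and chaining run in compiled code
(RcppArmadillo), as is usual for structural aligners.

The rigid route aligns atom-record sequences globally (Needleman–Wunsch,
BLOSUM62, affine gaps, via Biostrings), restricts to pairs with C&alpha;
coordinates, and fits one Kabsch transform with no outlier rejection — the
"superpose once and read everything off one frame" strategy the flexible
route improves on. The Kabsch solver itself is the standard SVD solution
restricted to proper rotations (reflections are rejected by sign-correcting
the smallest singular vector); degenerate (collinear) inputs are an error
rather than an arbitrary answer.

## Conservation calls

**3D call.** If the site's target residue is aligned, the homolog residue
decides (lysine exactly; arginine or histidine do *not* count — conservative
substitution is a separate question and is not folded into the verdict).
If the site is unaligned or the aligned residue is not lysine, the *rescue*
rule inspects unaligned homolog lysines: one whose C&alpha; falls within
`rescue_cutoff` (default 5.0 &Aring;) of the superposed target site
C&alpha;, under the containing block's transform, makes the site conserved
with `rescue_flag`. This quantifies the manual overlay inspection that
catches lysines missing from an aligner's sequence output. If the site maps
into a homolog coordinate gap, the *disorder* rule reads the declared
(SEQRES) sequence within `disorder_window` (±2) residues of the
gap-interpolated position: an unresolved lysine there makes the site
conserved with `disorder_flag`. The 5 &Aring; and ±2 values are this
package's quantification of visual steps; both are config keys.

**1D call.** Lysine in the site's column of a sequence-only alignment. Two
routes exist because practice uses both: an internally built
target-anchored sequence MSA (each homolog globally aligned to the target
and projected onto target columns), or an imported externally produced
gapped FASTA (`import_msa`), for when the sequence alignment of record was
made by another program.

**Discrepancies.** `open_star` = conserved in 1D only; `filled_star` =
conserved in 3D only; `agree` otherwise. These labels partition all calls.

**Rigid spatial read-off.** `call_site_3d(..., correspondence = "spatial")`
reproduces the superpose-once strategy: the nearest homolog C&alpha; to the
superposed site (within the same 5 &Aring; cutoff) decides. On hinged
families this is exactly the call that goes wrong — the moving domain lands
&Aring;ngstr&ouml;ms away under a single transform — which is the package's
internal demonstration of why the flexible route is the default.

## Anchored MSA

The structure-anchored MSA has one column per target residue, in target
order; each homolog row is filled from its pairwise correspondence. Homolog
residues aligned outside any target column (insertions) are dropped, not
rendered, and counted per homolog in `dropped_insertions` so the loss is
measurable. Anchoring is target-only: adding or removing a homolog never
re-gaps existing rows, and the per-homolog correspondence is recoverable
exactly from the matrix (a tested round-trip invariant).

## Feature annotation

Secondary structure is assigned from backbone geometry (P-SEA-style):
φ/ψ windows (helix φ ∈ [−115°, −30°], ψ ∈ [−80°, −5°]; strand
φ ∈ [−170°, −70°], ψ ∈ [80°, 180°] ∪ ψ ≤ −170°) confirmed by
C&alpha;(i)–C&alpha;(i+3) distances (helix-like 4.2–6.5 &Aring;, extended
> 7.5 &Aring;), with run minima of 4 (helix) and 3 (strand); everything
else is loop. Labels collapse to the three classes used for site
summaries, with an end-of-element flag for residues within two positions
of a segment terminus. A full hydrogen-bond-energy assignment was not
used because crystal structures lack hydrogens and three classes suffice
for the site statistics.

Solvent accessibility is Shrake–Rupley quadrature with a deterministic
golden-spiral point set (default 960 points/atom, probe 1.4 &Aring;; the
single-atom case is exact against $4\pi(r+p)^2$ regardless of point
count). Relative accessibility divides residue SASA by tabulated
Gly-X-Gly theoretical maxima, clipped to [0, 1.2]. *Surface-exposed* is
codified as relative accessibility ≥ 0.20 in single-chain context; the
ratio uses the whole residue rather than side-chain atoms only, because
the synthetic chains carry only C&beta;/N&zeta; side-chain atoms and a
whole-residue ratio behaves identically across real and synthetic inputs.
The threshold is a config key. Hydrogen bonds are distance-only
(donor–acceptor N/O pairs ≤ 3.5 &Aring;; water-mediated bonds need both
legs ≤ 3.5 &Aring;) — no angle term, again because hydrogens are absent.
Interface membership is any heavy atom of another polymer chain within
5.0 &Aring;. All three cutoffs are declared assumptions, not measured
constants, and are exposed in the configuration.

## Dataset handling

Homolog metadata (PDB id, UniProt accession, organism, taxon group,
resolution, wild-type flag) is input, never inferred: taxon labels come
from a closed set (Gram-negative/positive/variable, Eukaryote, Archaea,
synthetic). One representative structure per UniProt accession is chosen
as the highest-resolution wild-type entry (ties to the lexicographically
smallest PDB id; groups without a wild-type entry fall back, with a
warning, to the best non-wild-type). The identity filter keeps homologs
with ≥ 30% identity, boundary inclusive; percent identity is identical
aligned pairs over aligned (non-gap) pairs of the optimal global
alignment — the denominator had to be fixed somewhere, and aligned-pairs
is the convention that makes a short perfect fragment read as what it is.
Live structure-database and sequence-search clients are deliberately
absent: the metadata snapshot is an input so that results are
reproducible offline.

## The synthetic generator and what it does (not) show

`generate_family()` is first-class, tested code, not a fixture: it defines
the study conditions under which every acceptance property is measured.
Chains are built from ideal covalent geometry (N–C&alpha; 1.458,
C&alpha;–C 1.525, C–N 1.329 &Aring;; ω = 180°; helix φ/ψ = −57°/−47°,
strand −120°/+120°, loops drawn deterministically from a small set chosen
outside both the helix and strand dihedral windows) with C&beta; and, for
lysines, an idealized N&zeta;. Homolog sequences are mutated to a requested
identity (never *to* lysine, so planted truth stays clean; an unreachable
identity is an error stating the achievable bound); realized identity is
within one percentage point for chains of ≥ 100 residues. Hinges rotate a
domain rigidly about an axis through the domain boundary. Planted site
outcomes map one-to-one onto the verdict classes: `conserved`,
`substituted:X`, `shifted:k` (the lysine moves k positions in sequence but
keeps the target site's spatial position, with the intervening loop
rearranged so fragment alignment genuinely drops it — the filled-star
case), `disordered` (coordinates of the ±2 window removed, SEQRES kept),
and `displaced` (the local loop moves ~14 &Aring; away — the open-star
case). Shifted outcomes belong on loops: inside regular secondary
structure a two-position swap does not break 8-residue fragments, which is
faithful to the biology (sliding sites are a loop phenomenon) and is why
the default planted sites sit on loops.

Defaults — 6 homologs, 60% identity, coordinate noise σ = 0.3 &Aring;
(crystal-coordinate scale), 92-residue two-domain targets — are the
problem sizes used throughout the tests and the acceptance script; they
keep every run in seconds while leaving the geometry unambiguous.

What passing on synthetic families does *not* show: real crystal
structures bring alternate conformations beyond the highest-occupancy
policy, non-standard residues, crystal-packing contacts that mimic
interfaces, genuinely ambiguous loop correspondences, and sequence
divergence patterns far from uniform substitution. The generator makes the
*logic* of every rule testable with known truth; it does not certify
accuracy on real proteins, where visual inspection retains a role.

## Numerical choices and degenerate inputs

Kabsch fits reject < 3 points and collinear sets. The AFP scan restricts
fragments to runs of consecutive residues with C&alpha; coordinates, so
chain breaks never produce fragments spanning a gap. Chain selection
treats `opt_rmsd` ties within 1e-9 as equal, then lengths, then scores,
then the smallest chain id — making selection a pure function of the
alignment set, invariant to input order. Sequence-alignment tie-breaking
among co-optimal paths follows the deterministic backtrace of the
underlying alignment library; the optimum itself is verified against
exhaustive enumeration in the tests. Multi-model files keep model 1;
altloc ties go to the alphabetically first label; unknown residues become
`X` with a warning and unknown elements get a 1.8 &Aring; radius with a
warning rather than an error, since a single exotic atom should not abort
a whole-structure scan.

## Known limitations

No sequence-order-independent structural alignment (circular permutants
will not align); homolog insertions are invisible in the anchored MSA
except as counts; hydrogen-bond detection without angles over-counts
marginal contacts; the disorder rule's gap interpolation assumes the
disordered segment has equal length in target and homolog sequence
numbering; and conservation is strict lysine identity — positively
charged substitutions are left to downstream interpretation of the
per-call `aligned_aa` field.
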