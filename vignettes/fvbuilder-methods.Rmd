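---
title: "Modelling antibody variable fragments with FvBuilder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antibody variable fragments with FvBuilder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

FvBuilder builds three-dimensional models of antibody variable fragments
(paired VH+VL Fvs, heavy-only VHH nanobodies, and light-only domains) from
sequence, using a local library of template structures. This vignette
describes the modelling procedure, its assumptions, the tunable parameters,
and what the bundled synthetic-fixture generator does and does not emulate.

## The modelling pipeline

A model is built in four stages, orchestrated by `buildModel()`:

1. **Template selection.** Candidate structures (resolution no worse than
   2.5 Å by default) are scored by framework sequence identity: the
   percentage of matching residues over the scheme positions labelled
   framework in both sequences. If a single structure reaches 80% on *both*
   chains' frameworks, it is used as a **global** template, supplying both
   domains and their relative orientation; the record maximising the
   minimum of the two identities is chosen. Otherwise the mode is
   **hybrid**: the best VH donor and the best VL donor are used separately.
   Ties break by better resolution, then lexicographic id, so selection is
   deterministic. At 80% identity the calibration data give roughly a 75%
   probability of a sub-ångström framework template, which is why 80% is
   the default threshold.

2. **Orientation.** A global template fixes the VH–VL orientation by
   construction. For hybrid templates each donor chain's framework backbone
   is superimposed (least-squares, Kabsch) onto the corresponding chain of
   the best *global* candidate, so the assembled model inherits that
   structure's inter-domain orientation while keeping each donor's local
   geometry. This is a direct-superposition transplant: the original
   approach re-orients through a consensus-structure parameterisation whose
   reference coordinates are not part of this package, but the contract —
   hybrid models inherit the orientation of the highest-identity global
   template — is the same.

3. **CDR loop grafting.** Loops are modelled in the fixed order CDRL2,
   CDRH2, CDRL1, CDRH1, CDRL3, CDRH3 (better-predicted, less-contacting
   loops first; a VHH conserves the order as H2, H1, H3). For each loop,
   length-matched fragments from the CDR-specific database are filtered by
   anchor Cα-separation mismatch (±0.8 Å) and substitution score
   (BLOSUM62 sum ≥ 25), then ranked by **anchor RMSD**: both anchors
   (5 framework residues per side) are superimposed jointly as one rigid
   body onto the model's anchors, and the residual RMSD ranks the
   survivors. The top decoy's loop backbone is transformed by the joint
   anchor fit and substituted for the model's loop; anchor residues keep
   their model coordinates, and grafted residues take the target's residue
   identities. A decoy whose graft breaks the backbone (junction Cα–Cα
   above 4.5 Å) is rejected and the next decoy tried. When no decoy
   passes, the cascade continues: an Fv-wide fragment database (contiguous
   backbone windows of the loop lengths present, from anywhere in the
   library) is searched with the same filters; failing that, the most
   sequence-similar length-matched loop (maximum BLOSUM62 score, sources at
   resolution ≤ 2.5 Å, ties by anchor RMSD) is grafted ignoring the
   filters; if no length-matched fragment exists at all, a structured
   `abInitioRequired` condition is raised carrying the most
   sequence-similar unequal-length fragment, as a hook for an external
   loop modeller. Each loop's provenance stage is recorded in the report.

4. **Side chains and clash control.** The assembled model keeps template
   side chains wherever template and target residues are identical
   (*partial* prediction); remaining side chains are rebuilt from a small
   backbone-independent rotamer library, taking the highest-prior rotamer
   that introduces no new clash (least-clashing fallback). Retaining
   common residues' rotamers is measurably more accurate than rebuilding
   everything, which is why partial prediction is the default; a *complete*
   mode that rebuilds every side chain exists for comparison harnesses.
   Two atoms clash when their distance is strictly less than 65% of the
   sum of their van der Waals radii — 2.21 Å for two carbons at
   r = 1.7 Å — excluding covalently bonded pairs and 1–3 neighbours.
   If clashes are present the clashing residues are re-sampled first
   (*local* stage); if clashes persist every side chain is re-sampled
   (*global* stage); the first clash-free structure wins, otherwise the
   structure with the fewest clashes seen is returned with a warning.

## Numbering and region definitions

Sequences are numbered by global alignment (BLOSUM62, affine gaps) against
a bundled pre-numbered consensus for each chain type; query insertions
relative to the consensus receive insertion codes on the preceding
position, and alignments below 30% identity are rejected as unnumberable.
This consensus numbering is a deliberate simplification: it plays the role
a full HMM-based numbering scheme plays in production pipelines, keeps the
package dependency-free, and preserves the contract that structures
numbered in the same scheme are comparable position-wise. The CDR
definition table (`inst/extdata/cdr_definitions.tsv`) is editable; two
interval sets ship with the package, the default (`"north"`, wider loops)
and a narrower alternate (`"chothia"`) used by the benchmarking mode
switch. Both are expressed in the package's consensus numbering rather
than the historical position labels of the same names.

## Accuracy protocols

All accuracies are backbone RMSDs ({N, CA, C, O}; carbonyl O inclusion is
configurable in principle since only the atom-set constant gates it):

* **Fv RMSD** — superimpose all shared backbone atoms of both chains,
  report the RMSD over those atoms.
* **Framework RMSD** — per chain, superimpose the framework backbone only.
* **CDR RMSD** — superimpose the loop's own chain's framework backbone,
  then compute the loop RMSD *without refitting*. A stricter variant fits
  both chains' frameworks first (`bothChains = TRUE`), which also exposes
  inter-domain orientation error in the loop score. Loops of unequal
  length at shared positions are an error, never a partial RMSD.

Atom pairing everywhere is by shared scheme position; residues missing a
requested atom are dropped from that calculation with a warning.

## Confidence estimates

The confidence that a region is modelled within $x$ Å is a conditional
probability estimated from calibration data, not an energy or a fit
quality:

$$P(x \mid s) = \frac{P(x \cap s)}{P(s)}$$

where $s$ is the conditioning value — framework sequence identity for
framework regions, loop length for CDRs. For identity conditioning,
$P(s)$ is the fraction of calibration observations with identity in
$s \pm 2.5$ evaluated on a 1-unit grid (each grid bin is 1% wide), and
$P(x \cap s)$ additionally requires RMSD $\le x$. Loop lengths are
discrete, so length conditioning is an exact match with no window.
Framework calibration comes from all-vs-all framework superimpositions of
the library (VH–VH and VL–VL separately, since orientation accuracy is not
captured by either); CDR calibration comes from leave-one-out loop
prediction over the library. Inverting the curve — the smallest grid
$x$ (0.1 Å step) with $P(x \mid s) \ge p$ — yields the expected RMSD at a
chosen confidence, 75% by default. Bins with no observations yield an
explicit "no confidence available" result (`NA`), never zero; this is the
honest answer for, e.g., loop lengths never seen in the library. The
probability formulation is used instead of an "$x \pm \varepsilon$" error
band because the RMSD distribution changes shape across bins, so no single
dispersion parameter is faithful.

## Sequence liabilities

The target sequence is scanned for developability motifs (editable table,
`inst/extdata/liability_motifs.tsv`): the N-glycosylation sequon
Asn–X–Ser/Thr (X unrestricted by default; excluding proline is a
documented option), asparagine deamidation, aspartate isomerisation,
methionine/tryptophan oxidation, N-terminal pyroglutamate formation,
lysine glycation context, and cysteines outside the conserved intra-domain
pair (located via the consensus cysteine positions). Matching is
sequence-only and overlap-tolerant. A hit is *reported as exposed* only if
some residue in its span has relative accessible surface area strictly
greater than 10%. Relative ASA is computed by the Shrake–Rupley
sphere-point method (probe 1.4 Å, 92 points per atom) and normalised by
the Miller et al. standard-state Gly-X-Gly maxima, so a residue in a free
extended tripeptide reads close to 100%. The standard-state reference was
chosen over a theoretical-maximum set deliberately: theoretical maxima are
conformational upper bounds that physically extended conformations only
reach ~85–90% of, which would silently deflate every exposure estimate and
shift the 10% gate.

## The synthetic fixture generator

Everything above is testable without any external structure database
because the package generates its own study material. `makeIdealizedFv()`
builds a chemically complete variable domain: framework residues lie on a
regular helical path indexed by scheme position (radius 8 Å, 0.45 rad and
1.3 Å rise per residue), CDR loops on tangent-continuous curves between
their anchor points chord-stepped to 3.8 Å Cα spacing at any loop length,
carbonyl and side-chain directions alternating as in a β-strand, and side
chains placed from the rotamer library taking the first clash-free rotamer
in probability-weighted random order. Because framework coordinates depend
only on scheme position, structures derived from the same consensus share
framework geometry exactly, which gives the generator controlled ground
truth.

`makeTemplateFamily()` derives a family from the consensus by per-member
framework mutation (an exact count of positions, so realised identity is
controlled; default rates span 2–35%, bracketing the 80% selection
threshold), light CDR mutation (8% per position), two CDRH3 length
variants (0 or +2 insertions), per-residue coordinate noise whose σ grows
linearly with the framework mutation rate (0.05 + 1.5 × rate Å; the
displacement field is smoothed along the chain so neighbouring residues
move together and backbones stay contiguous), a small random inter-domain
rotation (σ = 2°), and simulated resolutions spanning 1.2–3.0 Å so the
2.5 Å template filter has work to do. Pairwise framework RMSD therefore
grows stochastically with sequence distance, identities bracket the
global/hybrid decision boundary, and the generating parameters are
returned as ground truth. These defaults are the package's study
conditions and are exercised unchanged by the test-suite.

What the fixtures do **not** emulate: real β-sandwich topology and
hydrogen bonding, Ramachandran statistics, correlated loop conformational
clusters ("canonical classes"), crystallographic artefacts, and any
energetic coupling between side chains beyond hard-sphere clashes. Tests
passing on fixtures therefore demonstrate the geometric and statistical
contracts of the pipeline — selection rules, grafting geometry, ranking,
calibration, exposure gating — not biophysical accuracy on real
antibodies. Benchmarks against crystal structures require a real template
library, which the same functions accept unchanged.

## Numerical choices

* Backbone atom set {N, CA, C, O}; intervals inclusive on both ends;
  coordinates in Å.
* Identity denominators use the intersection of framework positions
  present in both sequences (gap handling is otherwise ambiguous).
* Anchor length 5 residues per side; span tolerance 0.8 Å; substitution
  score threshold 25 (comparable in magnitude to environment-specific
  scores in the tens). The scorer is plain BLOSUM62 and is pluggable — an
  environment-aware scorer can be swapped in without touching the
  filter-then-rank-by-anchor-RMSD contract.
* Decoy ranking is a total order: anchor RMSD, then higher substitution
  score, then better resolution, then fragment id.
* Clash factor 0.65, strict less-than at the boundary (a 10⁻⁹ Å tolerance
  guards against floating-point representation of the threshold).
* Confidence: ±2.5 window on a 1-unit identity grid; exact match for loop
  lengths; 0.1 Å inversion grid; undefined bins are `NA`, never 0.
* Proline's CD atom is anchored on the backbone nitrogen so the
  pyrrolidine ring always closes; the CG–CD bond is recorded explicitly in
  the bond graph used for clash exclusions.
* The modelling path is deterministic: identical inputs, stores and
  configuration give byte-identical PDB and report output. Randomness
  exists only in fixture generation, always behind an explicit seed.

## Problem sizes used by the test-suite

The shipped tests run on families of 8–16 structures for unit contracts,
and the calibration-coverage property uses a 16-member calibration family
against 200 freshly generated targets (≈1600 scored regions). These sizes
give stable statistics for the stochastic properties (coverage within a
few percent run-to-run) while keeping a full test run in the minutes
range on one CPU.

## Known limitations

* The consensus-alignment numbering cannot number sequences below 30%
  identity to the bundled consensus and does not reproduce historical
  position labels; pre-numbered input is the escape hatch.
* The rotamer library is intentionally small (2–3 rotamers per residue,
  backbone-independent); χ accuracy on real structures would benefit from
  a backbone-dependent library, which the interface accepts.
* Clash resolution is greedy and can terminate with residual clashes
  (reported, with the minimum-clash structure returned); there is no
  continuous relaxation.
* The *ab initio* stage is a structured hand-off, not a loop builder.
* Confidence estimates assume the calibration library is representative of
  the targets; for sequences unlike anything in the library the estimates
  are explicitly unavailable or, worse, extrapolated from a thin bin —
  the per-bin sample counts are the user's guard.
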