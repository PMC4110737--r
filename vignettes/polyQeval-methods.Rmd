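---
title: "Evaluating predicted polyglutamine ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted polyglutamine ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyQeval)
```

## The evaluation problem

Polyglutamine (polyQ) fragments such as huntingtin exon 1 are
conformationally heterogeneous, and the crystal references available for
them are only partially resolved: the 17-residue amphipathic head is
essentially always present, density decays through the 17-glutamine tract,
and the proline-rich C-terminus is mostly missing. Two consequences drive
the design of this package.

First, a *single* predicted structure is the wrong unit of evaluation;
ensembles collected over independently seeded prediction runs are compared
instead, both against each other (reproducibility) and against the
reference panel (validity). Second, global similarity scores are not
enough. A model can superpose well onto a reference while its glutamine
tract sits one register off — biologically a different structure. The
package therefore pairs the TM-score with *exact* structure overlap
statistics that demand residue-position identity.

## The construct and its regions

All chains are mapped onto a `ConstructDef`: a sequence plus an exact
partition into head, polyQ tract and C-terminal region. The default,
`htt17qConstruct()`, is the 60-residue exon-1 fragment with 17 glutamines
(head 1–17, tract 18–34, Pro-rich tail 35–60). Author numbering in a PDB
file is translated by a per-file integer offset; because depositions of
fusion constructs number their chains idiosyncratically, the offset is
data, not code (a template lives in
`inst/extdata/reference_offsets.tsv`), and every import is validated
against the construct sequence so a wrong offset fails loudly rather than
silently mis-registering the tract.

"Resolved" means a CA coordinate is present; that is all superposition and
overlap need. Secondary-structure assignment additionally requires N, C
and O, so a CA-only residue participates in alignment but reports `M`
(missing) in profiles. These two tiers exist because crystal chains
genuinely come in both flavours.

## Superposition, TM-score, and the aligner

`kabsch()` computes the least-squares rigid superposition via SVD with
reflection correction. `tmScore()` maximizes

$$\mathrm{TM} = \frac{1}{L_N}\sum_i \frac{1}{1+(d_i/d_0)^2},\qquad
  d_0 = 1.24\,(L_N-15)^{1/3} - 1.8$$

over superpositions using the standard fragment-seeded iterative search
(seed windows of several lengths, refined by reselecting residues closer
than a cutoff). $L_N$ is floored at 17 and $d_0$ at 0.5 Å; below those the
cube root produces meaninglessly small scales for 60-residue chains.

`tmAlign()` finds the correspondence itself: seeds from gapless
threading, a coarse CA-geometry secondary-structure alignment, and a
combined distance/secondary-structure matrix are each refined by iterating
superposition → TM-weighted score matrix → dynamic programming until the
pair set repeats (cap 30 iterations). The DP uses a flat gap penalty of
−0.6 with free end gaps and resolves ties toward the diagonal, so results
are deterministic. The highest-TM alignment wins. Two reporting
conventions matter downstream:

* the stored transform is the TM-optimal superposition — the frame in
  which exact-match distances are measured;
* the reported RMSD is the least-squares value over the aligned pairs,
  the number a structural aligner conventionally prints.

TM-score normalization defaults to the reference chain, so validity
panels are comparable across references with different resolved lengths;
reproducibility analyses use `shorter`, which is symmetric for the
equal-length members of one ensemble. This is a configuration switch
(`normalize_by`), not a constant.

One calibration note: the familiar interpretation thresholds (≈0.17 for a
random alignment, >0.5 for the same fold) were derived for TM-scores over
a *fixed* correspondence. An optimizing aligner inflates scores of
unrelated chains somewhat, so the test suite checks the random level on
fixed-correspondence scores and checks only "well below the fold
threshold" for optimized alignments of unrelated coils.

## Exact structure overlap

For an alignment of length $L(A)$ between a model with $L_m$ and a
reference with $L_e$ resolved residues:

$$\mathrm{SO} = 100\cdot\frac{L(A)}{\min(L_m, L_e)},\qquad
  \mathrm{ESO} = 100\cdot\frac{L(EA)}{\min(L_m, L_e)},\qquad
  \mathrm{ESOP} = 100\cdot\frac{L(EAQ)}{\min(L_{Qm}, L_{Qe})}$$

An aligned pair is an *exact match* ($L(EA)$) when both residues occupy
the same construct position — which, after sequence validation, implies
the same amino acid — and their CA–CA distance in the superposition frame
is below a threshold (5 Å default). $L(EAQ)$ restricts exact matches to
tract positions, and $L_{Qm}, L_{Qe}$ count *resolved* tract residues.
Normalizing ESOP by resolved (not nominal) tract length is deliberate:
references with 10–15 resolved glutamines can then reach ESOP = 100 when
everything they do resolve is matched, which is the sensible reading of a
perfect local match against a partial reference.

Three reporting choices were genuinely open and are fixed as follows.
The distance stratification is three-way — below threshold ("close"), at
or above it ("other"), and their union ("all") — with ESO defaulting to
the close stratum that carries the 5 Å definition. "Total Q matches"
counts aligned glutamine–glutamine pairs by residue code without
requiring position identity, the most literal reading consistent with it
exceeding the exact Q count (note the construct also has glutamines
outside the tract, at positions 46/49/53/55/60, which this count
includes and the ESOP numerator excludes). And a register-shifted model
drives ESO and ESOP to zero while SO and TM stay high — the failure mode
these statistics exist to expose; a test asserts exactly this contrast.

## Secondary structure

`assignDssp()` implements the classic Kabsch–Sander rules: amide H placed
1.0 Å from N along the previous C=O direction, the electrostatic
hydrogen-bond energy $E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
1/r_{CN})\cdot 332$ kcal/mol with a bond below −0.5 kcal/mol, n-turns for
n = 3, 4, 5, helices H/G/I from consecutive turns, bridges and ladders
for B/E, turn interiors T, bends S above 70°, else coil. Overlaps resolve
with precedence H > E > B > G > I > T > S. Proline cannot donate. Coil is
emitted as an explicit `C` (machine-readable), and `M` marks unresolved
or CA-only positions so reference ensembles profile honestly. Newer DSSP
revisions (π-helix preference, polyproline II) are intentionally out of
scope. On ideal-geometry fixtures the assignment is checked against an
independent implementation (mdtraj's DSSP) at ≥95% agreement.

`ssProfile()` turns per-model strings into position × state count and
frequency matrices — the machine-readable form of a sequence logo; the
graphical rendering is left to the user's plotting tool of choice.

## The synthetic generator

The generator exists so the full pipeline is exercisable, determinate and
ground-truthed without running any predictor. It emulates:

* **ensemble shape** — 10 runs × 5 retained models by default, with
  synthetic C-score-like scores in (−5, 2), monotone in the realized
  noise, so rank/selection logic is exercised realistically;
* **regional conformational preferences** — per model, one backbone
  state per region sampled from defaults chosen to mirror the crystal
  picture (head: 90% helix; tract: 40% helix / 50% coil / 10% strand;
  C-terminus: 90% coil), built by exact internal-to-Cartesian (NeRF)
  geometry (N–CA 1.458, CA–C 1.525, C–N 1.329 Å; angles 111.2°, 116.2°,
  121.7°; ω = 180°; helix −57/−47, strand −135/135, coil drawn from a
  six-basin φ/ψ library);
* **coordinate uncertainty** — isotropic Gaussian noise applied in
  Cartesian space after construction, so the ground-truth correspondence
  stays trivially known (dihedral-space variability is what the state
  sampling provides);
* **reference-style masking** — heads always resolved, a consecutive run
  of resolved tract glutamines per chain, and a C-terminal resolution
  cutoff. The default 21-chain panel fixes the resolved-Q spread at
  10–17 for ten chains (one fully resolved, one at 15) and 1–8 for the
  other eleven, mirroring the crystallographic situation where ten of
  twenty-one chains keep at least nine consecutive tract residues.

`perturbedEnsemble()` additionally produces noisy copies of a single
template — the parameter-recovery setting where noise level is the *only*
difference between an ensemble and the structure it should recover, which
is what makes "TM falls and RMSD rises monotonically in σ" a fair test.

What the generator does **not** emulate: predictor-specific error
structure (fragment-library bias, template leakage), side chains, real
crystallographic disorder or anisotropy, and any energetic realism.
Passing tests on synthetic data therefore demonstrate that the
*measurement machinery* is correct and discriminating — not that any
particular predictor is good.

## Statistics policy

Distributions are summarized mean ± sd when a Shapiro–Wilk test at 0.05
does not reject normality, otherwise by 25%/75% quantiles (all fields are
always returned; the flag records which presentation applies). Two-sample
comparisons use Welch's t-test when both samples pass the normality
check, else the Wilcoxon rank-sum test — rank-sum, not signed-rank,
because model sets are unpaired. Significance is α = 0.05; constant
degenerate samples are treated as non-normal and never significant. No
multiple-testing correction is applied across the metric panel, matching
the study design this pipeline reproduces.

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; generator and
  pipeline functions restore the caller's RNG state.
* The aligner, DP tie-breaks and the TM search are fully deterministic,
  so identical config + seed reproduce output files byte-for-byte (the
  test suite asserts this on TSV bodies).
* Degenerate inputs fail loudly: fewer than 3 points for superposition,
  fewer than 5 resolved residues for alignment, a reference without
  resolved tract glutamines for ESOP, an empty post-filter reference
  list for the validity study.
* Coordinates are written at PDB precision (3 decimals); round-trip
  tests use a 2 × 10⁻³ Å tolerance accordingly.

## Problem sizes in the test suite

The suite runs the studies at their design sizes where the combinatorics
are the point — 50-model ensembles (1225 pairs, 45 best-model pairs, 500
panel records) and the 21-chain reference panel — and uses smaller
ensembles (2–6 models, 1–3 references, 20 seeds per noise level on a
σ ∈ {0.5, 1, 2, 4} Å grid) for distributional and recovery properties,
sizes chosen to give stable means while keeping the suite quick to run.

## Known limitations

* The aligner follows the published TM-align *scheme*, not its code;
  bit-for-bit agreement with the original binary is a non-goal, and
  scores on unrelated chains can differ by a few hundredths.
* DSSP here is the classic 8-state algorithm; chains consisting largely
  of proline (the C-terminal tail) have few donors and therefore little
  assignable structure beyond bends and turns, which is faithful but
  worth remembering when reading profiles.
* mmCIF, multi-model NMR entries, ligands and insertion codes are out of
  scope; insertion codes or non-standard residues inside the mapped
  range raise errors by design.
* ESOP is undefined against a reference with zero resolved tract
  residues; such references should be removed by the consecutive-Q
  filter before panel computation.
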