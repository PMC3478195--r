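---
title: "Binding-site prediction by configuration enumeration: models and methods"
author: "aceDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site prediction by configuration enumeration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aceDock)
```

## The problem and the model

Two protein subunits that form a complex bury a set of *interface residues*
at their contact surface. aceDock predicts those residues from the two
unbound subunit structures alone, by searching over rigid-body
*configurations* — relative placements of subunit A against a fixed subunit
B — and keeping the configuration with the lowest Atomic Contact Energy
(ACE).

ACE is a statistical desolvation score over 18 heavy-atom types: each
cross-subunit atom pair $(s, t)$ within a contact cutoff $d$ contributes a
pre-tabulated log-likelihood energy $T[s,t]$,

$$E_{\mathrm{ACE}} \;=\; \sum_{s \in S_1,\; t \in S_2,\; \lVert s-t\rVert \le d} T[s,t],$$

with $d = 6\,\text{Å}$ by default. Each table entry derives from observed
versus expected contact counts against solvent (type 0),

$$T_{ij} = -\ln \frac{N_{ij}/C_{ij}}{(N_{i0}/C_{i0}) (N_{j0}/C_{j0})},$$

implemented in `contactEnergy()` / `buildAceTable()`. The published 18×18
parameterisation is not redistributed here: the shipped
`ace_table_synthetic.tsv` is a clearly labelled synthetic stand-in with the
same file format and a full 20-residue heavy-atom typing map, and any table
in that format (or rebuilt from counts) can be substituted. All of the
package's own tests use explicitly constructed toy tables, so nothing in
the test suite depends on the synthetic values.

## The search

A naive search over all pairs of candidate interacting atom pairs is
$O(n^4)$; the pipeline prunes it in three stages.

**Stage 1 — candidate fragment pairs.** Both subunits are read as ordered
atom sequences. A *minimising* Smith–Waterman local alignment over the two
type sequences (match penalty $T[\cdot,\cdot]$, gap penalty $+1$) finds
subsequence pairs with strongly negative summed ACE — atom runs that could
pair favourably if geometry allowed it. Segments are extracted best-first
with Waterman–Eggert row/column masking until the best remaining score
exceeds the cap $x = 0$. Each segment is then scanned with a sliding window
of 15 alignment columns; a window qualifies only if at least 10 of its
atoms on *each* side are surface atoms, and qualifying windows are emitted
as fragment pairs and removed before the scan continues. Gap columns count
toward window length but contribute no surface atom (columns are the only
well-defined window unit once gaps exist).

**Surface atoms and clashes.** A 1 Å lattice is built around each subunit;
a lattice point is *protein* if it lies within 2 Å of any atom, *interior*
if all six axis neighbours are protein, else *surface*; an atom is a
surface atom if it lies within 1.5 Å of a surface lattice point. Two posed
subunits *clash* when their interior lattice point sets, computed
independently on one shared lattice, overlap by more than
$\theta \cdot \min(X_A, X_B)$ with $\theta = 0.17$. The lattice is anchored
at `floor(min coordinate) − (radius + spacing)` in each axis, so at the
default 1 Å spacing all lattice points have integer coordinates and the
fixed subunit's interior set can be cached across poses without changing a
single label (the cache-versus-shared-lattice equality is asserted in the
tests). `dock()` therefore requires the default 1 Å spacing; the standalone
grid functions accept any spacing.

**Stage 2 — geometric filtering.** The endpoints of each fragment pair
supply two anchor interaction pairs $(a_i, b_{i'})$ and $(a_j, b_{j'})$.
Candidate positions for $a_i$ are the lattice points of pitch $\epsilon d$
inside the $d$-ball of $b_{i'}$; for each, candidate positions for $a_j$
lie on the sphere of radius $\lVert a_i - a_j\rVert$ about the placed
$a_i$, restricted to the $d$-ball of $b_{j'}$ (a spherical cap, discretised
at arc pitch $\epsilon d$ with the cap pole always included); the remaining
degree of freedom is swept by rotations about the $a_i$–$a_j$ axis. Every
candidate pose is clash-checked on the full structures; clash-free poses
are ACE-scored on the fragment atoms, and a fragment pair survives only if
some pose scores below the threshold 400.

**Stage 3 — the final configuration.** With $k$ surviving fragment pairs
there are at most $\binom{2k}{2}$ anchor combinations; each is enumerated
as in stage 2 but scored on the *full* structures (the scored atom set in
the final ranking was a genuinely open choice; full-structure ACE is the
default and the scored span is exposed as an argument to
`enumeratePoses()`). Clash-free poses are ranked by ACE ascending with
lexicographic grid-index tie-breaks, and the best pose's residue pairs
within 4.5 Å (inclusive) are the predicted interface. If no fragment pair
survives or no pose is clash-free, the result is an explicit
"no prediction", not an error.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `contactCutoff` | 6 Å | ACE contact distance $d$ |
| `epsilon` | 0.1 | grid pitch as a fraction of $d$ (test scale uses 0.5) |
| `rotationStep` | 1° | axis-rotation step (test scale uses 60°) |
| `clashTheta` | 0.17 | shared-interior clash threshold |
| `gapPenalty`, `scoreCap` | 1, 0 | alignment gap cost and extraction cap $x$ |
| `windowLength`, `windowSurfaceMin` | 15, 10 | surface window rule (2/3 of 15) |
| `fragmentAceThreshold` | 400 | stage-2 fragment filter |
| `interfaceCutoff` | 4.5 Å | predicted-interface distance |
| `vdwMargin` | 1 Å | actual-interface rule: $d < r_s + r_t + 1$ (strict) |
| `gridSpacing`, `proteinPointRadius`, `surfaceAtomRadius` | 1, 2, 1.5 Å | surface lattice |
| `topNPoses` | 10 | reported poses |

Distance comparisons are inclusive (`≤`) throughout, with the single
deliberate exception of the *actual*-interface rule and native contacts,
which the evaluation defines strictly (`<`). Boundary cases are
measure-zero for experimental coordinates; the lattice code additionally
allows a 1e-9 slack on the squared radius so that coordinates constructed
to sit exactly on a label boundary receive the same label along any
floating-point-equivalent code path.

## Evaluation statistics

`accuracyCoverage()` reports accuracy ($100\,|P \cap A|/|P|$) and coverage
($100\,|P \cap A|/|A|$) of a predicted residue set $P$ against the actual
set $A$ (pooled across subunits by default, per-subunit on request);
`fScore()` is their harmonic mean on the 0–1 scale; a prediction is a
*success* when accuracy ≥ 50% (inclusive), and an empty prediction counts
as a failure (conservative default). `irmsd()` follows the CAPRI-style
convention — the details (which atoms, which superposition) are a
convention of this package, not a claim about the original definition:
native-interface residues are taken from `actualInterface()`, their
C$_\alpha$ atoms are superposed by least squares (Kabsch, via bio3d), and
the RMSD over those atoms is reported. `nativeContactFraction()` uses
minimum heavy-atom cross distances per residue pair, consistent with the
atom-level 4.5 Å rule. Van der Waals radii are a shipped element table
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, fallback 1.70 Å).

## The synthetic fixture generator

`makePlantedComplex()` builds toy complexes in which the true interface is
known by construction: subunit B carries a dense slab, a 16-atom floor row
whose last 14 atoms have the favourable ACE type, and a rim column whose
favourable top atom is collinear with the patch axis; subunit A carries a
16-atom patch row (15 favourable atoms) held `pocketDepth` (default 3 Å)
above the floor, with body rows stacked over it. Under the toy table
(favourable pair −20, background +1) the favourable contact count is
maximised exactly at the planted pose, the planted pose is clash-free at
$\theta = 0.17$, every planted-interface atom is a surface atom, and the
fragment ACE is far below the 400 threshold — all verified at construction
time.

The construction is deliberately *lattice-commensurate*: the planted
anchor offset is a d-ball lattice vector whenever the grid pitch divides
`pocketDepth` (3 Å at test scale $\epsilon = 0.5$, 0.6 Å at the published
$\epsilon = 0.1$), the rim anchor lies on the ray through the patch axis so
the cap pole coincides with the native anchor position, and seeds vary
only whole-Ångström scene translations, exact axis-aligned proper
rotations, subunit sizes and jitter on non-interface atoms. The planted
pose is therefore *exactly* representable in the enumeration, and recovery
tests measure whether the pipeline finds it — not whether the
discretisation happens to straddle it. The flip side is a list of things
the generator does **not** emulate: real amino-acid chemistry and packing,
side-chain flexibility, partial surface burial of true interfaces,
near-degenerate alternative binding modes, and poses that are close to but
off the search lattice. Passing the recovery suite shows the pipeline's
stages compose correctly and its optimum is where the construction puts
it; it does not certify accuracy on experimental structures.

## Numerical and design choices

* **Ties.** All orderings (segment extraction, window scan, pose ranking)
  break ties lexicographically on indices, making every pipeline stage
  bit-reproducible.
* **Antiparallel anchors.** The minimal-rotation construction in
  `anchorTransform()` degenerates when the source and target directions are
  antiparallel; a 180° rotation about a deterministic perpendicular axis
  (cross with x, falling back to y) is used instead.
* **Degenerate anchors.** Anchor pairs closer than twice the grid pitch
  give an ill-conditioned cap and are skipped with a warning.
* **Frame dependence.** The d-ball lattice is anchored at the atom
  $b_{i'}$, so the whole enumeration is exactly equivariant under
  translations of the fixed subunit (tested). The lattice axes and the
  cap's azimuthal reference are world-frame, so equivariance under
  arbitrary rotations of B holds only to grid resolution — a documented
  property of the lattice constructions, not an accident.
* **Clash before score.** Clash rejection precedes ACE evaluation as an
  optimisation; it cannot change results because clashing poses are never
  ranked.
* **Problem sizes.** The test suite and the acceptance script run the
  generator's test scale — ε = 0.5, 60° rotations, toy complexes of
  ~30–180 atoms, 20 seeds — which exercises every stage in seconds while
  the published operating point (ε = 0.1, 1°) remains the package default
  for real use.

## Known limitations

Rigid subunits only; no score refinement or minimisation of ranked poses;
the shipped ACE values are synthetic placeholders until a user supplies a
real parameterisation; `dock()` fixes subunit B and assumes the caller
passes the larger subunit as B when that matters; mmCIF input and NMR
ensembles are out of scope.
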