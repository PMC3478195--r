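# aceDock

Rigid-body protein–protein **binding-site prediction by configuration
enumeration**. Given two subunit structures (PDB format), aceDock searches
over rigid placements of one subunit against the other, scores every
candidate configuration with the Atomic Contact Energy (ACE) desolvation
function, rejects clashing and non-surface placements, and reports the
lowest-energy configuration's interface residues. It is aimed at
structural bioinformaticians who want a transparent, fully deterministic
docking-based binding-site predictor together with the standard evaluation
machinery (accuracy, coverage, F-score, success rate, interface RMSD,
fraction of native contacts).

## The method in brief

A configuration is scored as

    E_ACE = sum over cross-subunit atom pairs (s, t) with ||s − t|| <= d of T[s, t],

with d = 6 Å and T an 18×18 atom-type contact-energy table,
T_ij = −ln[(N_ij/C_ij) / ((N_i0/C_i0)(N_j0/C_j0))] from observed/expected
contact counts against solvent. The search is pruned in three stages:

1. a **minimising Smith–Waterman** local alignment over the two atom-type
   sequences (ACE entries as match penalties, gap penalty 1, score cap 0)
   proposes candidate fragment pairs, filtered by a sliding 15-column
   window requiring ≥ 10 surface atoms per side — surface atoms come from
   a 1 Å labelled lattice (protein within 2 Å of an atom; interior iff all
   six neighbours protein; atom is surface within 1.5 Å of a surface
   point);
2. fragment endpoints become anchor pairs; candidate poses are the product
   of a **d-ball lattice** (pitch εd) for the first anchor, a **sphere
   cap** for the second, and **axis rotations** for the remaining degree
   of freedom; poses whose interior lattice points overlap by more than
   θ·min(X_A, X_B) (θ = 0.17) clash and are discarded; fragment pairs with
   no pose under an ACE of 400 are dropped;
3. the surviving anchor combinations are re-enumerated scoring the full
   structures, and the best clash-free pose defines the predicted
   interface (residue pairs with atoms within 4.5 Å).

The published 18×18 ACE parameterisation is not redistributed: the shipped
table (`inst/extdata/ace_table_synthetic.tsv`) is a labelled synthetic
stand-in in a documented editable format, and `buildAceTable()` rebuilds a
table from user-supplied counts. See the methods vignette
(`vignettes/acedock-methods.Rmd`) for the full model, parameter table and
design choices.

## Worked example

The package ships a seeded generator of toy complexes with a *planted*,
analytically known interface, so the whole pipeline can be exercised
without downloading anything:

```r
library(aceDock)

pc  <- makePlantedComplex(seed = 1)          # toy complex, planted interface
par <- new("ScoringParams", epsilon = 0.5, rotationStep = 60)  # test scale
res <- dock(pc@subunitA, pc@subunitB, pc@construction$table, par)
res
#> DockResult: ok
#>   k = 1 fragment pairs; 10 reported poses; best ACE = -1389
#>   predicted interface: 18 residue pairs
#>   counters: segments=1 fragmentPairs=1 survivingPairs=1 posesEnumerated=996 posesClashing=494
```

One alignment segment survives the surface window filter (k = 1 fragment
pair), 996 candidate poses are enumerated from its anchors, 494 clash, and
the best remaining pose scores ACE −1389 — 90 favourable patch–floor
contacts at −20 plus background contacts at +1. Its 18 predicted residue
pairs equal the planted interface exactly:

```r
identical(interfacePairs(res@interface), interfacePairs(pc@plantedInterface))
#> [1] TRUE
fScore(44.3, 70.5)   # the F statistic used throughout the evaluation
#> [1] 0.5441028
```

Real structures go through `readPDB()`/`assignAceTypes()`, or the thin
command-line wrapper:

```sh
Rscript inst/cli/acedock.R dock --receptor A.pdb --ligand B.pdb \
    --chains-r A --chains-l B --out-prefix run
Rscript inst/cli/acedock.R evaluate --receptor pred.pdb --ligand pred.pdb \
    --native complex.pdb --chains-r A --chains-l B --out-prefix eval
```

(exit codes: 0 success, 2 "no prediction", 1 I/O error; every run writes a
log with its effective configuration).

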