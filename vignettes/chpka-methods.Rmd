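---
title: "Computing and learning C–H acidity with chpka"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and learning C-H acidity with chpka}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chpka)
library(dplyr)
```

## The problem

Deprotonating a C–H bond creates a carbanion, and which C–H bond of a
molecule deprotonates first — the site with the lowest pKa — largely decides
the regiochemistry of enolate chemistry (aldol, Claisen, Michael additions)
and is a useful proxy for aryl C–H borylation sites. Experimental C–H pKa
values in DMSO are scarce, so chpka implements a two-track strategy:

1. an **energy track**: enumerate every symmetry-distinct C–H site, compute
   the heterolytic deprotonation free energy
   $\Delta G^\circ = E(\mathrm{A^-_{solv}}) - E(\mathrm{AH_{solv}})$
   for each site with a pluggable energy backend, and map the per-molecule
   minimum $\Delta G^\circ_{\min}$ onto experimental pKa values through an
   empirical linear free-energy relationship
   $\mathrm{p}K_a = a\,\Delta G^\circ + b$;
2. a **learning track**: describe each site carbon by sorted partial charges
   in topological shells and train gradient-boosted models that predict the
   site pKa directly, or flag the lowest-pKa site as a binary label.

Everything runs without a quantum-chemistry engine: energies and charges
enter through contracts (`energy_backend()`, `charge_provider()`), and the
package ships a deterministic synthetic world with known ground truth that
exercises every stage end to end.

## Site enumeration

Molecules are parsed through Open Babel; the canonical SMILES fixes the atom
order, so all atom indices are reproducible across input spellings. Two
routes produce the site list:

* the *fast path* groups H-bearing carbons into graph-automorphism orbits
  (igraph, with vertex colors for element/charge and edge colors for bond
  class, aromatic bonds distinguished from their kekulized orders) and
  deprotonates one representative per orbit;
* the *oracle path* deprotonates every H-bearing carbon and deduplicates by
  canonical anion SMILES.

Equivalent C–H bonds give the same carbanion, so the two routes must agree;
the test suite asserts that they do across the fixture set. Carbons that
carry a formal charge or radical are skipped with a warning — the workflow
is defined for closed-shell neutral acids. Each site records the number of
hydrogens pooled over its equivalence class, and sites are computed once per
class (the multiplicity is bookkeeping, not repeated computation).

## Conformers

Ensemble sizes follow `min(1 + 3 n_rot, 20)`. A rotatable bond is a
non-ring single bond between two non-terminal heavy atoms; rotatable-bond
counts differ subtly between toolkits, so the definition is stated
explicitly and exposed through `rotatable_bonds()`.

Embedding is an own-written deterministic internal-coordinate builder: a
breadth-first walk places atoms at ideal bond lengths (covalent radii with
bond-order corrections) and hybridization-dependent angles, rings open
cis-first so closure is cheap, and a harmonic relaxation over bond
distances (including ring-closing bonds), 1–3 distances and a soft steric
repulsion cleans the result. The builder uses no random numbers; additional
conformers are seeded random torsion rotations about the rotatable bonds.
This choice was forced by reproducibility: general-purpose 3-D generators
here do not accept a seed, and the ensemble contract demands bit-identical
geometries for a fixed seed. The geometries are coarse by design — energies
never come from the geometry itself but from the backend.

Ensembles are pruned to a 3 kcal/mol window above the minimum (inclusive:
only conformers *above* the window are removed), then deduplicated by
Butina clustering on best-fit (Kabsch) heavy-atom RMSD at 0.5 Å. Butina
ties (equal neighbor counts) resolve to the smallest conformer id so runs
are deterministic. Atom mapping in the RMSD is the identity — conformers of
one species share an atom order — which can over-count clusters for
topologically symmetric molecules; this is documented rather than solved.

One deliberate deviation from a pure centroid rule: when energies are
assigned, each cluster is represented by its lowest-energy member rather
than the centroid. A centroid rule can discard the global energy minimum as
a mere neighbor, and the stage exists precisely to feed an argmin; the
centroid rule remains available (`representative = "centroid"`).

## Energies and calibration

A backend is any deterministic function from (species, geometry) to a total
free energy in kcal/mol in implicit DMSO (ε = 47.2, 298.15 K); Hartree
values convert at 627.509474 kcal/mol. Adapters for external tight-binding
or DFT engines reduce to an XYZ writer plus an output parser
(`parse_xtb_energy()`); none is required. Backends that report vibrational
frequencies flag records with imaginary modes as `imaginary_freq` instead of
dropping them — silently dropping a site would bias the per-molecule
minimum.

Calibration is ordinary least squares of experimental pKa on
$\Delta G^\circ_{\min}$, with an iterative outlier loop: fit, predict,
remove every point whose |predicted − experimental| exceeds 5 pKa units,
refit, until stable (a `max_iter` of 10 guards against pathological cycling;
in practice the loop converges in one or two rounds). Points at or beyond
the DMSO autoprotolysis limit (pKa ≥ 35), where experimental values are
extrapolated, can be excluded up front; the flag defaults to on and such
points are reported separately from residual outliers. Outlier inspection in practice also involves
data-curation judgments (mislabeled values, structures that do not match
their literature source); those are not computations, so the package
automates only the residual rule and leaves curation to an explicit
exclusion list. Two points suffice for an interpolating line; the fit
refuses degenerate input (fewer than two distinct energies).

## Descriptors

The descriptor of a site carbon concatenates, for each topological distance
d = 0..6, the charges of all atoms exactly d bonds away, sorted descending
and right-padded to per-dataset slot widths. Radius 6 is the default.
Hydrogens are explicit and occupy shells. Design choices the descriptor
records in its schema (so models are reproducible):

* sort direction is descending — a fixed order is required and descending
  follows the sorted-charge convention this descriptor family uses;
* the pad value is 0.0, and each shell's true occupancy count is appended to
  the vector, so a learner can always distinguish padding from a genuine
  near-zero charge;
* slot widths default to the maximum occupancy observed in a first pass over
  the dataset, then freeze; a molecule that overflows a frozen width raises
  an error telling the user to recompute widths rather than silently
  truncating.

Truncating a radius-6 vector to radius 5 equals computing radius 5 directly
(tested), so stored descriptors can be narrowed without recomputation.

The default charge provider is a deterministic surrogate — a fixed function
of element, aromaticity, formal charge and heteroatom-neighbor count,
shifted to conserve net charge. It respects molecular symmetry exactly,
which is what the descriptor invariants require. A CM5-from-tight-binding
provider (20 conformers, force-field optimize, take the lowest-energy
conformer's charges) plugs into the same contract when an engine is
available.

## Models

Both tasks use gradient-boosted trees (xgboost). Labels for the
classification task: within each molecule, sites within a tolerance (0, 1
or 2 pKa units; default 1) of the lowest pKa are 1, everything else 0; ties
at the minimum are all positive, so every molecule has at least one true
site. The split is by compound — 20% of compounds held out
(`round(0.2 n)`, which reproduces 620/155 at n = 775), and five shuffled
folds each re-split the training compounds 90/10 — so no molecule leaks
sites across a split.

Hyperparameters are found by seeded random search over a declared space
(tree count, learning rate, depth, minimum child weight, row/column
subsampling, L1/L2, and a positive-class weight for the imbalanced
classifier), scored by the mean over folds of validation RMSE (regression)
or MCC (classification), then the best configuration is refit on the full
training set. One scoring detail: a validation fold that happens to contain
a single class makes MCC undefined; such folds are scored by accuracy
rescaled to [−1, 1] so that a perfect fit still counts as perfect, while
*reported* metrics keep the strict zero-denominator convention (MCC = 0,
PPV/NPV = 0), which is what makes the all-negative null model read
TPR = PPV = 0, TNR = 1, MCC = 0.

A regressor doubles as a site classifier: predict per-site pKa, then flag
sites within the tolerance of the parent's predicted minimum. Reaction-site
evaluation pools per-site confusion counts across reactions
(micro-averaging, reproducing a single confusion table); borylation mode
restricts candidates to aromatic C–H sites and widens the window to 1.5 pKa
units before flagging.

## The synthetic world

`make_world()` builds the ground truth the tests rely on: fixture molecules
(a literal core set spanning ketones, 1,3-dicarbonyls, esters, nitriles,
heteroaromatics, arenes, alkanes, sulfoxides/sulfones, nitroalkanes,
amides, ethers, extended by deterministic homolog series when more are
requested), per-site true pKa values from a functional-group rule (doubly
activated 12 < nitroalkane 17 < α-carbonyl 26 < α-ester 30 ≈ α-nitrile 31 <
benzylic 43 ≈ aromatic 44 < alkyl 51, plus a seeded ±2 jitter), and a
deprotonation-energy oracle
$\Delta G = (\mathrm{p}K_a^{true} - b)/a + \mathcal{N}(0, \sigma/|a|)$
with defaults a = 0.35 pKa/(kcal/mol), b = −150, σ = 1 pKa unit. The rule
tracks broad DMSO acidity trends to give the learners realistic structure;
it makes no claim of chemical accuracy, and passing tests demonstrate the
machinery (invertibility, calibration recovery, label plumbing), not
predictive power on real molecules. Real data differ in ways the world does
not emulate: correlated errors across related compounds, conformer-dependent
energies, resonance effects the functional-group rule cannot see.

At σ = 0 the whole pipeline is exactly invertible — calibration returns
(a, b) to machine precision and every site's true pKa comes back — and at
σ = 1 the pipeline's mean absolute error approaches the Gaussian mean
absolute deviation σ√(2/π) ≈ 0.80. The surrogate backend assigns each
species a constant energy (geometry-independent), so the conformer stages
cannot perturb the oracle; mock backends with geometry-dependent energies
are used where the conformer logic itself is under test.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the noiseless world at the
36-molecule core set (~83 sites), the noisy pipeline at 140 molecules
(~600 sites), calibration recovery at n = 200, Butina equivalence over 100
random small ensembles, and model tuning with a budget of 20 configurations
over ~250–400 sites — sizes chosen so the whole battery completes on a
single CPU in a few minutes while keeping the statistical checks
well-powered. Every random draw flows from explicit integer seeds; worlds,
splits, ensembles and tuned models regenerate bit-for-bit from the same
seed.

## A short worked example

```{r example, eval = FALSE}
world <- make_world(seed = 1, noise_sigma = 0)
backend <- surrogate_energy_backend(world)

res <- compute_site_pka(world$molecules, backend,
                        world$calibration[, c("id", "pka_exp")])
head(res)

fit <- attr(res, "calibration")
glance(fit)
autoplot(fit)
```

## Known limitations

* Geometries from the internal-coordinate builder are coarse; fused-ring
  and bridged systems relax to plausible but not physical conformations.
  Any serious energy backend should re-optimize internally.
* Open Babel's aromaticity and canonicalization define equivalence; corner
  cases (tautomers, exotic aromatics) inherit its behavior.
* Symmetry-aware atom mapping is not used in RMSD, over-counting clusters
  for symmetric species.
* The outlier loop automates only the residual rule; curation-type outliers
  need the explicit exclusion list.
* N–H/O–H/S–H acidity, tautomer enumeration, and steric or base-dependent
  (kinetic) selectivity are out of scope: the models predict the
  thermodynamic carbanion.
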