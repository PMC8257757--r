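---
title: "Two-state triage analysis of glycosylase lesion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state triage analysis of glycosylase lesion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeilTriage)
```

## The model

hNEIL1 is a broad-specificity DNA glycosylase: it initiates base excision
repair for a structurally diverse set of damaged bases while leaving the
vast excess of normal bases alone.  NeilTriage implements the quantitative
machinery for a *triage* view of how it does this.  When a flipped
nucleobase sits in the enzyme pocket, the GS-rich lesion-recognition loop
(hinged at Gly240 and Gly249) can adopt three conformations:

* **apo / encounter** — the loop is swung away from the base-binding
  position, as in the free enzyme (rotated by roughly 40 degrees about the
  hinge, with the residue-242 side chain more than 9 A from the base
  position);
* **242-in / activated** — the Lys or Arg side chain at position 242 makes
  a short (~3.0 A) hydrogen bond to a ring nitrogen of the flipped base via
  a tautomerization-dependent mechanism; only this state is catalytically
  competent;
* **244-in / quarantine** — Tyr244 stacks on the base (~3.6 A ring-centroid
  separation), burying it in a hydrophobic enclosure that *prevents*
  catalysis.  The two bound states swap the positions of residues 242 and
  244, a flip reminiscent of the kinase DFG flip.

Because the quarantine state competes thermodynamically with the activated
state, the observed single-turnover rate is auto-inhibited.  With the
binding step treated as pre-equilibrated, the rate is

$$ r = k_{cat}\,[\mathrm{ES}]_A
   = \frac{k_{cat}}{1 + e^{\Delta G/RT}}\,[\mathrm{ES}]
   = \tilde k_{cat}\,[\mathrm{ES}],
   \qquad \Delta G = \Delta G_{conf} + \Delta G_{chem}. $$

$\Delta G$ is the free energy of the activated state relative to the
quarantine state (positive when quarantine dominates and repair is
suppressed).  $\Delta G_{conf}$ carries the loop-conformation ("structural
check": stacking, desolvation) contribution, $\Delta G_{chem}$ the
tautomerization ("chemical check") contribution.  The package implements
the equality form of this rate law; the underlying substitution of the
activated population by its equilibrium value is an approximation the
model inherits.  $\Delta G_{conf}$ and $\Delta G_{chem}$ are *inputs*
(upstream enhanced-sampling or electronic-structure work, or population
estimates from `statePopulations()`); the package deliberately does not
recompute them from physics.

The pipeline has five stages, each usable on its own: coordinate I/O and
superposition (`readStructure()`, `superposeStructures()`), geometric
descriptors (`computeD242()`, `computeD244()`, `detectTautomerHbond()`,
`loopRotationAngle()`, `countShellWaters()`, `deltaNWater()`), state
classification and free energies (`classifyEnsemble()`,
`findMetastableZones()`, `statePopulations()`,
`deltaGFromPopulations()`), the rate law (`TwoStateModel()`,
`apparentKcat()`, `discriminationRatio()`, `buildTriageReport()`), and
single-turnover kinetics (`simulateTimecourse()`, `fitTimecourse()`,
`kobsRatioTest()`, `triageConsistencyCheck()`).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| temperature | 298.15 | K | free energies are quoted per RT; RT = 0.59248 kcal/mol at the default.  The source analyses quote RT without a stated temperature, so the conventional 25 C is used. |
| R | 1.98720425e-3 | kcal/(mol K) | gas constant |
| H-bond cutoff | 3.5 | A | donor–acceptor heavy-atom distance, inclusive at the boundary.  The crystallographic interrogation contact sits near 3.0 A; 3.5 A is the conventional heavy-atom criterion.  No angle term: X-ray models carry no hydrogens. |
| shell radius | 5.0 | A | water-counting shell around the base, matching the shell inspected in the crystal structures |
| state centroids | apo (12, 10); in242 (3, 8); in244 (8, 3.5) | A | operational (d242, d244) centroids consistent with the crystallographic conformers.  No numerical centroids are published for the conformational zones, so these ship as an explicit, overridable config (`inst/extdata/state_references.yaml`); classification never invents references silently. |
| zone bin width / threshold | 0.5 A / 0.2 of modal density | | landscape parameters are not published; both are configurable |
| time grids | 13 points, 0.083–180 min; extended 5–4320 min | min | the standard single-turnover sampling schedule, and a 72-h schedule for very slow substrates (see below) |
| amplitude bound | A <= 1.2 | | tolerates noise overshoot while rejecting degenerate fits |

## Descriptor operationalizations

Two quantities in the structural narrative need explicit numerical
definitions, and the choices here are stated prominently because other
reasonable choices exist:

* **Conformational landscape axes.**  The metastable-zone analysis uses
  (d242, d244) — the residue-242 terminal-nitrogen-to-base minimum distance
  and the 244/base ring-centroid distance — as the two axes describing the
  relative positions of the loop residues and the flipped base.  These two
  distances separate the three crystallographic conformers cleanly and are
  computable from any coordinate set.
* **Loop rotation angle.**  Both structures are superposed on the shared
  core C-alphas *outside* residues 240–249; the loop plane is taken through
  the C-alphas of the two hinge glycines and of residue 244, and the angle
  is measured about the hinge C-alpha axis.  This plane-through-apex
  construction is exact for rigid rotations about the hinge (the toy
  generator verifies 40.000 degrees on a constructed 40-degree rotation)
  but is one of several possible operationalizations of a loop swing; the
  function accepts any reference conformer.

Per-residue "terminal nitrogen" sets are enumerated explicitly (Lys NZ;
Arg NE/NH1/NH2; His ND1/NE2 for the 242His mutant); base heterocyclic-ring
atom names are hard-coded for canonical nucleotides and ring-preserving
lesions (dihydro-, glycol- and hydroxy-pyrimidines), while ring-rearranged
hydantoins fall back to all base heavy atoms with a flag.  Missing atoms
(for example the loop segments that are unbuildable in some crystal forms)
yield `NA` descriptors with a reason attribute — never silent imputation.

## What the synthetic generators emulate

`genConformationalEnsemble()` draws (d242, d244) snapshots from a
three-component Gaussian mixture whose component weights are Boltzmann
factors of per-state free energies: this emulates the *equilibrium
populations* of a well-converged simulation of the loop, with basin widths
(default sd 0.5 A per axis) far smaller than the basin separations, as in
the crystallographically distinct conformers.  It does not emulate
kinetics, barrier crossings, correlated or non-Gaussian basin shapes, or
classification ambiguity from overlapping basins — so green recovery tests
demonstrate that the estimator chain is correct and correctly propagates
counting error, not that real simulation data are this clean.

`genToyStructure()` builds minimal coordinate fixtures (idealized planar
hexagonal rings, uniform bond lengths, a C-alpha-only scaffold) whose
descriptors equal the requested values *exactly*, with the apo conformer
produced by rigidly rotating the loop about the hinge axis.  They are
geometry fixtures, not chemically valid models.  `genSolvationShell()`
places a Poisson-distributed number of water oxygens whose minimum distance
to the base falls inside the requested shell, plus a far-field set, so the
in-shell count is known exactly.  `genTimecourseDataset()` composes the
rate law with the one-phase-association observation model
$y = A(1 - e^{-k_{obs} t}) + \varepsilon$, with additive homoscedastic
Gaussian noise (no noise model is stated for the gel assays;
heteroscedastic densitometry error is out of scope).

All generators derive per-operation substreams from one master seed
(`seed * 7919 + 104729 * i mod 2^31 - 1`) and restore the caller's RNG
state, so multi-stage pipelines are replayable.

## Numerical choices

* `activatedFraction()` is evaluated as `plogis(-dG/RT)`: numerically
  stable in both tails, exact at 0.5 for dG = 0, and maps infinite dG to
  0/1 exactly.  Infinite free-energy components are legal limiting markers;
  only opposing infinities are an error.
* A fraction of zero in `deltaGFromPopulations()` returns an infinite-dG
  marker rather than throwing; the standard error uses binomial
  propagation on the log-ratio, $RT\sqrt{1/n_A + 1/n_Q}$.
* Classification ties break deterministically by label order
  apo < in242 < in244; alternate locations resolve to the
  highest-occupancy conformer with ties broken by altloc letter.
* The H-bond cutoff comparison is inclusive (a pair exactly at the cutoff
  counts).
* One-phase-association fits run bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`, A in [0, 1.2], k_obs >= 0) from three rate starts
  (1/t-half-reach, 1/t-max, 10/t-max), keeping the best residual; if every
  start fails the fit falls back to a profile search over k_obs with the
  conditionally optimal amplitude and is flagged `converged = FALSE`
  rather than raising.  All-zero data short-circuit to (A, k) = (0, 0).
* The extended 72-h grid places its 13 points quasi-geometrically over
  5–4320 min, weighted toward the hours that actually constrain a rate of
  order 1e-4 min^-1.  Inside the standard 180-min window such a curve is
  indistinguishable from a straight line, so amplitude and rate are not
  separately identifiable there — the test suite demonstrates both the
  failure on the standard grid and the recovery on the extended one.

## Problem sizes used in the checks

The package's own validation uses ensembles of n = 10,000 snapshots for
free-energy recovery (20 seeded replicates at each of
$\Delta G^\ast \in \{-2,-1,0,1,2\}$ kcal/mol, requiring 3-SE coverage of
at least 95%), n = 3,000 for zone detection, 200 seeded repeats of
3-replicate fits at noise sd 0.02 for kinetics recovery (median relative
error under 5%), and 1,000 random points for the classifier/enumeration
equivalence — sizes at which the binomial and curvature-based standard
errors the package reports are themselves well calibrated.

## Known limitations

* The H-bond criterion is distance-only; with hydrogens present one would
  add angular terms.
* No Markov-state modeling, kinetic clustering or transition-path
  analysis: the package quantifies equilibrium populations, not exchange
  rates between states.
* $\Delta G_{chem}$ and $\Delta G_{conf}$ are never computed from
  electronic structure or enhanced sampling here — they are inputs.
* Validation of the descriptor layer against deposited crystal structures
  requires the user to supply the coordinate files locally (no code path
  performs downloads); the packaged checks exercise the same code on
  synthetic conformers constructed to the published geometry, which tests
  the measurement machinery, not the deposited coordinates themselves.
* Multi-turnover Michaelis–Menten behaviour, AP-lyase second-step
  kinetics, and gel-image densitometry are out of scope; fraction-product
  tables are the expected kinetic input.
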