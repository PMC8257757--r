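# NeilTriage

Quantitative analysis of how the broad-specificity DNA glycosylase hNEIL1
*triages* flipped nucleobases between two competing interaction states of
its lesion-recognition loop: an **activated** ("242-in") state in which the
residue-242 side chain hydrogen-bonds the base and catalysis can proceed,
and a **quarantine** ("244-in") state in which Tyr244 stacks on the base and
auto-inhibits cleavage.  The balance of the two states lets one enzyme
excise a structurally diverse set of lesions while keeping gratuitous
repair of normal bases in check.

The package is for structural biologists and enzymologists who have (a)
protein–DNA coordinate files or tables of per-snapshot geometric
descriptors from conformational ensembles, and/or (b) single-turnover
cleavage time-courses, and want to connect loop geometry to state
populations, free energies and observed rates within one model.

## The model

Only the activated fraction of the enzyme–substrate complex reacts.  With
binding pre-equilibrated, the single-turnover rate obeys the
auto-inhibition rate law

    r = k_cat [ES]_A = k_cat / (1 + exp(dG/RT)) [ES] = k~_cat [ES]
    dG = dG_conf + dG_chem

where `dG` is the free energy of the activated state relative to the
quarantine state (positive = quarantine dominates, repair suppressed),
decomposed into a loop-conformation term (`dG_conf`, the "structural
check": stacking and desolvation of the base) and a tautomerization term
(`dG_chem`, the "chemical check").  Observed rates come from one-phase
association fits of fraction-product time-courses,
`y = A (1 - exp(-k_obs t))`.

Pipeline stages (each independently usable):

1. **structio** — PDB/mmCIF reading (via bio3d), altloc resolution, water
   separation, residue views, Kabsch superposition, minimal PDB writing.
2. **descriptors** — d242 (242 terminal N to base, min heavy-atom
   distance), d244 (244/base ring-centroid distance), the
   tautomerization-dependent H-bond call, the loop rotation angle about
   the Gly240–Gly249 hinge, solvation-shell water counts and
   desolvation profiles.
3. **states** — nearest-centroid classification into apo / 242-in /
   244-in, density-based metastable-zone detection, and
   `dG = RT ln(p_quarantine / p_activated)` with propagated errors.
4. **thermo** — the rate law: `TwoStateModel`, `activatedFraction()`,
   `apparentKcat()`, discrimination ratios, triage reports.
5. **kinetics** — simulation and bounded nonlinear fitting of
   single-turnover time-courses on the standard 13-point (0.083–180 min)
   or extended 72-h schedules.
6. **synthdata** — generators with exact ground truth for every stage
   (Boltzmann-weighted descriptor ensembles, toy conformers whose
   descriptors are placed exactly, Poisson solvation shells, kinetics
   datasets with truth sidecars).

## Worked example

```r
library(NeilTriage)

## three synthetic conformers, analyzed like any PDB input
dir <- tempfile(); dir.create(dir)
paths <- file.path(dir, c("activated.pdb", "quarantine.pdb", "apo.pdb"))
genToyStructure("in242", path = paths[1])
genToyStructure("in244", path = paths[2])
genToyStructure("apo",   path = paths[3])
analyzeStructures(paths, reference = paths[1])[,
  c("source", "d242", "d244", "hbond", "rotationDeg", "label")]
#>       source d242 d244 hbond rotationDeg label
#> 1  activated 3.00  8.0  TRUE           0 in242
#> 2 quarantine 8.00  3.6 FALSE          28 in244
#> 3        apo 9.63 17.3 FALSE          40   apo
```

The activated conformer shows the ~3.0 A interrogation hydrogen bond; the
quarantine conformer the 3.6 A stacking contact; the apo loop is rotated
40 degrees about the hinge with both contacts beyond 9 A.

```r
## a descriptor ensemble generated at dG = +1 kcal/mol, recovered
ens <- genConformationalEnsemble(ensembleSpec(
  freeEnergies = c(apo = 0, in242 = 1, in244 = 0), n = 10000, seed = 1))
statePopulations(ens[, c("d242", "d244")])
#> EnsembleSummary: 10000 classified snapshots ( 0 unclassifiable )
#>                apo    in242     in244
#> count    4637.0000 881.0000 4482.0000
#> fraction    0.4637   0.0881    0.4482
#> deltaG (activated vs quarantine): 0.9638 +/- 0.0218 kcal/mol at 298.15 K
```

The generating free energy (+1 kcal/mol) is recovered within two standard
errors from the classified populations.

```r
## the rate law over a parameter table
buildTriageReport(data.frame(
  variant = c("K242", "R242"), substrate = c("DHU", "DHU"),
  kcat = c(1.0, 1.0), dGconf = c(0, 0.6), dGchem = c(0, 0.4)))
#> TriageReport over 2 variant/substrate pairs
#>   variant substrate kcat dGconf dGchem temperature deltaG activatedFraction
#> 1    K242       DHU    1    0.0    0.0       298.1      0            0.5000
#> 2    R242       DHU    1    0.6    0.4       298.1      1            0.1561
#>   apparentKcat
#> 1       0.5000
#> 2       0.1561
```

A 1 kcal/mol quarantine penalty drops the activated fraction from 0.500 to
0.156, i.e. a 3.20-fold discrimination in apparent rate between the two
variants at equal intrinsic k_cat.

```r
## simulate a noisy single-turnover assay and fit it back
ds <- genTimecourseDataset(kineticsSpec(data.frame(
  variant = "K242", substrate = "DHU", kcat = 1, dGconf = 0, dGchem = 0),
  noiseSd = 0.02, seed = 2))
fitKineticsTable(ds)
#>   variant substrate     A  kObs     seA seKObs    rss converged nPoints
#> 1    K242       DHU 0.898 0.511 0.00526 0.0154 0.0226      TRUE      39
```

True values were A = 0.9, k_obs = 0.5 min^-1; the pooled three-replicate
fit recovers both within one standard error.

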