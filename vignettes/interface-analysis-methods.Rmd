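---
title: "Post-docking interface analysis and peptide mimetic design with boomdock"
author: "boomdock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-docking interface analysis and peptide mimetic design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boomdock)
```

# Scope and model

`boomdock` implements the computational stages that sit *after* structure
prediction and rigid-body docking when one characterizes a protein-protein
interface and designs short peptides that mimic one side of it. The
motivating system is the plant transcription factor Baby Boom (BBM), an
AP2/ERF-family regulator of embryogenesis whose two DNA-binding fragments
are docked against partner transcription factors (LEC1, LEC2, WUS, AGL15);
every stage, however, is generic over PDB inputs. Structure prediction,
the docking engine, molecular-dynamics engines and external peptide-folding
servers are out of scope: their outputs (confidence-scored models, pose
ensembles, score tables, trajectories) are this package's inputs.

The stages and their models:

1. **Confidence-based fragment extraction.** Predicted models carry a
   per-residue confidence score (pLDDT convention, 0-100) in the B-factor
   column. Residues with score strictly above a threshold (default 90, the
   usual ">90" rule; an inclusive mode exists because printed thresholds
   rarely state strictness) form maximal runs; runs separated by at most
   `mergeGap` low-confidence residues (default 15) are grouped into one
   docking fragment. The default reproduces the canonical two-fragment
   split of the receptor: intra-fragment gaps of at most 13 residues merge,
   the 19-residue gap between residue runs 295-296 and 316-317 splits.
   `mergeGap` is a free parameter because the grouping rule is a design
   choice, not something the confidence scores determine.

2. **Pose clustering (Daura/GROMOS).** Docked poses are compared by
   all-atom least-squares RMSD (Kabsch superposition, reported in nm). The
   clustering repeatedly extracts the pose with the most neighbors within
   the cutoff (neighbor: RMSD <= cutoff, default 0.3 nm) together with
   those neighbors, the pose becoming the cluster center. Equal neighbor
   counts break to the lower pose index so results are deterministic, and
   equal-sized clusters are recorded as ties -- the "most populated
   cluster" is then not unique and `representative()` says so rather than
   silently picking one.

3. **Interface detection by buried surface.** Solvent-accessible surface
   area uses the Shrake-Rupley quadrature: 960 quasi-uniform points per
   atom on the probe-expanded sphere (probe 1.4 A, Bondi element radii,
   both shipped as editable config). Per residue,
   `dSASA = SASA(side alone) - SASA(complex)` over identical coordinates,
   so burial is positive and `dSASA > 0` defines the interface set. With
   identical coordinates in both states the profile cannot be negative
   beyond quadrature noise; the implementation evaluates both states with
   the same point set, so far-from-interface residues get exactly zero.

4. **Classified contacts and the affinity model.** An interfacial contact
   is a cross-chain residue pair with any heavy-atom distance <= 5.5 A
   (inclusive; hydrogens are absent from the consumed models). Residues are
   classed charged (D, E, K, R), polar or apolar; the split ships as config
   because published tables rarely print their convention, and the contact
   table reports the full six class-pair counts plus both readings of the
   usual "Polar:Polar / Non-Polar:Non-Polar" columns (charged kept separate
   vs. folded into polar). Binding affinity is the published contact-based
   linear model: weighted class-pair counts plus the apolar and charged
   percentages of the non-interacting surface (surface = relative SASA of
   at least 5% of a residue-type maximum, interface removed), with
   intercept, all loaded from a versioned JSON config -- weights are data,
   not constants. The dissociation constant follows as
   `Kd = exp(dG / (R T))` with `R = 1.9872e-3 kcal/(mol K)`, 298.15 K by
   default. Printed (dG, Kd) pairs can only be checked to the rounding of
   the printed dG, which at one decimal means about 0.06 kcal/mol of slack;
   that consistency bound is what the test suite asserts for all twenty
   published pairs.

5. **Peptide mimetic design.** Interfacial residue lists (notation
   `"G131, F132, X, D137"`, where X marks one missing residue and hyphenated
   tokens like `R-185` are equivalent) are scanned for maximal stretches in
   which every gap is exactly one residue long; two or more consecutive
   missing residues end a stretch. Any number of such isolated gaps may
   occur in one stretch -- the only reading consistent with published
   peptides carrying two and three bridged gaps. Gaps are bridged with
   glycine, and candidates spanning at least 8 positions are kept. Running
   the bundled printed lists yields exactly the seven published sequences.
   Ids are assigned in input order (fragment-1 lists first, block order,
   then position); the published P-numbering interleaves the two fragment
   tables in a way that is not a deterministic function of the tables, so
   the package does not try to reproduce it -- the candidate set and
   lengths are what is comparable.

6. **Overlap scoring.** Receptor-side interface residues are counted
   against the receptor's DNA-binding ranges (fragment 1: 210-276,
   fragment 2: 312-370, config-overridable). This measures whether a
   designed peptide occupies the DNA-binding surface.

7. **Trajectory metrics.** RMSD supports independent fit and measure
   selections: fitting on the receptor while measuring the peptide keeps
   the peptide's translational motion in the series (the convention for
   judging whether a peptide stays docked); fitting on the measured
   selection removes rigid motion. RMSF superposes frames on the
   time-averaged structure (two fit passes) and reports, per residue, the
   root-mean-square displacement over frames and atoms, in nm; 0.3 nm is
   the customary "mobile residue" threshold. Hydrogen bonds use
   donor/acceptor heavy-atom templates per residue type with a
   distance-only criterion (default 3.5 A) because the models carry no
   hydrogens and no angle is measurable. Hydrophobic contacts default to
   cross-chain carbon-carbon pairs within 4.0 A, annotated main-chain
   (N, CA, C, O) versus side-chain; a permissive mode (any heavy-atom pair
   between apolar residues) matches interaction-diagram tools that also
   list N/O atoms.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| confidence threshold | 90 (strict >) | score | fragment extraction |
| mergeGap | 15 | residues | run grouping into fragments |
| cluster cutoff | 0.3 | nm | GROMOS neighbor rule |
| contact threshold | 5.5 | A | interfacial contact definition |
| SASA points / probe | 960 / 1.4 | - / A | quadrature accuracy, solvent size |
| NIS surface cutoff | 5 | % rel. SASA | non-interacting surface definition |
| H-bond cutoff | 3.5 | A | donor-acceptor distance |
| hydrophobic cutoff | 4.0 | A | carbon-carbon contact |
| min peptide length | 8 | positions | candidate filter |
| temperature | 298.15 | K | dG to Kd conversion |

# Synthetic data: what it emulates, what it does not

The generators stand in for the upstream tools so that every stage is
testable offline with known answers:

* `makeConfidenceTrack()` plants high-confidence segments (>90) on an
  ideal-geometry chain; everything else is at or below 90. It emulates a
  predicted model's confidence track, not its coordinates' realism.
* `makeToyComplex()` places ideal-geometry residues on a 12 A grid so the
  cross-chain contact map is *exactly* the requested pair set and burial
  cannot leak to neighbors (the SASA occlusion reach of two carbons is
  about 6.2 A, well under the grid spacing). The chains are not covalently
  continuous -- a deliberate trade of physical realism for exact ground
  truth. The construction is verified internally by a brute-force scan and
  fails loudly when a request is infeasible.
* `makePoseEnsemble()` separates cluster centers by random *deformation*
  fields rather than rigid moves (superposition would erase rigid
  separation), members jitter within the declared spread. The default
  center separation is `max(6 * spread, 0.5 nm)`: at least the documented
  `4 * spread` floor, and large enough that the partition is recoverable
  at the 0.3 nm cutoff, which needs separation > cutoff + 2 * spread.
* `makeTrajectory()` adds per-residue Gaussian jitter (expected RMSF =
  sigma * sqrt(3)) and an optional rigid ligand displacement after the
  reference frame.

Passing tests on these fixtures demonstrate algorithmic correctness --
recovery of planted truth at stated tolerances -- not performance on real
docked ensembles, whose pose diversity, packing and composition the
generators do not model. Published quantities that depend on the study's
own pose files and trajectories (per-complex contact counts, MD cluster
membership, specific hydrogen-bond partners) are therefore not reproduction
targets; everything derivable from printed tables is reproduced exactly.

# Numerical choices

* RMSD fitting uses the SVD form of the Kabsch solution with the
  determinant correction, so reflections are never applied. Units: PDB
  coordinates are Angstrom throughout; RMSD/RMSF convert to nm at the
  reporting boundary.
* RMSF fit bias: superposition removes 6 rigid-body degrees of freedom of
  the 3N coordinate variance, biasing RMSF down by roughly a factor
  `sqrt(1 - 2/N)` for N atoms of pure noise; recovery tests use chains
  large enough (about 60 atoms) that this sits well inside the 5%
  tolerance. The test suite uses 2000-frame trajectories and 20 seeds for
  this property, and 200 random matrices at n <= 20 for the clustering
  equivalence -- sizes chosen to exercise the estimators well past
  stochastic noise while keeping the default suite under two minutes.
* Contact and neighbor tests are inclusive (`<=`), matching the GROMOS
  convention at the cluster cutoff and the contact-model threshold; a
  `1e-12` slack guards squared-distance comparisons against floating-point
  noise on constructed geometries.
* The residue-list parser repairs a token that breaks number monotonicity
  to previous + 1 only in lenient mode, flagging it (`repaired`); strict
  mode errors. The bundled fragment-1 LEC2 block needs exactly one such
  repair (a printed residue number contradicts its own block's ordering and
  the fragment-2 table prints the corrected number for the same stretch).
* Two adjacent printed single-residue stretches separated by one missing
  residue merge under the single-gap rule (this occurs once in the bundled
  lists, at LEC1 residues 118/120); no stretch at or above the length
  filter is affected.
* Altloc handling keeps the highest-occupancy conformer, first on ties;
  predicted models have none, so this only matters for experimental inputs.
* SASA quadrature uses a deterministic golden-section spiral; the same
  point set serves bound and unbound states, making dSASA exactly zero far
  from the interface.

# Known limitations

* The affinity model is the published linear contact model; it is not a
  physics-based (MM/PBSA-class) estimate and its absolute dG on synthetic
  toy complexes is not meaningful -- only the model arithmetic and the
  dG/Kd conversion are asserted.
* Hydrogen-bond detection without hydrogens cannot check geometry beyond
  donor-acceptor distance; expect over-calls relative to angle-aware tools.
* mmCIF and nucleic-acid chains are unsupported; PDB only.
* The idealized peptide builder produces backbone + CB geometry at fixed
  torsions -- an input stand-in for externally modelled peptides, not a
  folding prediction.
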