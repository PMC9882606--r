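---
title: "Hotspot pharmacophores: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot pharmacophores: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Protein–RNA interfaces built around single-stranded RNA are broad and polar,
but their energetics are concentrated: typically one or two nucleobases are
buried far more deeply than their neighbours, stacked against aromatic
sidechains and pinned by a small number of intermolecular hydrogen bonds.
`hotphore` assumes that a small molecule reproducing the three-dimensional
arrangement of exactly these moieties — the aromatic ring systems plus the
hydrogen-bonding groups actually used — can substitute for the RNA hotspot,
and that everything else on the base (polar atoms that make no intermolecular
contact) is a liability rather than a requirement and may be treated as
carbon.

The pipeline therefore has four stages: **burial selection** (solvent
accessibility of each base, in the complex versus in the RNA alone),
**hydrogen-bond collection** (geometric criteria on heavy atoms, with an
angle term only where hydrogens exist), **polar reversion** (non-bonding base
N/O → carbon features), and **clustering** (single-linkage over feature
positions; each ring-containing cluster becomes one pharmacophore). Screening
inverts the representation: ligand conformers are aligned rigidly to the
template under a Gaussian shape-plus-typed-feature overlap objective and
scored with Tanimoto coefficients.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `burial_threshold` | 0.75 | – | "deeply buried" is qualitative; fractional burial alone flags tiny bases whose free area is small, hence the paired absolute criterion below. Both configurable. |
| `min_buried_area` | 40 | Å² | a hotspot base should lose a physically meaningful contact patch, not just a large *fraction* of a small one. |
| `hbond_dist` | 3.5 | Å | conventional heavy-atom donor–acceptor cutoff. |
| `hbond_angle` | 120 | deg | applied only when the donor hydrogen is present (NMR models); distance-only otherwise, because inventing hydrogen positions would manufacture geometry the structure does not contain. |
| `cluster_cutoff` | 4.5 | Å | stacked adjacent bases sit ~3.4–4.0 Å apart, so a dinucleotide hotspot forms a single cluster while separate pockets stay separate. |
| `sasa_points` | 1920 | – | golden-spiral Shrake–Rupley; per-atom error stays within 2 % of a converged reference wherever the accessible patch exceeds ~5 % of the sphere (sliver patches converge only at much higher density). Probe 1.4 Å, Bondi radii, hydrogens excluded. |
| `gaussian_p` | 2.7 | – | Gaussian amplitude; the exponent is then fixed by requiring the isolated-atom integral to equal the hard-sphere volume, which needs `p > 1`. |
| `shape_radius` / `color_radius` | 1.7 / 1.0 | Å | uniform heavy-atom radius (common shape-overlay practice; per-element radii available); tighter spheres for typed features so color rewards near-coincidence. |
| `n_random_starts` | 8 | – | added to the 4 proper inertial-axis flips; ties between starts break by start index, keeping results deterministic under a fixed seed. |
| `dedup_threshold` | 0.98 | – | two library entries whose pseudo-molecules mutually align at `S_combo ≥ 0.98` are geometric duplicates; the criterion behind published "unique pharmacophore" counts is not stated anywhere we could follow, so this value is explicit and logged. |

## Numerical choices

*Overlap volumes* are first-order: the set overlap is the sum of pairwise
Gaussian product integrals, neglecting higher-order intersection corrections.
This keeps the objective smooth, cheap, and exactly equal to the grid
integral of the product of the two summed densities (the approximation is
relative to hard-sphere volumes, not to the Gaussian model itself). Tests
hold pairs to 1 % and ≤10-atom sets to 5 % of a 0.1 Å grid oracle.

*Alignment* optimises 7 parameters (unit quaternion + translation) with
Nelder–Mead at `reltol 1e-6`; the quaternion is renormalised inside the
objective so the parametrisation is unconstrained. Rotation starts come from
principal axes of the two point clouds (4 proper sign flips) plus seeded
random rotations. Ring normals are deliberately *not* scored: centroid-only
color keeps the objective interpretable and testable against simple oracles;
normal-weighted color exists as a config extension, off by default.

*Dual-role polar atoms* (an atom hydrogen-bonding once as donor and once as
acceptor) emit a single feature carrying both capability flags; color
matching is per-role, so such a feature pairs with either a donor or an
acceptor on the ligand side, counted once per pair.

*MDS* uses classical (Torgerson) scaling as the initial configuration and
refines it by SMACOF stress majorisation with uniform weights. Majorisation
never increases raw stress — that monotonicity is asserted in the tests
rather than assumed. Exactly-planar distance inputs embed to stress < 1e-6.

*Hydrogen-bond distances* in fixtures and scoring use 2.9 Å as the canonical
planted geometry, comfortably inside the 3.5 Å detection cutoff.

*Degenerate inputs*: coincident atoms are legal in the accessibility sampler
(points exactly on a twin's surface count as accessible by the strict
inequality); a base inaccessible even in the free RNA has burial defined as 0
with a warning; an empty overlap set scores 0 with a warning; distance-matrix
alignment failures record distance 1 with a flag.

## The synthetic-data generator

`make_toy_complex()` builds complexes with *planted, known ground truth*:
ideal-geometry planar bases (regular-polygon rings at 1.39 Å bond length, a
short lateral backbone tail), occluding shells of alanine-like residues on a
6.2 Å sphere whose angular coverage is tuned by bisection until the measured
burial is within 0.05 of target — measured at 4× the production point
density, so the fixture's truth does not depend on the production SASA
settings — plus hydrogen-bond partner arms (lysine-like donors, backbone
carbonyl acceptors) at 2.9 Å, optional bridging waters, phenylalanine rings
at 3.8 Å parallel stacking geometry, and an optional clash wall. Everything
is deterministic given the seed; the same spec reproduces the PDB byte for
byte.

What the generator does *not* emulate: real backbone conformations, real
packing density, crystallographic disorder, protonation, or energetics.
Passing the planted-recovery tests shows the pipeline's selection logic and
geometry are correct, not that thresholds calibrated here transfer
unchanged to every experimental structure.

`make_msi1_like_complex()` is a synthetic reconstruction of one published
binding-site topology — the Musashi-1 RRM1 hotspot: stacked adjacent A106 and
G107 buried against three phenylalanine rings (23/65/96), with a lysine
sidechain donating to G107 O6 and backbone carbonyls accepting from G107
N1/N2 and A106 N6, four hydrogen bonds in all and no ordered waters. It is
built from the same ideal-geometry primitives, not from deposited
coordinates, so the shipped worked example runs entirely offline and
requires no structure download; it demonstrates the pipeline on a
topology-faithful stand-in. Running extraction on the real NMR ensemble is a
one-line substitution (`read_complex("<file>")`) when a structure file is at
hand.

## Design choices where the field is genuinely open

- **Burial definition.** Fractional burial alone, absolute buried area
  alone, or both? We require both (0.75 and 40 Å²): fraction captures
  "deeply buried", area suppresses degenerate positives on small or
  partially disordered bases.
- **What the reported score is.** Shape Tanimoto, color Tanimoto, and their
  mean are all emitted; ranking uses `S_combo`. Published overlay scores in
  `[0, 1]` do not identify which variant was used, so none of the published
  numerical scores are treated as reproduction targets here.
- **Distance symmetrisation.** Pharmacophore-to-pharmacophore alignment is
  not symmetric; `d = 1 − (S(P→Q) + S(Q→P))/2` averages the two directions
  and forces an exactly symmetric matrix.
- **Ensembles.** Extraction defaults to model 1; library building takes
  model 1 per NMR entry by default with a flag to include all models, since
  including every model inflates apparent library diversity with
  conformational replicates of the same complex.
- **Backbone atoms** may join a cluster when hydrogen-bonded (the method
  collects *any* RNA atom in an intermolecular bond) but cannot seed one:
  a pharmacophore without an aromatic ring has lost the feature that makes
  hotspot mimicry work, so ring-free clusters are discarded.
- **Conformer generation** is seeded distance-geometry embedding (ETKDG) +
  MMFF94 minimisation with RMSD pruning at 0.5 Å, capped at 200 conformers —
  determinism under a fixed seed was a hard requirement, and this
  combination provides it.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
toy complexes of ~200–900 atoms, pharmacophores of 10–25 features, probe
pseudo-molecules of 10–25 atoms, libraries of 6–10 entries, distance
matrices up to 20×20. These sizes exercise every code path while keeping a
full run in the minutes range on one CPU; all functions accept full-size
structures (the extraction stage on a ~1500-atom complex is seconds).

## Known limitations

- The interaction score is a capped Lennard-Jones plus per-bond bonus for
  clash filtering and coarse ranking only — it is not a physical energy
  function, and no pose minimisation is performed in the receptor.
- Shape overlap uses uniform heavy-atom radii and first-order volumes; it is
  not a bit-compatible reimplementation of any commercial overlay tool.
- No tautomer/protomer enumeration, no partial charges, no structure repair
  or protonation prediction, no symmetry expansion of crystal mates.
- Water handling stops at first-shell bridges.
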