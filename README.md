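# hotphore

Hotspot pharmacophores from protein–RNA complexes, and ligand shape
screening against them.

## The problem

RNA-binding proteins recognise single-stranded RNA across broad, flat, polar
surfaces — terrible targets for docking, and with no natural small-molecule
binding pocket. But the interface is not energetically uniform: complexes of
single-stranded RNA usually bury one or two nucleobases far more deeply than
the rest, and those bases, stacked on aromatic sidechains and locked in by a
handful of hydrogen bonds, carry most of the binding energy. They are the RNA
analogue of protein–protein interface *hotspots*.

`hotphore` turns that observation into a screening tool. It distills a
protein–RNA complex structure into a minimal **hotspot pharmacophore** — a
3-D template of ring, donor, acceptor, and carbon features — and then searches
for small molecules whose shape and hydrogen-bonding pattern can mimic it.
A molecule that reproduces the buried dinucleotide's geometry can reuse the
protein's own recognition machinery, sidestepping de-novo design against a
featureless surface. The same machinery, run across a *library* of
pharmacophores from many complexes, profiles a candidate compound for likely
off-target RNA-binding proteins and maps pharmacophore space in 2-D.

## Method

**Extraction.** For each nucleotide the burial fraction is
`b = 1 − SASA_base(complex) / SASA_base(RNA alone)`, computed by
Shrake–Rupley sampling (960 points/atom, probe 1.4 Å) over base (non-backbone)
atoms. Bases with `b ≥ 0.75` and an absolute buried area `≥ 40 Å²` are
hotspot bases. All RNA atoms in intermolecular hydrogen bonds
(donor–acceptor heavy atoms `≤ 3.5 Å`; D–H⋯A `≥ 120°` when hydrogens are
present; water bridges optional) are collected. Polar base atoms *not* in
hydrogen bonds are reverted to carbon — they need not be carried into a
ligand. Features within 4.5 Å are single-linkage clustered; each cluster with
at least one aromatic ring becomes one pharmacophore.

**Alignment and scoring.** Every atom/feature is a spherical Gaussian
`p·exp(−αr²)` with `p = 2.7` and `α` chosen so the isolated-atom integral
equals the hard-sphere volume. A conformer is rigidly aligned to a
pharmacophore by multi-start simplex optimisation of the first-order overlap
volume `V_AB(shape) + V_AB(color)`, where *color* overlap counts same-type
feature pairs only (ring–ring, donor–donor, acceptor–acceptor). Scores are
Tanimoto coefficients

    T = V_AB / (V_AA + V_BB − V_AB),   S_combo = (T_shape + T_color) / 2

all in `[0, 1]`. Aligned conformers are placed back into the receptor frame,
clash-filtered, and ranked; libraries of pharmacophores support selectivity
profiles and a stress-majorised 2-D MDS map.

**Conformers.** Seeded distance-geometry embedding (ETKDG) with MMFF94
minimisation and RMSD deduplication, via the bundled RDKit helper script
(`inst/python/embed_conformers.py`; requires `python` with `rdkit` on PATH).

## Worked example

The package ships a generator for a *synthetic* reconstruction of the
Musashi-1 RRM1/RNA binding-site topology (ideal-geometry bases and planted
protein contacts — not deposited coordinates):

```r
library(hotphore)

msi <- make_msi1_like_complex()
phores <- extract_pharmacophores(msi$structure)
length(phores)
#> [1] 1

phore <- phores[[1]]
phore
#> <pharmacophore> MSI1_RRM1_synthetic model 1 residues 106+107
#> # A tibble: 4 x 2
#>   kind         n
#>   <chr>    <int>
#> 1 acceptor     1
#> 2 carbon      17
#> 3 donor        3
#> 4 ring         4

annotate_stacking_partners(msi$structure, phore)
#> # A tibble: 3 x 4
#>   chain resno resname min_dist
#>   <chr> <int> <chr>      <dbl>
#> 1 A        23 PHE         3.8
#> 2 A        65 PHE         3.7
#> 3 A        96 PHE         4.82
```

One pharmacophore is found, spanning the stacked adjacent bases A106+G107.
Its four donor/acceptor features are G107 O6 (acceptor, from a lysine
sidechain bond), G107 N1 and N2 (donors, to a backbone carbonyl), and A106
N6 (donor); the four aromatic rings of the purine pair are retained, and the
three phenylalanines stacking against them are recovered. Aligning a probe
molecule built from the pharmacophore itself scores `S_combo ≈ 1.00`:

```r
probe <- make_probe_ligand(phore)
fit <- align_to_pharmacophore(probe, phore)
tidy(fit)[, c("T_shape", "T_color", "S_combo")]
#> # A tibble: 1 x 3
#>   T_shape T_color S_combo
#>     <dbl>   <dbl>   <dbl>
#> 1       1       1       1
```

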