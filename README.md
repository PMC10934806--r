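# abconform

Conformational-descriptor analysis for ensembles of the 42-residue
amyloid-β peptide (Aβ42) and of S-shaped cross-β fibril models, in R.

Molecular-dynamics studies of Aβ42 — wild type and the familial variants
E22Q (Dutch), E22G (Arctic), E22K (Italian), D23N (Iowa) — are typically
summarised by a small set of conformational descriptors rather than raw
trajectories. `abconform` computes those descriptors from multi-model PDB
trajectories:

* **Monomers**: per-residue secondary-structure timelines and α-helix /
  β-sheet content from Kabsch–Sander backbone hydrogen-bond energies;
  residue-pair hydrogen-bond frequencies in the turn-bearing 16–42
  region; GROMOS-style RMSD clustering with a cluster-weighted
  **U-shape percentage**; Cα contact maps; mass-weighted radius of
  gyration — the columns of a standard monomer summary table.
* **Fibrils** (2MXU-like stacks, residues 11–42 per strand): the five
  compactness distances
  D_HC (Gly33 strand 3↔8), D_VC (Phe19–Val39 per core strand, averaged),
  D_HE (Gln15 strand 3↔8), D_VE (Glu11–Val39 averaged),
  D_IS (His14 of adjacent core strands), plus the fan-like motion
  amplitude (range of D_VE) and the variance fraction of the first Cα
  principal component.
* **Synthetic ground truth**: a generator builds ideal helices, β-strands,
  U-shaped hairpins, mixture ensembles with Gaussian noise and scripted
  hydrogen-bond contacts, and fibril stacks with programmable rise,
  fan-opening schedules and strand dissociation — so every analysis can
  be validated against known answers without any external data.

The core statistics are standard: Kabsch SVD superposition with
RMSD(i,j) matrices, RoG = √(Σmᵢ|rᵢ−r_com|²/Σmᵢ), Kabsch–Sander
E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the −0.5
kcal/mol bond threshold, and PCA of superposed Cα coordinates.

## Worked example

```r
library(abconform)

## a 60-frame ensemble: 75% U-shaped hairpins, 25% extended, 1 A noise
tr  <- make_monomer_ensemble(n_frames = 60,
                             weights = c(U = 0.75, extended = 0.25),
                             sigma = 1.0, seed = 2)
rep <- analyze_monomer(tr)
print(rep)
#> Monomer report
#>   alpha-helix : 8.3%
#>   beta-sheet  : 3.9%
#>   HB (16-42)  : None
#>   U-shape     : 75.0%
#>   RoG         : 18.7 +/- 13.5 A
```

The U-shape percentage recovers the programmed 75% mixture exactly: the
trajectory clusters into a hairpin and an extended basin, and the
hairpin cluster holds 75% of frames. The helix content is what survives
of the hairpin's two helical arms under 1 Å coordinate noise, and no
residue-pair hydrogen bond persists in ≥ 10% of frames ("None", as in
disordered metal-free ensembles).

```r
## a 10-strand fibril driven from the open (32 A) to a closed (22 A) state
fb  <- make_fibril(n_strands = 10, n_frames = 100,
                   fan_targets = seq(32, 22, length.out = 100))
frep <- analyze_fibril(fb)
print(frep)
#> Fibril report (10 strands, 100 frames)
#>   descriptor mean  sd
#> 1       D_HC 24.0 0.0
#> 2       D_VC 21.8 1.6
#> 3       D_HE 24.0 0.0
#> 4       D_VE 27.0 2.9
#> 5  D_IS_mean  4.8 0.0
#>   fan amplitude: 10.0 A | PCA mode-1 fraction: 1.00
```

D_HC, D_HE and D_IS are pure stacking distances (5 × 4.8 Å and 4.8 Å for
an in-register stack) and stay constant while the fan hinge sweeps D_VE
from 32 to 22 Å — amplitude 10 Å, with essentially all Cα variance in
one collective mode.

A command-line front end is installed with the package
(`exec/abconform`): `abconform generate|monomer|fibril --config cfg.json
--in traj.pdb --out outdir`, with per-threshold override flags.

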