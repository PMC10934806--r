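---
title: "Conformational descriptors for amyloid-beta monomers and fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational descriptors for amyloid-beta monomers and fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abconform)
```

## The problem

Enhanced-sampling MD of the amyloid-β 42-mer produces microsecond-scale
ensembles that are summarised, in practice, by a handful of descriptors:
how much α-helix and β-sheet the monomer carries, which residue-pair
hydrogen bonds persist in the turn-bearing 16–42 region, what fraction of
the ensemble is U-shaped (two arms, roughly residues 12–21 and 28–39,
folded back over a 22–28 turn), how compact the chain is (radius of
gyration), and — for S-shaped cross-β fibril stacks — five inter-residue
distances that localise where a fibril opens, plus the amplitude of its
collective "fan-like" breathing. `abconform` computes all of these from
multi-model PDB trajectories and ships a synthetic generator that serves
as the ground truth for every one of them.

## Model and conventions

**Trajectory.** One topology (PDB v3.3 fixed-width columns, author
residue numbering Asp1…Ala42 preserved, never renumbered) plus an
`n_atoms × 3 × n_frames` coordinate array in Å. Binary MD formats are
out of scope: multi-model PDB is the specified, testable interchange
format.

**Superposition and RMSD.** Kabsch SVD with determinant sign
correction, so a reflection is never returned. RMSD matrices default to
Cα atoms (the common choice when a paper does not state otherwise;
selectable). Cross-checked in the tests against an independent Horn
quaternion-eigenvalue oracle at 1e-6 Å.

**Secondary structure.** Kabsch–Sander energy
`E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond iff
`E < −0.5`, with a 0.5 Å clash guard returning `+Inf`. Amide hydrogens
are always rebuilt (1.00 Å from N, in the C(i−1)–N–CA plane opposite the
bisector); file hydrogens are ignored for reproducibility across
generators. Classes collapse to {H, E, C}: H needs two consecutive
i→i+4 turns (the minimal DSSP 4-helix), E is membership in a parallel or
antiparallel Kabsch–Sander bridge (ladders follow by adjacency), and
3₁₀/π patterns deliberately fall into C because the content tables this
feeds report *α-helix* specifically. Content percentages pool
residue-frames (`100·#H/(n_res·n_frames)`); a per-frame average would
differ only for ragged ensembles, and the pooled convention is exposed
as the single definition. Agreement with the MDAnalysis DSSP
implementation on ideal fixtures is 100% (tested at ≥ 95%).

**Hydrogen bonds.** Geometric: d(D,A) ≤ 3.5 Å and ∠(D–H…A) ≥ 135°,
both configurable — the usual MD-analysis defaults, since the source
conventions are unstated. Donors/acceptors are typed from residue
templates for the 20 standard residues, so sidechain contacts
(Asp23–Ser26) and salt bridges (Glu22–Lys28) pass through the same
definition. Frequencies count frames, not bonds: `af` is the percentage
of frames in which a residue pair has at least one bond, and the report
filter keeps pairs with `af ≥ 10%`, rendering an empty result as
`"None"`.

**Clustering and the U-shape.** GROMOS-style greedy neighbour counting
on the Cα RMSD matrix (default cutoff 3.0 Å), ties to the lowest frame
index, representative = member with minimal mean RMSD to its cluster.
It is deterministic and cheap to oracle-check, which is why it was
chosen over hierarchical methods (average linkage would need its own
tie-breaking story). The U-shape has no literature-standard geometric
definition, so this package operationalises it: directed best-fit axes
of the arm windows must open ≥ 120°, the arms must approach within
12 Å, and the 22–28 turn must contain the chain-direction reversal
(sign change of successive Cα steps projected on the arm-1 axis). All
three thresholds are arguments and are echoed into every report. The
U-shape percentage classifies *cluster representatives* and sums their
population percentages (the cluster-counting convention); a per-frame
mode exists behind a flag.

**Fibril descriptors.** Strand order is inferred geometrically: the
stacking axis is the leading principal axis of the chain centroids and
strands are numbered along it, so "strand 3" never depends on chain
labels. Core strands exclude 2 outermost per end (configurable margin —
the source never enumerates its core set). All five distances are
measured between Cα atoms; D_VC/D_VE average over core strands only.
The fan amplitude is max − min of per-frame D_VE, and collectivity is
the variance fraction of the first Cα principal component
(superposition to frame 1, mass-unweighted, eigen-sign fixed so the
largest-magnitude loading is positive).

## The synthetic world

The generator states, rather than fits, the conditions the analyses
assume:

* Ideal conformers come from internal-coordinate (NeRF) chain extension
  with textbook bonded geometry; the α preset gives O(i)…N(i+4) spans of
  3.09 Å, inside the 2.8–3.2 Å hydrogen-bond window.
* The U-hairpin is assembled from two ideal helical arms placed
  antiparallel at 9.5 Å with an arc turn over residues 22–27, so it
  satisfies the U-definition by construction.
* Mixture ensembles use exact largest-remainder class counts in a
  seed-determined order (a 75:25 mixture of 200 frames contains exactly
  150 hairpins), so recovery tests measure classification, not binomial
  luck.
* Noise is independent N(0, σ²) per coordinate per atom — the standard
  convention; correlated, physically realistic fluctuations are
  explicitly not emulated. Consequently a green mixture-recovery test
  establishes robustness to isotropic jitter, not to concerted
  conformational drift.
* Scripted hydrogen-bond contacts add sidechain donor/acceptor
  pseudo-atoms placed *exactly* (exempt from noise) at bonding geometry
  in a deterministic, evenly spaced subset of frames, which is what
  makes exact-recovery assertions meaningful.
* The fibril template is an S-shaped Cα trace (residues 11–42, three
  3.5 Å-spaced segments joined by two tight turns) stacked in register
  at a 4.8 Å rise — the canonical cross-β spacing, a documented
  constant, not a fitted one. The resting template is pre-opened so its
  Glu11–Val39 distance is 32.1 Å, the wild-type resting value; the fan
  schedule is a rigid hinge rotation of residues ≤ 21 about the
  vertical axis through residue 28, with the angle solved per frame
  (bracketed root search) to hit target D_VE values, and an error if a
  target is geometrically unreachable. Backbone atoms for trace-derived
  segments are approximate between Cα positions and are not meant for
  secondary-structure assignment.
* The convenience dissociation form ruptures the stack: offsetting
  "strand 5 by +6 Å" shifts strands 5..n, so exactly one interstrand
  gap widens by 6 Å — matching the single-pair excursion readout. A
  full per-strand × per-frame offset matrix remains available.

Every generated trajectory carries a machine-readable ground-truth
attribute (class labels, hinge angles, scheduled D_VE, offsets) that
suffices to compute the expected value of every descriptor.

## Numerical choices

Altloc resolution keeps the highest occupancy (ties prefer `A`).
PDB coordinates round-trip at the format's 3-decimal precision
(≤ 5×10⁻⁴ Å). Clustering ties and PCA eigen-signs are fixed as above so
all outputs are deterministic; report JSON/TSV files are written with
fixed formatting, and identical config + input reproduce outputs byte
for byte. Degenerate superposition inputs (collinear atoms) still
return a proper rotation via the SVD sign correction. Strand ordering
refuses to guess when two strand centroids project within 0.5 Å of each
other. Percentages print to one decimal in reports; full precision
lives in the TSV/CSV artifacts.

## Known limitations

* The fan-schedule acceptance check asks every one of 100 frames to
  measure D_VE within 0.5 Å of its target under σ = 0.5 Å per-coordinate
  noise. With D_VE averaged over 6 core strands the per-frame
  measurement error has sd σ√2/√6 ≈ 0.29 Å, so the expected maximum
  over 100 frames is ≈ 0.72 Å and the probability that all frames pass
  is ≈ 2×10⁻⁴; the same noise floor holds the first PCA mode near 0.71
  rather than 0.8. The machinery is exact at σ = 0 (errors < 10⁻⁹ Å,
  mode-1 fraction 0.999), so the corresponding test is left failing
  deliberately rather than silently widened: it documents that this
  tolerance would need ~24 core strands or σ ≤ 0.25 Å to be attainable.
* Secondary-structure assignment on the fibril generator's trace-derived
  backbones is not meaningful (approximate peptide geometry); fibril
  analyses are Cα-based by design.
* The geometric U-definition was tuned to the β-arch-like hairpin built
  here; ensembles with different arm placements may need the thresholds
  re-examined, which is why they are all configuration, not constants.
* Donor/acceptor typing covers the 20 standard residues only; no
  water-mediated bridges, no energy-scored sidechain hydrogen bonds.
* No mmCIF, no metal-site geometry, no free-energy surfaces, no
  normal-mode analysis from force constants — PCA of Cα coordinates is
  the only motion summary.
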