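Package: abconform
Title: Conformational Descriptors for Amyloid-Beta Monomer and Fibril Ensembles
Version: 0.1.0
Authors@R:
    person("The abconform authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Analysis of conformational ensembles of the 42-residue
    amyloid-beta peptide (Abeta42) and of S-shaped cross-beta fibril models.
    Reads and writes multi-model PDB trajectories; computes Kabsch
    superpositions, all-to-all RMSD matrices, mass-weighted radii of
    gyration and principal components of C-alpha motion; assigns
    three-class secondary structure (helix/sheet/other) from
    Kabsch-Sander backbone hydrogen-bond energies; detects geometric
    hydrogen bonds and tabulates per-residue-pair contact frequencies;
    performs GROMOS-style greedy RMSD clustering with U-shape
    classification of cluster representatives and contact maps; and
    measures the five fibril compactness distances (horizontal and
    vertical core/external plus interstrand) together with fan-like
    motion amplitude. A synthetic generator builds ideal helices,
    beta-strands, U-shaped hairpins and stacked fibril models with
    programmable fan-opening and strand-dissociation schedules, giving
    every analysis a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
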