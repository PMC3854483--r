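Package: pistack
Title: Aromatic Stacking and Binding Analysis of Peptides on Carbon
    Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the adsorption of small amyloidogenic peptides
    onto carbonaceous nanomaterials (C60 fullerene, single-wall carbon
    nanotubes, graphene).  Provides deterministic generators for the three
    nanomaterial geometries with aromatic ring perception, a geometric
    classifier of peptide-surface pi-stacking (none / offset / face-to-face)
    with six-category two-ring arrangement tracking and occupancy statistics,
    per-residue contact stability, buried contact area, radial distribution
    functions and RMSF, Kabsch-superposition RMSD single-linkage clustering
    with representative-structure selection, and umbrella-sampling free-energy
    profiles via the weighted histogram analysis method (WHAM).  A synthetic
    trajectory and umbrella-window generator with ground-truth labels supports
    validation of every analysis without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
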