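# pistack

Aromatic stacking and binding analysis of peptides on carbon
nanomaterials.

## What it is for

Amyloidogenic peptides adsorb strongly onto carbonaceous nanomaterials —
C60 fullerenes, single-wall carbon nanotubes, graphene — and the
curvature of the surface changes how they bind, move and (potentially)
seed fibrils.  The workhorse observables in such studies are geometric:
which of the peptide's aromatic rings is π-stacked on the surface and
how, which residues stay in van der Waals contact, how much surface area
is buried, how structured the surrounding water is, and how much free
energy it takes to pull the peptide off.  `pistack` implements that
analysis layer for R, for structural-bioinformatics users who have (or
want to simulate placeholders for) multi-frame coordinates of a peptide
over a rigid nanomaterial.

## What is inside

* **Geometry generators** — `build_c60()` (analytic truncated
  icosahedron, 60 atoms on one sphere, bond lengths 1.40/1.46 Å),
  `build_armchair_nanotube(n, min_length)` (whole translational cells of
  4n atoms, period √3·a_cc; (5,5) at ≥38 Å gives 320 atoms, diameter
  6.78 Å), `build_graphene()` (periodic sheet from the 4-atom
  orthorhombic cell), and `detect_rings()` (minimal 5-/6-cycles of the
  bond graph with centroids and best-fit normals).
* **π-stacking classifier** — per ring and frame: *none* if the minimum
  ring–surface atom distance exceeds 4.5 Å or the ring tilts more than
  30° from the nearest surface-ring normal; otherwise *face-to-face* if
  the lateral centroid displacement from the nearest hexagonal surface
  ring is below 0.71 Å (half a C–C bond), else *offset*.  Two rings give
  six arrangement categories; `track_trajectory()`, `occupancy()` and
  `tracking_map()` accumulate them.
* **Contact statistics** — `contact_stability()` (% of frames with any
  residue atom < 4 Å from the surface), `buried_contact_area()`
  (Shrake–Rupley buried SASA), `rdf()` (ideal-gas-normalised g(r)),
  `rmsf()` (per-residue fluctuation after Kabsch superposition).
* **Clustering** — `kabsch_rmsd()` and `single_linkage_cluster()`
  (connected components under a 2 Å RMSD cutoff, medoid representatives
  of the three largest clusters).
* **Free energies** — `wham_solve()` (standard WHAM self-consistency on
  umbrella windows, harmonic bias k = 8000 kJ mol⁻¹ nm⁻²),
  `dissociation_free_energy()` (terminal-plateau ΔG),
  `binding_energy()` (E_complex − E_peptide − E_nanomaterial),
  `window_overlap()` diagnostics.
* **Synthetic data with ground truth** — `build_peptide_model()`
  (all-atom zwitterionic peptide; MSTYTGIFTDQ → 169 atoms, charge −1),
  `place_ring()`/`synth_adsorption_trajectory()` (posed phenyl rings with
  labels the construction forces), `sample_biased_windows()` (Metropolis
  samples from flat/harmonic/Morse-like potentials),
  `synth_hydration_shell()`.
* **I/O** — multi-frame XYZ, PDB (via bio3d), single-frame GRO (nm→Å),
  and plain-text umbrella window files.

## Worked example

Pose a peptide's two phenyl rings over graphene on a known schedule, let
the package classify every frame, then recover a 5 kcal/mol synthetic
binding well by umbrella sampling + WHAM:

```r
library(pistack)

graphene <- build_graphene(30, 30)
pep <- build_peptide_model("MSTYTGIFTDQ")
pep
#> <peptide_model> MSTYTGIFTDQ, 169 atoms, formal charge -1 (zwitterionic)

sched <- c(
  lapply(1:6, function(i) list(tyr = pose_spec("FACE_TO_FACE", 3.4),
                               phe = pose_spec("FACE_TO_FACE", 3.5))),
  lapply(1:3, function(i) list(tyr = pose_spec("OFFSET", 3.5, lateral_shift = 1.0),
                               phe = pose_spec("NONE", 6.0))),
  list(list(tyr = pose_spec("NONE", 6.5), phe = pose_spec("NONE", 6.5))))
sim <- synth_adsorption_trajectory(pep, graphene, sched, seed = 1)
rec <- track_trajectory(sim$trajectory, graphene, sim$selectors)
occupancy(rec)
#> <stack_occupancy> over 10 frames
#>   category: 1: 10.0%  2: 30.0%  3: 0.0%  4: 0.0%  5: 0.0%  6: 60.0%
#>   main groups: none 10.0% | offset 30.0% | face-to-face 60.0%

w <- sample_biased_windows("morse_like", list(depth = 5, alpha = 1.2, d0 = 4),
                           centers = seq(3.5, 10.5, 0.35),
                           n_per_window = 5000, seed = 105)
pmf <- wham_solve(w)
pmf
#> <pmf_profile> 78 bins over [3.45, 11.15] A at 300 K; converged after 2205 iterations
#>   free energy range: 0 to 5.08 kcal/mol
dissociation_free_energy(pmf)
#> [1] 4.83
```

The occupancy table is exactly the 6/3/1 frame schedule (categories 6, 2
and 1), and the recovered dissociation free energy sits within a few
percent of the 5 kcal/mol ground-truth well depth.

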