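---
title: "Methods: aromatic stacking and binding analysis on carbon nanomaterials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aromatic stacking and binding analysis on carbon nanomaterials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pistack)
```

## Scope and model of the data

`pistack` analyses how a short aromatic-bearing peptide adsorbs onto
carbonaceous nanomaterials of decreasing curvature — a C60 fullerene, a
single-wall carbon nanotube and a graphene sheet.  The package implements
the *analysis* layer of such a study: given multi-frame coordinates of a
peptide over a (restrained) nanomaterial it classifies the π-stacking
state of the peptide's two phenyl rings frame by frame, accumulates
arrangement statistics, measures per-residue contact stability, buried
contact area, water structuring (RDF) and flexibility (RMSF), clusters
conformations by RMSD, and turns umbrella-sampling windows into a
potential of mean force (PMF) by WHAM.  It does **not** run molecular
dynamics: all inputs are either user trajectories or the package's own
synthetic generator, which produces labelled data for validation.

## Nanomaterial geometries

All three generators are deterministic and parameter-free apart from the
carbon–carbon bond length (1.42 Å by default, so that half a bond —
0.71 Å — is the face-to-face displacement threshold used by the
classifier).

**C60.**  Buckminsterfullerene is built analytically as a truncated
icosahedron.  An icosahedron edge of length $L = 2 b_{65} + b_{66}$
truncated at fraction $t = b_{65}/L$ from each end yields exactly the two
graphitic bond classes: the mid-segment of each edge becomes the
hexagon–hexagon bond ($b_{66} = 1.40$ Å) and the truncation points around
each vertex form pentagons with edge $b_{65} = 1.46$ Å.  Vertex
transitivity puts all 60 atoms on one sphere; with these bond lengths the
radius is

$$ r = R_{\mathrm{ico}}\sqrt{1 - 2t(1-t)\left(1 - \tfrac{1}{\sqrt 5}\right)}
     = 3.564\ \text{Å}, $$

consistent with the nominal ∼3.5 Å radius of C60.

**Armchair nanotube.**  An $(n,n)$ tube is the honeycomb lattice rolled so
that the circumference $3 n a_{cc}$ runs along the armchair direction; the
translational cell holds $4n$ atoms and repeats every $\sqrt 3\,a_{cc}$
along the axis.  The generator uses the fewest whole cells reaching the
requested length and maps atoms exactly onto the cylinder, so every atom
is equidistant from the axis.  For $(5,5)$ at 1.42 Å this gives a
$21.3/\pi = 6.78$ Å diameter and, for a ≥38 Å tube, 16 cells × 20 atoms
= 320 atoms.

**Graphene.**  The sheet is tiled from the 4-atom orthorhombic cell
($\sqrt 3 a_{cc} \times 3 a_{cc}$), rounding the requested extent *up* to
whole cells so no partial hexagons appear, with the cell periodic in the
sheet plane.  A 27 × 20 supercell reproduces the common 2160-atom model.

**Ring perception.**  Bonds are perceived with a 1.7 Å distance cutoff
(comfortably above both bond classes, far below the 2.46 Å second
neighbour), honouring minimum-image convention on periodic axes; atoms
with more than three bonds raise an error.  Rings are the minimal 5- and
6-cycles found by closing each bond angle with a shortest path
(smallest-set-of-smallest-rings semantics for graphitic lattices), with
member coordinates unwrapped across periodic boundaries.  Each ring
carries its centroid and the best-fit-plane unit normal (smallest singular
direction of the centred members).  Normal signs are cosmetic — the
classifier folds angles into [0°, 90°] — and default to +z-dominant, or
toward a reference point when supplied.

## The π-stacking classifier

A peptide phenyl ring is classified against the surface with three
thresholds (`stacking_params()`), all acting geometrically:

* **no stacking** if the minimum atom–atom distance between ring and
  nanomaterial exceeds 4.5 Å, *or* the angle between the ring normal and
  the surface normal exceeds 30°;
* otherwise **face-to-face** if the ring centroid sits within 0.71 Å
  (half a C–C bond) of the nearest hexagonal surface-ring centroid,
  **offset** otherwise.

Two conventions were genuinely open and are fixed as follows:

* *The displacement is lateral.*  At van der Waals contact (∼3.4 Å) a 3-D
  centroid–centroid distance can never be below 0.71 Å, so the threshold
  is only meaningful in the plane: the peptide centroid is projected
  along the surface-ring normal onto the surface-ring plane and the
  in-plane distance to that ring's centroid is compared against 0.71 Å.
* *The "surface normal" on curved nanomaterials* is the normal of the
  nearest surface ring by centroid distance (of any size — pentagons
  participate in the distance and angle tests), which reduces to the
  sheet normal on graphene and generalises smoothly to C60 and the tube.
  Pentagons are never face-to-face partners: the displacement is always
  measured against the nearest *hexagonal* ring.

Boundary equalities follow the strict wording of the thresholds: a pose
*at* 4.5 Å or *at* 30° is still in contact/register, and a displacement of
exactly 0.71 Å is offset, not face-to-face.

With two aromatic rings (Tyr and Phe in the 11-mer) the unordered pair of
states collapses onto six arrangement categories — (1) none/none,
(2) offset/none, (3) offset/offset, (4) face-to-face/none,
(5) face-to-face/offset, (6) face-to-face/face-to-face — and
`occupancy()` reports per-category percentages plus the three main groups
(category 1 | categories 2–5 | category 6) used in occupancy tables.

## Contact statistics

* `contact_stability()` counts, per residue, the percentage of frames in
  which *any* residue atom is strictly within 4 Å of *any* surface atom
  (the van der Waals contact criterion; strict inequality by the literal
  reading of "less than 4 Å").
* `buried_contact_area()` defines the peptide–nanomaterial contact area as
  buried solvent-accessible surface area,
  $(\mathrm{SASA}_P + \mathrm{SASA}_N - \mathrm{SASA}_{P+N})/2$, because
  the "contact area" of adsorption figures is otherwise underdetermined.
  SASA uses deterministic Shrake–Rupley sampling on a Fibonacci sphere
  lattice (960 points/atom by default; doubling the density changes
  results by under 1%) with Bondi radii (C 1.70, N 1.55, O 1.52, S 1.80,
  H 1.20 Å) and a 1.4 Å probe.
* `rdf()` normalises A–B minimum-image distance histograms by the
  ideal-gas shell count at the B-group density, so uncorrelated groups
  give $g(r) = 1$; the range is capped at half the smallest cell length.
* `rmsf()` superposes every frame onto the first (Kabsch), then reports
  per residue the square root of the atom-averaged mean squared deviation
  from the time-averaged positions.

## Clustering

`kabsch_rmsd()` is the textbook SVD superposition with the
proper-rotation determinant correction.  `single_linkage_cluster()` forms
the connected components of the graph linking frames with RMSD strictly
below 2 Å, orders clusters by size (ties by first frame index), and
returns as representatives the *medoids* — the frame minimising summed
RMSD within its cluster, ties to the lowest index — of the up to three
largest clusters.  Medoids realise "the most frequently sampled
structure"; taking the three largest clusters (rather than three draws
from one) covers distinct basins, and in the pipeline the clustering is
run separately within each stacking category.

## Umbrella sampling and WHAM

The reaction coordinate is the distance between the mass-weighted
nanomaterial centre of mass and the glycine α-carbon near the middle of
the peptide.  Windows carry a harmonic bias with force constant
8000 kJ mol⁻¹ nm⁻² (converted internally to 19.12 kcal mol⁻¹ Å⁻², giving
a thermal width $\sigma = \sqrt{k_BT/k} = 0.177$ Å at 300 K) and 0.5 Å
spacing in production use.

`wham_solve()` iterates the standard self-consistency equations on bin
centres,
$$ p_b \propto \frac{\sum_i h_{ib}}{\sum_i N_i\, e^{-\beta (w_{ib} - g_i)}},
   \qquad e^{-\beta g_i} = \sum_b p_b\, e^{-\beta w_{ib}}, $$
until the largest change in any $g_i$ drops below 10⁻⁷ kcal/mol (at most
10⁵ iterations; the convergence flag is part of the result and
`dissociation_free_energy()` refuses unconverged profiles).  Defaults:
0.1 Å bins, 300 K.  The PMF is zeroed at its minimum — the associated
state — and the dissociation free energy ΔG is the mean over the final
2 Å of the sampled profile, a plateau rule standing in for "until fully
dissociated".  With a single unbiased window the equations degenerate to
direct Boltzmann inversion of the histogram, which the tests exploit.
Adjacent-window histogram overlaps are always computed
(`window_overlap()`); zero overlap warns and taints the profile.

### Validation design

The WHAM stack is validated on analytic potentials sampled by the
package's Metropolis generator, *not* on molecular systems: a flat
potential (unbiasing must return a constant), a harmonic well (curvature
recovery) and Morse-like wells of depth 1, 5 and 10 kcal/mol
(dissociation ΔG recovery, monotone in depth).  Three design choices
matter and were fixed a priori:

* **Decorrelation.**  The Metropolis proposal step is auto-tuned to
  30–60% acceptance and only every 10th state is recorded, so the 5000
  samples per window used throughout the validations are approximately
  independent (lag-1 autocorrelation ≈ 0).
* **Window spacing in validations.**  At $k$ = 8000 kJ mol⁻¹ nm⁻² the
  ideal biased distribution is only 0.177 Å wide, so 0.5 Å spacing leaves
  ∼16% adjacent-histogram overlap — below the ≥30% adequacy level that
  overlap monitoring is meant to enforce, and the window-matching noise
  then dominates flatness/depth errors.  Validation runs therefore space
  windows 0.35 Å apart (overlap ≈ 32%); the 0.5 Å production spacing is
  kept as the default and for the curvature check, which is insensitive
  to it.
* **Problem sizes.**  Validations use 9–21 windows × 5000 samples, 0.1 Å
  bins; these recover the flat profile within 0.15 kcal/mol, curvature
  within a few percent and well depths within 10% across seeds.

Reproducing *molecular* ΔG values (of order 1–15 kcal/mol for this
peptide on C60 → graphene) requires nanosecond-scale sampling of the real
solvated system and is explicitly out of scope; parameter recovery on
analytic potentials is the automated substitute.

## The synthetic-data generator

`build_peptide_model()` produces an all-atom, extended-backbone peptide
from sequence.  Its *contract* is compositional: per-residue all-atom
content with ionised Asp/Glu and protonated Lys/Arg, zwitterionic termini
(NH₃⁺, COO⁻), the formal charge, residue labelling, and exact regular
phenyl hexagons (C–C 1.39 Å) for Tyr/Phe.  For MSTYTGIFTDQ this gives 169
atoms and charge −1 (hence a single neutralising Na⁺ in the simulated
system); the 169 count is only consistent with an *all-atom* zwitterionic
composition, which is why the generator is all-atom even though
united-atom force fields are common for such systems.  The remaining
side-chain geometry is an idealised deterministic placement with no
physical meaning.

`place_ring()` poses a phenyl hexagon over a chosen surface hexagon at a
given height, lateral shift and tilt, and returns the stacking label the
parameters *force*.  The pose validator only accepts parameter regions
with safety margins (e.g. face-to-face requires shift ≤ 0.55 Å versus the
0.71 Å threshold; out-of-contact requires height ≥ 5.5 Å versus 4.5 Å),
sized so that the 0.05 Å Gaussian jitter added by
`synth_adsorption_trajectory()` cannot flip a label.  This makes the
generator an independent ground-truth oracle for the classifier: the
labels come from the construction, not from running the classifier.

`sample_biased_windows()` and `synth_hydration_shell()` provide the WHAM
and RDF ground truths described above.  All generators draw from a single
explicit seed and are bit-reproducible.

**What passing tests do and do not show.**  The synthetic trajectories
are rigid ring poses with jitter: no force field, no solvent, no peptide
dynamics, no thermal ring deformation.  Green tests therefore validate
the *analysis code* — geometry, classification logic, statistics,
estimators — under controlled truth, not the physical realism of any MD
observable.  Real trajectories add noise sources (ring flexibility,
surface restraint drift, finite sampling) that the thresholds are
designed to absorb but that these tests do not exercise.

## Known limitations

* Only armchair $(n,n)$ tubes; no chiral/zigzag tubes, defects or
  multi-wall structures; the nanomaterial is treated as rigid.
* No T-shaped/edge-on aromatic classes and no peptide–peptide stacking;
  the six categories only cover ring–surface arrangements.
* The buried-SASA contact area is one of several defensible definitions
  of "contact area"; outputs are labelled as buried SASA.
* WHAM provides no bootstrap error bars; the convergence and overlap
  diagnostics are the only built-in quality signals.
* The GRO reader handles single-frame orthorhombic files only.
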