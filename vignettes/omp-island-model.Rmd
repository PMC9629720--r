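---
title: "Modelling supramolecular OMP islands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling supramolecular OMP islands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The outer membrane (OM) of *E. coli* is an asymmetric bilayer:
lipopolysaccharide (LPS) in the outer leaflet, phospholipids (PLs) in the
inner leaflet, densely packed with beta-barrel outer-membrane proteins
(OMPs). Imaging and cross-linking evidence supports a picture in which the
abundant trimeric porins (OmpF/OmpC) form imperfect hexagonal networks —
centroid spacings of roughly 80–90 &Aring;, with small triangular
arrangements whose internal angles cluster near 60&deg; — and in which
low-abundance OMPs (TonB-dependent transporters, LptD, BamA) sit inside
these networks, held by shared annular lipids rather than by direct
protein–protein contacts. An LPS molecule whose headgroup region sits in
the first lipid shell of two barrels at once ("an OMP–LPS–OMP bridge")
glues the pair together; summed over a whole cell, these bridges are a
plausible source of the OM's rigidity and of the absence of long-range OMP
diffusion.

`ompisland` builds this picture as an explicit 2D object — a 150 nm ×
150 nm membrane patch, the *island* — and derives its testable numbers:

1. **Scaffold** (`build_scaffold`). OmpF-trimer centroids are placed on the
   edge midpoints of a triangular lattice (a kagome-type arrangement), so
   corner-sharing triangles enclose hexagonal rings. The packaged reference
   layout has 102 scaffold sites forming 18 complete hexagons; every
   nearest-neighbour distance is exactly the lattice spacing (default
   8.5 nm) and every triangle angle is exactly 60&deg;. A `kagome-patch`
   layout generates rings ab initio for any hexagon count, and `jitter_sd`
   produces the "imperfect" arrays seen on live cells.
2. **Guests** (`place_guests`). With the OmpF fraction fixed at 47% of 218
   OMPs, the 116 remaining OMPs are split equally (round-robin, so counts
   differ by at most one) over BtuB, FhuE, FhuA, FepA and the BAM and LptDE
   complexes, occupying hexagon centres first and then interstitial
   positions, never closer than 8 nm to any other centroid.
3. **Lipids** (`populate_lipids`). Each OMP receives an annular first shell
   of rough LPS placed at equal angles on the circle of radius
   *r* + *d*/2 (footprint radius plus half an LPS footprint). The
   closed-form ring capacity `annular_shell_count(r, d)` =
   &lfloor;2&pi;(r + d/2)/d&rfloor; gives 18 LPS around an OmpF trimer
   (r = 3.5 nm) and 13 around a TBDT barrel (r = 2.25 nm) at the default
   d = 1.43 nm. The outer leaflet is then filled to exactly 8093 LPS and
   the inner leaflet to exactly 25,099 PLs at 90/5/5
   POPE/POPG/cardiolipin (largest-remainder rounding).
4. **Contacts** (`first_shell_assignment`, `count_bridges`,
   `extrapolate_cell`). First-shell membership is recomputed from
   coordinates: a lipid belongs to an OMP's shell iff its centre lies
   within *r* + `shell_margin` of the centroid (default margin: one LPS
   diameter). Every outer-leaflet LPS with two or more memberships counts
   one contact per bridged pair. The patch count divides by an OM area
   fraction to give a whole-cell figure.
5. **Mass** (`mass_summary`). Mature-sequence masses per species; the BAM
   and LptDE lipoprotein partners ride along with their barrel's species
   but are excluded from the "OMP" numerator of the protein fraction;
   3 Ca²⁺ per LPS neutralise the LPS charges and count toward total mass
   only. The default island computes to ≈ 74.6 MDa with ≈ 27.5%
   contributed by barrels (both quantities are recomputed, not stored).
6. **Dynamics** (`simulate_membrane`, `dual_cutoff_contacts`,
   `occupancy_stats`, `lattice_order`). A statistical stand-in for
   coarse-grained MD (see below).
7. **Imaging** (`render_cells`, `bandpass_filter`, `find_maxima`,
   `normalize_cell`, `blink_calibration`, `estimate_copies`). Synthetic
   fluorescence/AFM-like rasters with ground truth, and the quantification
   pipeline that runs on them.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `patch_size` | 150 | nm | island side length |
| `lattice_spacing` | 8.5 | nm | OmpF centroid spacing; constrained to [8, 9] |
| `ompf_fraction` | 0.47 | — | scaffold share of `total_omps` (218) |
| LPS footprint `d` | 1.43 | nm | shell geometry; ≈1.6 nm² cross-section of rough LPS |
| OMP radii | 3.5 / 2.25 / 3.0 / 2.4 | nm | OmpF trimer / TBDT / BAM / LptDE footprints |
| `shell_margin` | 1.43 | nm | first-shell membership margin (one lipid ring) |
| `soi_area_fraction` | 0.0006 | — | patch share of a ~6 µm² cell used for extrapolation |
| dual cutoffs | 0.475 / 0.8 | nm | contact opens below / closes above |
| `prominence` | 20 | intensity | maxima threshold |
| bandpass | 1–20 (or 1–50) | px | difference-of-Gaussians band |

The OMP footprint radii are tunable estimates; they were fixed once so that
the ring-capacity formula reproduces the canonical 18/13 shell counts, and
all downstream numbers inherit them.

## Bridge counts: what the constructive model gives

With one placed ring per OMP and the membership rule above, the default
island yields roughly 500–600 OMP–LPS–OMP contacts (e.g. 566 at pipeline
seed 1; the exact value varies by a few percent with the seeded ring
phases). This is a factor ~2.5 below whole-shell estimates of ~1400
contacts for a patch of this size, and the extrapolated whole-cell figure
at a 0.06% area fraction (≈ 9.4 × 10⁵) falls just short of the 10⁶
mark. The shortfall is structural, not numerical: a constructive model has
exactly one ring of LPS centres at radius *r* + *d*/2, so a lipid can only
bridge a neighbour whose membership disc reaches that circle. At 8.5 nm
spacing that admits ~3 bridging lipids per adjacent OmpF pair and excludes
small guests entirely, whereas molecular-dynamics first shells are diffuse
(lipids wander radially and azimuthally), which roughly doubles to triples
the bridging population. The count is strongly sensitive to
`shell_margin`: doubling the margin to two lipid diameters brings small
guests into range and roughly triples the count. We deliberately keep the
one-lipid-ring default and report the honest constructive number rather
than widening the margin to meet an external figure.

Two further conventions matter here. First, ring positions of neighbouring
OMPs that land within half a lipid footprint (*d*/2) of each other are
merged into a single lipid tagged with all owners — these are the shared
interfacial lipids, and merging them is what conserves the LPS total and
makes bridges countable once each. Second, the whole-cell extrapolation
exposes both the conventional 0.06% area fraction and the geometric value
`patch_area / cell_area` (0.375% for 150 nm² of a 6 µm² cell); the two
differ by ~6×, and the report carries both.

## Dynamics: an emulation, and which part is faithful

Microsecond coarse-grained MD of a 33,000-lipid island is not a desk-scale
computation. `simulate_membrane` replaces it with overdamped Brownian
motion: per-species diffusion coefficients (defaults: PLs 0.05 nm²/ns —
a fluid-phase lipid at ~5 µm²/s — free LPS 0.005, OMPs 0.01 when
mobile), annular-shell LPS tethered to their ring anchor in the asymmetric
membrane (non-accumulating Gaussian fluctuation with the per-frame
Brownian step of the species, so a frozen species shows exactly zero
displacement), everything mobile and PL-like in the symmetric membrane,
periodic wrapping, and hard reflection of lipids off OMP footprints so a
diffusing PL samples the annular contact zone but never the protein
interior.

The faithful re-implementation is the *statistic*, not the force field:
`dual_cutoff_intervals` opens a contact at the first frame below 0.475 nm
and closes it at the first frame above 0.8 nm, with the grey zone
prolonging but never opening a contact — the standard double-threshold
that suppresses boundary flicker in residence-time estimates. Distances
are surface-to-surface: centroid separation minus the OMP footprint radius
minus the lipid footprint radius. (Measured centre-to-edge instead, a
placed ring lipid would sit 0.715 nm "away" from a protein it is touching
and could never register a contact; the surface convention reduces to
centre-to-edge for a point lipid and matches how minimum atom-pair cutoffs
behave in particle simulations.)

Under the defaults the qualitative contrast of the asymmetric OM is
reproduced rather than its printed MD values: tethered shell LPS occupy
their OMP contact for ≥ 95% of frames in every seed tested, free PLs far
less (the exact PL figure depends on OMP density — in the crowded test
islands it is tens of percent, in sparse patches a few percent), and the
hexatic order of the OMP pattern survives in the asymmetric membrane while
it decays in the symmetric one for the same seeds. Occupancy is reported
per species, optionally split by tether class, because bulk LPS far from
the lattice legitimately dilutes the species mean.

For the order metric we use the *global* bond-orientational parameter
&vert;&lang;&psi;₆&rang;&vert; = &vert;mean over OMPs of mean over six
nearest neighbours of exp(6i&theta;)&vert;: it is exactly 1 on a perfect
triangular lattice (computed with minimum-image neighbours on a
commensurate box) and ~0.05 on uniform random points. The per-point-modulus
variant (mean of &vert;&psi;₆,ᵢ&vert;) has a ~0.36 floor on random
patterns — the modulus of six random unit phasors does not vanish — which
makes it useless as an order/disorder discriminant; we therefore use the
global form throughout.

## Imaging: generators and quantification

`synth_cell_field` produces capsule cells carrying clusters ("islands") of
20–30 point emitters; `synth_pore_lattice` produces a triangular pore
lattice at 8.5 nm spacing under a broad curvature dome. `render_cells`
sums Gaussian point-spread functions (emitter intensity = integrated
counts, so an island of N emitters adds N·F to its ROI sum), adds scalar
or matrix background, and applies seeded Poisson/Gaussian noise. What the
generators do *not* emulate: detector pixelation artefacts, drift, uneven
illumination, AFM tip convolution and phase/height contrast differences —
so passing benchmarks here demonstrates the correctness of the
quantification machinery, not its performance on raw instrument data.

`find_maxima` reimplements prominence-thresholded maxima detection
(the "prevalence" setting of the usual find-maxima tools) as topographic
prominence with 8-connectivity: pixels are processed from high to low and
merged union-find style; when a component is absorbed by a higher-peaked
one, its prominence is its peak height above the merge (saddle) level.
Plateau ties break by scan order; the surviving global maximum takes its
prominence relative to the image minimum, which also makes a constant
image yield no maxima. The test suite checks the implementation against an
independent flood-fill oracle (binary search over threshold levels) on
smooth random images.

The bandpass filter is a difference of Gaussians with &sigma; = band/2 px
at each end — a deliberate approximation to FFT bandpass tools, which are
specified by pixel bands rather than a transfer function; it is exactly
zero-mean on constants and linear. On noiseless pore lattices under a
100 px dome, bandpass (1–20 px) followed by maxima detection achieves
recall and precision ≥ 95%, and the detected pattern's nearest-neighbour
distance mode recovers the generating spacing within one 1-nm bin.

Copy-number estimation follows the photobleaching convention: copies =
(I&#7522; − B&#7522;)/F&#7522;, with the single-fluorophore intensity
F&#7522; and off-level B&#7522; calibrated from the blinking tail of the
trace by Otsu two-level thresholding (means of the on and off classes).
The trace generator models tail blinks as non-overlapping single-molecule
events; coincident two-molecule blinks would bias the on-level upward,
and in long sparse acquisitions isolated blinks are what is observed.
With 5% multiplicative noise, recovery is within ±2 copies for well over
90% of islands at 20–30 copies; on noiseless traces the estimator is
unbiased.

## Numerical choices and degenerate inputs

- **Seeding.** Every stochastic stage derives its own 31-bit seed from the
  top-level seed and a stage label (`derive_seed`), so stages rerun
  independently and full runs are byte-identical. RNG state is always
  restored afterwards.
- **Leaflet filling.** Bulk lipids go on hexagonal grids whose spacing is
  solved adaptively (shrink by 3% until the target count fits), with
  seeded jitter bounded so grid positions cannot collide; a spacing that
  would fall below one lipid diameter raises a capacity error instead of
  overlapping.
- **Shell dedup.** The d/2 merge tolerance is a half footprint: closer
  ring positions are physically the same lipid. Merging is greedy in
  placement order with a cell-hash, hence deterministic.
- **Intervals.** Contact intervals are half-open `[start, end)` in 0-based
  frames; an open contact at the end of a trajectory runs to the final
  frame. Concatenating series whose boundary is closed concatenates the
  interval sets.
- **Degenerate inputs.** Empty config files give the full default island;
  a patch too small for the requested hexagons, guests that outnumber
  slots, shell demand exceeding the LPS pool, non-positive prominence, and
  `on >= off` cutoffs all raise early, named errors. A model with zero
  OMPs has an OMP mass fraction of 0 by convention.

## Problem sizes used in the test suite

The suite exercises the full default island (218 OMPs, 33,192 lipids)
through the pipeline, but runs dynamics on a 7-hexagon kagome island
(~64 OMPs, ~2,700 lipids, 100–150 frames, subsampled to ≤ 120 lipid
trajectories), oracle comparisons on 10⁴-frame distance series and
64 × 64 px images, and detection benchmarks on 200 × 200 px lattices —
sizes chosen so the whole suite completes in well under a minute per file
on one CPU while every statistical assertion retains comfortable margins.

## Known limitations

- The island is a 2D footprint abstraction: no conformational detail, no
  O-antigen, no electrostatics, no explicit divalent-cation bridging
  (Ca²⁺ enters mass accounting only).
- Placement is constructive, not packed or energy-minimised; bridge counts
  therefore represent a single-ring lower bound (see above).
- The Brownian emulation has no lipid–lipid excluded volume and no
  hydrodynamics; occupancy magnitudes are density-dependent, and only the
  asymmetric/symmetric *contrast* should be interpreted.
- Cell outlines for normalisation come from ground truth; no segmentation
  is included.
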