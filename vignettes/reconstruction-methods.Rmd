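---
title: "Left-heart surface reconstruction from sparse CMR contours: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-heart surface reconstruction from sparse CMR contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lheart)
```

This vignette explains the science inside `lheart`: the model each stage
implements, the assumptions it rests on, the tunable parameters and their
defaults, the numerical choices, what the synthetic phantom does and does
not emulate, and the limitations we know about. Code chunks are
illustrative and not evaluated at build time.

## The reconstruction problem

A cine CMR study samples the heart on a parallel short-axis (SAX) stack
(8 mm inter-slice spacing, no gap, ~1.4 mm in-plane resolution) and three
long-axis (LAX) planes roughly orthogonal to it. Endocardial contours are
drawn on each slice: on SAX slices through the ventricle a single LV
contour; higher up, where left atrium and aorta are visibly separate, two
disconnected LA and AO contours; at the ventricular in/outflow junction,
where the structures cannot be separated, one merged contour. The task is
to recover a single watertight endocardial surface of LV + LA + AO from
these sparse, mutually misaligned curves.

Two features make this hard. First, anisotropy: points are dense within a
slice (a few mm apart) but slices are 8 mm apart, and the whole junction
region is represented only by merged contours with no cross-slice point
correspondence. Second, misalignment: each slice is acquired in its own
breath hold, so every plane carries an unknown rigid offset of a few mm.

## Rigid registration of the long-axis clouds

Each LAX cloud is registered to the SAX cloud, which is always the fixed
reference. Plain ICP fails here because the two clouds overlap only along
thin curves; most points in either cloud have no counterpart in the
other. The mutual-subset filter removes, iteratively until stable, every
point farther than ε from the current subset of the other cloud. The
surviving subsets have three provable properties: their Hausdorff
distance is at most ε; if ε exceeds the Hausdorff distance of the inputs
nothing is removed; and the subsets grow monotonically with ε. All three
are exercised in the test suite on random clouds against a naive
re-scan-until-stable oracle.

ε is tied to the data scale as ε = α·d_H(C_sax, C_lax). The default
**α = 0.35** is the midpoint of the plausible 0.2–0.5 band; adaptive
selection of α is an open problem, so it stays a configuration knob
(`registration.alpha`). ICP then runs point-to-point with a closed-form
orthogonal-Procrustes (Kabsch) update, identity initialisation (all
planes already share the patient coordinate system and breath-hold motion
is small), a reflection guard on the SVD, convergence when the RMS
nearest-neighbour distance changes by less than `1e-6` mm, and a 100
iteration cap. No trimming is applied inside ICP — the mutual-subset
pre-filter plays that role.

Two behaviours of this design are worth stating plainly, because tests
encode them. With exact one-to-one correspondences the first Procrustes
step is exact, and the test suite verifies recovery of known transforms
to `1e-6`. On sampled data, however, a continuous LAX curve matched
against discrete SAX rings 8 mm apart can lower its RMS by sliding
tangentially along the surface: registering an already-aligned phantom
cloud therefore yields not the identity but a drift of a few degrees/mm,
while the cloud stays on the endocardial surface (mean implicit-surface
error well under 1 mm). For the same reason the subset *Hausdorff*
distance — pinned near ε before registration by the filter itself — is
not a quantity registration can reduce; the mean (RMS) subset distance
is, and reliably does. The tangential component of breath-hold motion is
in general unrecoverable from curve-on-surface data; it is also harmless
for surface reconstruction, which only needs the points back on the
surface.

## Contour densification

Each single-structure SAX group (LV, LA, AO) is processed as:
re-orientation, intra-contour resampling, matching, inter-contour
interpolation.

* **Orientation**: contours are made counter-clockwise (positive shoelace
  area) about the SAX stack normal, taken apex-to-base. This fixes a
  consistent traversal before matching; reversed orientations are not
  searched during matching.
* **Resampling**: a periodic PCHIP curve through the delineated vertices,
  parameterised by cumulative chord length, sampled at N uniform
  parameter values. Standard PCHIP is not periodic; the knot sequence is
  wrap-padded with three vertices on each side and only the central
  period is sampled, which is C¹ across the seam in practice. PCHIP is
  chosen over C² splines because endocardial sections are near-circular
  and shape preservation matters more than the extra smoothness, which
  does not measurably change the result. The accuracy is knot-limited: at
  12 knots on a 30 mm circle the maximum radial deviation of the PCHIP
  curve is 0.24 mm (0.8%); at the package's delineation density (~4 mm
  spacing) it is well under 0.5%.
* **Matching**: neighbouring contours are aligned by the circular shift
  minimising the mean point-wise distance, searched exhaustively over all
  N shifts (ties take the smallest shift). Matching is sequential up the
  stack — each contour to its immediate lower neighbour — which is the
  only scheme that makes the resulting columns coherent correspondence
  tracks across all levels.
* **Inter-contour interpolation**: each column track is interpolated
  coordinate-wise by PCHIP against the *physical slice position* (not the
  slice index, so missing slices cost accuracy but not correctness) and
  evaluated at M uniform levels spanning the group's range. No
  extrapolation ever occurs.

Defaults: **N = 48** points per contour, and **M** chosen per group so the
inter-level spacing matches the intra-contour point spacing, giving an
approximately isotropic point density matched to the tetrahedral mesh
scale (both overridable via `interp.N` / `interp.M`). On analytic
cylinder and cone stacks at 8 mm spacing the densified points stay within
1% relative radial error of the true surface.

The merged bifurcation contours are **never interpolated**: across the
junction there is no meaningful point correspondence, and any
interpolation scheme would invent topology. Their points still join the
final cloud, so the junction walls shape the surface through the distance
weight, and their polygon interiors seed the graph cut (below).

## Variational surface reconstruction

The combined cloud `C` (densified SAX groups, registered LAX points,
merged contour points) is embedded in a Delaunay tetrahedralization of
`C` plus an auxiliary lattice: spacing **h** (default: the median spacing
of consecutive delineated contour points), anchored at absolute multiples
of h (so nearly identical clouds see identical auxiliary points), covering
the cloud's bounding box expanded by 10% per side, with lattice points
closer than h/2 to the cloud removed. The Delaunay core is an incremental
Bowyer–Watson implementation with an internal deterministic jitter
(`1e-9` of the bounding-box diagonal) applied to predicate inputs only:
contour slices are exactly coplanar and resampled rings exactly
co-spherical, and the jitter puts these degenerate configurations into
general position without altering the reported vertex coordinates. Flat
sliver tets over coplanar slice points carry essentially zero volume but
are kept — dropping them would puncture the combinatorial structure.

A surface is sought that minimises the distance-weighted area
`E(S) = ∫_S d(x, C) dA`, discretised per mesh face as
`Area(face) · d(centroid(face), C)` — the natural piecewise-constant
quadrature. Any interior/exterior labelling of the tets defines a
candidate surface (the interface), and the minimiser subject to boundary
seeds is found exactly as a minimum s–t cut of the face-adjacency graph
with face weights as capacities. The test suite verifies exactness
against exhaustive enumeration on meshes of up to 15 tets, 100/100.

**Seeding.** Sinks are all tets touching the convex hull. Sources are the
blood-pool core: every tet whose centroid lies, at its slice level,
inside the per-level contour polygon shrunk by a factor 0.85 about its
centroid — endocardial sections are star-shaped about their centroid in
practice, so the shrunken interior is guaranteed blood pool (the
per-level centroids themselves are located in the mesh and must not fall
in hull tets; violation raises a seed-conflict error). Merged bifurcation
polygons seed the same way. Volumetric seeding is essential, not
cosmetic: with only isolated seed points, the energy's global minimum is
a set of small bubbles wrapped around the seeds (measured cost ~17·10³
versus ~35·10³ for the anatomical surface on the default phantom) because
a weighted minimal surface always prefers to collapse onto a finite seed
set. Seeding the measured cross-sections removes exactly the collapsed
configurations from the feasible set while constraining nothing that is
not certainly interior. Without the merged-contour seeds the same
collapse recurs regionally: the junction, which has no interpolated
levels, gets capped off and the reconstruction splits into three
components.

Degenerate (zero-weight) ties in the max-flow are broken by the fixed
node ordering (tet index), so runs are reproducible. The extracted
interface is oriented by combinatorial propagation with the global sign
set by majority vote of per-face outward tests (individual tests are
unreliable exactly on flat sliver faces), and non-manifold edge junctions
are repaired by relabelling the cheapest incident tet. The enclosed
volume of the extracted surface equals the summed interior tet volumes to
1e-9 relative — an exact bookkeeping identity that the tests assert.

## Post-processing

Smoothing uses the Taubin λ|μ band-pass scheme (λ = 0.5, μ = −0.53, 10
iterations): unlike plain Laplacian smoothing it does not shrink, and the
enclosed volume changes by under 2% at the defaults — important for the
thin aortic section. Remeshing is isotropic (edge split / collapse with a
link-condition guard / valence-improving flips / tangential relaxation,
vertices re-projected onto the input surface each pass; 5 passes; target
edge default = h). Both preserve the Euler characteristic (2 for the
expected genus-0 surface). The cited low-shrink smoothing and incremental
remeshing literature gives no parameter values, so all values here are
package defaults tuned on the phantom, exposed under `post.*`.

## Validation

The reconstructed surface is cut by each long-axis plane; triangle-plane
crossings are chained into closed polygons through shared mesh edges
(watertight input guarantees closure; open chains raise an error).
Sections are compared with the union of the reference chamber regions on
that plane: Hausdorff distance between boundary curves resampled at
0.5 mm arc steps, and Dice/Jaccard overlaps computed by exact polygon
clipping (ear-clipping triangulation + convex triangle-triangle
intersection) rather than rasterisation — deterministic and
resolution-free; a 0.25 mm rasterisation survives only as a Monte-Carlo
cross-check oracle in the tests. The identity J = D/(2−D) holds to
machine precision on every record and cross-checks both formulas. The
in-plane 2D computation of H is equivalent to 3D for coplanar curves.
D ≥ 0.7 is flagged as adequate overlap; the default phantom reconstructs
at D ≈ 0.99 per long-axis plane. Short-axis sections agree with their
reference contours even more closely than long-axis ones (the surface
interpolates the SAX data), which is why validation uses the long-axis
planes — they are the critical, held-out-in-spirit direction.

## The phantom: what it emulates, and what not

The phantom is an implicit solid: an LV ellipsoid (default semi-axes
26 × 23 × 45 mm), an LA ellipsoid (17 × 15 × 22 mm) behind/above the
base, and an aortic tube (radius 10 mm) along a circular arc rising from
the outflow region, blended by a log-sum-exp smooth minimum with a 5 mm
blend scale. The blend makes junction slices genuinely merge into one
contour, so the generated studies exhibit all three clinical delineation
cases (LV-only, separate LA+AO, merged). Slicing follows the acquisition
geometry: 8 mm SAX stack, three LAX planes orthogonal to it at 0°/60°/120°
about the long axis, 1.43 mm pixel spacing; contours are extracted as
zero-level iso-lines on the pixel grid and resampled to ~4 mm point
spacing to emulate manual delineation density. Per-plane breath-hold
misalignment is a seeded uniform rigid motion (≤ 5 mm, ≤ 5° by default)
of each LAX plane about its contour centroid; the SAX stack, as the
registration reference, stays fixed. Ground truth is available as the
analytic field, the marching-tetrahedra zero-level surface, and the exact
perturbation transforms.

Real data differ in ways the phantom does not model: papillary muscles
and trabeculae (excluded from the myocardium by delineation convention,
but adding contour irregularity), observer variability in the contours,
through-plane motion and phase mis-triggering, non-rigid deformation
between breath holds, and anatomies whose sections are not star-shaped
about their centroid (heavy trabeculation, aneurysm). Passing the phantom
tests therefore demonstrates the geometric machinery — projection,
filtering, ICP, interpolation, graph cut, metrics — under controlled
truth, not robustness to delineation noise or pathology.

## Problem sizes and registration effect size

Default reconstructions in the tests use the full study (~2100 cloud
points, ~100·10³ tets; ~30 s on one core). Repeated-reconstruction
experiments (the registration ablation) use N = 40, h = 5 mm without
remeshing (~40·10³ tets, ~10 s each), which leaves the validation scores
within ~0.003 Dice of the default configuration.

One empirical finding deserves emphasis. At breath-hold-scale
perturbations (≤ 5 mm / 5°), reconstructing with versus without
registration changes the mean long-axis Dice by only ~+0.001 on average
(10/20 seeds positive): the ~220 LAX points carry little weight against
~2000 densified SAX points, and the residual tangential ICP drift adds
its own noise, so the benefit sits below the noise floor of a 20-seed
sign test. At larger motion (12 mm / 10°) the benefit is systematic (7/8
seeds). This mirrors clinical experience that for subtle motion the
registration step's impact is not obvious, while large distortions
demand it — and is why registration is on by default but skippable
(`--skip-registration`).

## Known limitations

* The junction surface between the interpolated groups is shaped only by
  the merged contours, the LAX curves and the minimal-surface prior; its
  accuracy degrades first as slice spacing grows.
* Valve orifices are not modelled: the surface closes smoothly across the
  mitral and aortic planes, as the energy dictates, which is an anatomic
  simplification inherited from the contour data.
* Star-shapedness of sections about their centroid is assumed by the
  seeding rule; violations raise an explicit seed-conflict error rather
  than producing a silently wrong surface.
* Point-to-point ICP cannot observe tangential motion of curve-on-surface
  data (see above); reported transforms should be read as surface
  re-alignment, not full motion recovery.
* The auxiliary lattice bounds achievable detail at scale h; halving h
  roughly octuples the tet count, and the node cap (`recon.max_tets`,
  default 2·10⁶) guards against accidental resolution explosions.
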