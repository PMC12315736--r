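---
title: "Direct cytoarchitectonic segmentation of the cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct cytoarchitectonic segmentation of the cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoseg)
```

## The problem

Cortical gray matter is organized into areas and layers with distinct
cytoarchitecture. Conventional MRI-based parcellation warps an annotated
template onto a subject's structural scan; because structural contrast sees
only the shape of the cortical ribbon, the warped areal borders are accurate
mostly where cortical curvature provides landmarks. Ultra-high-resolution
diffusion MRI offers an alternative: scalar microstructural parameters
derived from the water-displacement propagator (anisotropy, non-Gaussianity,
zero-displacement probabilities) differ between cortical layers and areas,
so cortical voxels can be clustered *directly* on their microstructural
signatures, with no template and no spatial information.

`cytoseg` implements that pipeline: cortical reference frame (CRF)
estimation from tissue masks, orientation-adaptive denoising of the
diffusion-weighted volumes, scalar parameter maps, per-hemisphere Gaussian
mixture clustering with BIC model selection, 3D morphological label
refinement, and label harmonization across hemispheres. Every stage is
validated against a synthetic two-hemisphere cortical phantom with known
ground truth.

## Cortical reference frame

From disjoint gray-matter (GM) and white-matter (WM) masks the package
computes, per voxel:

* **depth** in [0, 1] — 0 at the GM/WM interface, 1 at the pial surface;
* **radial direction** — the unit vector perpendicular to the local cortical
  surface, pointing from WM to pia.

Equidistant depth is `d_wm / (d_wm + d_pial)` with voxel-size-aware
Euclidean distance transforms; a half-voxel offset places both boundaries on
the voxel faces. Because the voxel-center distance transform of a curved
boundary carries lattice bumpiness of a fraction of a voxel, the distance
fields are lightly smoothed (Gaussian, 1 voxel) before they are
differentiated; the radial field is the normalized gradient of the *signed*
difference of the two distance cones, which stays monotone through WM,
cortex, and background, so the gradient and its divergence remain well
defined right at the boundaries.

Equivolumetric depth corrects equidistant depth for curvature: a layer of
fixed thickness occupies more volume on the convex side of a fold. We model
a cortical column as a generalized frustum whose cross-sectional area
evolves along the column as `dA/ds = A div(r)` with `r` the radial unit
field. For each GM voxel the streamline of `r` through the voxel is traced
both ways (fixed 0.25-voxel step) until it crosses the WM-facing or
pial-facing boundary surface (the zero level of the *unsmoothed* face
distance fields, which are exact near the faces); the equivolume depth is
the fraction of the accumulated area-weighted column volume lying below the
voxel. On a flat slab the divergence vanishes and equivolume equals
equidistant depth; on a spherical shell with radii `a < b` the construction
reproduces the analytic solution `(r^3 - a^3) / (b^3 - a^3)`, which is the
package's testable contract for the step (the layering tests use an
`a = 12, b = 24` voxel shell, where six layers are 1.6-2.6 voxels thick;
on much thinner shells individual layers fall below one voxel and voxel
counts are no longer meaningful). Tracing the streamline *through each
voxel* (rather than seeding columns on the WM surface and resampling
voxels to the nearest column) avoids any nearest-column quantization and
gives every voxel a consistent column by construction.

Layer `k` of `n` collects voxels with depth in `[(k-1)/n, k/n)`, with depth
exactly 1 assigned to layer `n` (deterministic tie-break).

## Orientation-adaptive denoising

Each cortical voxel is replaced by a Gaussian-weighted sum of its
`5 x 5 x 5` neighborhood. The kernel is anisotropic and *rotationally
symmetric about the radial axis*: standard deviation 0.1 mm radially and
1.0 mm tangentially (defaults), so smoothing acts within the plane tangent
to the cortical surface — along layers, not across them. At 0.2 mm voxels
the 5-voxel support means at most 1 mm of tangential blurring. Weights are
sampled at voxel-center offsets and renormalized to sum to one, which makes
the filter exactly conservative on constant signals; at image borders only
in-grid neighbors contribute. Voxels without a defined frame pass through
unchanged, and by default out-of-cortex neighbors do contribute (an optional
`mask_restrict` confines the kernel to cortex, since either convention is
defensible).

Two quantitative contracts pin the implementation down. First, for iid
input noise the output variance per voxel is the input variance times the
kernel's sum of squared weights — verified by Monte Carlo. Second, an
orientation-discrimination test: on a slab with a layered depth profile, the
correctly oriented filter must leave the layer-mean profile essentially
unchanged while a sigma-swapped filter (radial and tangential roles
exchanged) must degrade it severely. Deviations are measured relative to the
profile's dynamic range. This fixture is sampled at 0.4 mm: at 0.2 mm the
one-voxel radial tap of a 0.1 mm Gaussian still carries weight
`exp(-2) = 0.135`, so *any* radial kernel mixes adjacent voxels across layer
boundaries and the two thresholds (< 2% correct, > 20% swapped) cannot be
separated cleanly on a piecewise-constant profile; coarser sampling makes
the radial taps negligible and isolates the orientation effect being tested.

## Scalar microstructural maps

The tensor fit solves `ln S = ln S0 - b g' D g` per voxel by ordinary least
squares followed by one reweighting pass with weights equal to the squared
predicted signal (the standard correction for log-transformed data).
Eigenvalues are clamped to `1e-7` mm^2/s. DTI scalars follow the usual
formulas (FA, MD, AD, RD).

The propagator-based parameters are computed in the **Gaussian (tensor)
limit**, where they have closed forms in the eigenvalues and the diffusion
time `tau = Delta - delta/3` (26 ms for the default 6/28 ms pulse timing):

* `RTPP = (4 pi tau l1)^(-1/2)` (mm^-1)
* `RTAP = (4 pi tau)^(-1) (l2 l3)^(-1/2)` (mm^-2)
* `RTOP = (4 pi tau)^(-3/2) (l1 l2 l3)^(-1/2)` (mm^-3), so
  `RTOP = RTAP * RTPP` identically
* `PA = sqrt(1 - cos^2 theta)` with
  `cos theta = 2^(3/2) (|D| |D_iso|)^(1/4) / |D + D_iso|^(1/2)`,
  `D_iso = MD * I` — the angular similarity between the propagator and its
  closest isotropic Gaussian, verified in the tests against brute-force grid
  integration of the two propagators.

A full series-expansion propagator fit is deliberately out of scope: the
package's contribution is the segmentation pipeline, and the Gaussian limit
preserves every downstream contract while remaining analytically
verifiable. Two consequences are handled explicitly: non-Gaussianity (NG) is
identically zero in this limit, so NG is never computed from DWIs — it
enters clustering only as a supplied map (simulated directly by the
phantom); and PA is reported without the literature's sigmoidal rescaling,
which is monotone and therefore irrelevant after feature z-scoring.

Accordingly the pipeline supports two parameter routes. The production
workflow this package models obtains its propagator maps from an external
fit, so in phantom runs the default (`param_route = "supplied"`) clusters
the phantom's calibrated parameter maps — the stand-in for that external
fit, and the only route on which the phantom's class-separation setting is
defined. The internal route (`param_route = "fitted"`: CRF-filtered DWIs,
tensor fit, Gaussian-limit maps) always runs too and can also feed the
clustering; its accuracy is pinned by its own contracts (noiseless
recovery, noise robustness of MD/FA). Clustering the fitted maps on the
default phantom is substantially harder than the calibrated setting —
within-class spread is then governed by tensor jitter and fit noise rather
than by the separation calibration, and systematic filter mixing at block
boundaries becomes visible — which is a realistic property of the route,
not a target of the fidelity contract.

## Clustering

Features (defaults: PA, NG, RTAP, RTPP) are z-scored per hemisphere — the
hemisphere is the clustering unit, so its feature matrix is normalized
self-contained — and carry no voxel coordinates. The Gaussian mixture with
full covariances is fit by batch EM: k-means++ seeding polished by a short
Lloyd pass, five restarts keeping the best log-likelihood, `1e-6` diagonal
covariance regularization, convergence when the relative log-likelihood
change drops below `1e-7` (500-iteration cap). Batch EM makes the result
independent of voxel order; components are reordered canonically
(lexicographically by mean vector) so hard labels are reproducible. Empty
components are re-seeded at the worst-explained points.

At this scale (k around 14, tens of thousands of voxels, closest classes a
few sigma apart) plain restarted EM has a characteristic failure mode: it
fuses one close component pair while splitting another component in two — a
genuine local optimum that further iterations never leave. The fit
therefore ends with a deterministic split-and-merge refinement: propose
merging the closest component pair (Mahalanobis distance under the pooled
covariance) while splitting the highest-spread component along its
principal axis, rerun EM, and keep the move only if the log-likelihood
improves (up to five rounds). On the default phantom this reliably moves
every initialization into the same optimum, whose hard assignment matches
the Bayes rule computed from the true generative parameters. The component count
is selected by `BIC = -2 logL + p log n` with
`p = (k-1) + k d + k d(d+1)/2`, searched over `k = 8..20` around the
operating point `k = 14`. The covariance structure, normalization,
initialization, and search range are design choices of this package; full
covariances are used because microstructural features are correlated.

## Morphological refinement

Spatially agnostic clustering can assign disjoint domains to one cluster.
Refinement (1) relabels every connected component (26-connectivity, which
avoids spurious splits of thin curved laminae) of every cluster as its own
label, then (2) iteratively merges the smallest component under 100 voxels
into the face-adjacent neighbor sharing the most voxel faces (6-face
counting approximates shared surface area; ties go to the lower label id;
sizes and adjacency are recomputed after every merge). Components exactly at
the threshold are retained — the threshold semantics "at least 100 voxels
survive" resolves the boundary case deterministically. At 0.2 mm resolution
100 voxels is 0.8 nL, about the smallest cytoarchitectonic domain one
expects to resolve. The refinement conserves the labeled voxel set, leaves
no sub-threshold component (isolated neighborless islands are kept and
logged), and is idempotent up to label renaming.

## Hemisphere harmonization

Cluster labels are arbitrary per hemisphere. Both hemispheres are
cross-tabulated against a *symmetric* reference — each atlas area split
into six equivolumetric layers, encoded `area * 100 + layer` — giving
contingency matrices `C_L`, `C_R` with identical, identically ordered
reference rows. The product `M = C_L' C_R` is then an affinity between left
and right cluster labels. One exact Kuhn-Munkres round (an exported
Jonker-Volgenant solver, brute-force-verified on all small problems)
maximizes total overlap one-to-one; remaining labels of the larger side are
attached greedily in decreasing size order, each to its best counterpart
(many-to-one), one per round — this realizes "match iteratively by
decreasing size" while guaranteeing every label ends up matched unless its
affinity row is all zero. Only label identities change; region geometry is
untouched.

## The synthetic phantom

The phantom emulates what the pipeline needs from real data and nothing
more: a two-hemisphere cortical ribbon (flat slab by default; spherical
shell and sinusoidally folded ribbon for curvature-sensitive tests) over a
WM slab, partitioned into 5 areas tangentially and 3 laminar classes by
depth. The 15 area-layer blocks share 14 distinct classes (one class
appears in two disjoint blocks, exercising the component split). The right
hemisphere is the exact mirror image of the left with class labels renamed
by a random permutation; a 3-voxel midline strip belongs to neither
hemisphere, so no labeled component can span hemispheres, while the tissue
itself is continuous across the midline (a lateral tissue gap would tilt
the radial field toward it).

Each class carries a diffusion-tensor signature — prolate and radially
oriented for the deep and deepest-third classes, oblate (tangential) for
the middle third, modulated by area — plus an NG level. The NG map carries
a 0.005 Gaussian standard deviation. An optional per-voxel multiplicative
eigenvalue jitter (`lambda_jitter`) is available but defaults to zero:
jitter propagates through the nonlinear scalar maps and curves the
within-class feature distributions, and a BIC-selected mixture then
*legitimately* buys extra components to fit that curvature — with tens of
thousands of voxels even a 1% jitter shifts the selected component count
above the generative class count. The default phantom therefore keeps the
within-class model exactly Gaussian (the calibrated feature noise below),
the regime in which BIC consistency is the meaningful, testable contract. Scalar signatures
are computed through the package's own closed forms, so the generator and
the analysis agree by construction. Diffusion-weighted signals follow the
monoexponential tensor model with Rician noise (magnitude of a
complex-Gaussian-perturbed signal) at a default b0 SNR of 30, typical of
long fixed-tissue acquisitions.

The key calibrated quantity is **class separation**: Gaussian feature noise
is added to the parameter maps with per-feature scale chosen (by root
finding) so that the minimum pairwise Mahalanobis distance between class
signatures — measured against the *total* within-class standard deviation,
jitter included — equals exactly 4. At that separation the closest class
pair overlaps by roughly the two-sided 2-sigma tail, so clustering is
challenging but solvable; this is the operating point for the
cluster-count-recovery and fidelity tests. The default grid gives 54,000
GM voxels per hemisphere.

What the phantom does *not* model: realistic gyral geometry from meshes,
partial-volume averaging at tissue interfaces, non-monoexponential
(kurtosis) signal decay, spatially correlated noise, and histology-scale
within-area gradients. Passing tests therefore demonstrate the pipeline's
correctness and its behavior under controlled separation and noise — not
performance on real tissue, where feature distributions are heavier-tailed
and boundaries are not crisp.

## Numerical choices and degenerate inputs

* All geometry is computed in mm from the voxel dimensions; label 0 is
  background everywhere; b-values at or below 50 s/mm^2 count as
  non-weighted (the default multi-shell scheme starts at b = 100, so signal
  normalization uses the lowest shell).
* Distance transforms are exact Euclidean (Felzenszwalb-Huttenlocher),
  voxel-size aware.
* Gradient directions are renormalized with a warning when off unit length;
  zero directions on weighted volumes are errors.
* Voxels with non-finite features are excluded from clustering with a
  logged count; constant feature maps are rejected outright.
* GM voxels unreachable from either boundary are excluded from the cortical
  frame; zero-gradient voxels are excluded from the radial field.
* The EM reports and re-seeds degenerate components; covariances that still
  fail Cholesky after regularization get a stronger ridge.
* Orphan components with no neighbor are kept, not deleted, and logged.

## Problem sizes

The validation suite runs the full pipeline on the default phantom
(54,000 GM voxels per hemisphere, 112 simulated DWI volumes) and the BIC
sweep over k = 8..20 on one hemisphere; smaller geometries of the same
layout (identical class structure, reduced extent) are used for the
stage-level unit tests, which keeps the whole suite at desk scale. These
sizes are the package's standard study conditions; scaling the phantom up
changes runtimes, not contracts.

## Known limitations

* The equivolume construction assumes the radial field is integrable into
  well-defined columns; in real data with topological defects in the masks
  (handles, holes) streamlines can terminate early, and those voxels fall
  back to the traced fraction rather than a column-complete value.
* The Gaussian-limit propagator metrics understate restriction effects at
  high b-value; rankings across tissue classes are preserved, absolute
  values are not comparable to a full propagator fit.
* Harmonization assumes the reference atlas is symmetric; with an
  asymmetric reference the contingency product is still computable but the
  optimality of the matching no longer implies anatomical correspondence.
* With more cluster labels than reference labels the greedy rounds are
  many-to-one by design; genuinely ambiguous labels (equal overlap with two
  references) resolve by the deterministic tie-break, not by anatomy.
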