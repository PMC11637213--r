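---
title: "Crown–pulp registration by pulp-horn mapping surfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crown–pulp registration by pulp-horn mapping surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the registration model and its assumptions, the preprocessing chain, the
parameters that matter, what the synthetic phantoms do and do not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The registration model

Two point clouds of the same tooth crown are to be aligned rigidly: the
intraoral-scan crown `Y` (free, dense, low noise) and the CBCT-derived
equivalent crown `C` (fixed, voxel-limited, noisy, with occasional
outlying points), with the CBCT pulp cloud rigidly attached to `C`. The
clinical quantity of interest is not the crown-surface residual but the
pose of the registered crown *relative to the pulp*.

The method rests on one anatomical observation: each pulp horn points at
its cusp. A horn's **feature direction** is the unit vector from the pulp
centroid to the horn apex. A crown CBCT point is a **mapping point** when
the angle between its outward surface normal and the closest horn
direction is at most `gamma_max`; these are the cusp-flank regions whose
geometry constrains the pulp pose. The registration loop is:

1. **Correspondence.** For every (transformed) free point, find its
   nearest fixed point. If that point lies in the `k_y`-neighbourhood of
   a mapping point, fit a local moving-least-squares quadric over its
   `k_c`-nearest neighbourhood, sample the quadric on a grid of spacing
   `d_s` over a tangent-plane disk of radius `r_s`, and take the nearest
   sample as the match (point-to-surface); otherwise match point-to-point.
   A sample is accepted only if it is no farther than the nearest point
   plus `d_s`, and an exact point match needs no patch.
2. **Robust gate.** Pairs farther than `trim_factor` (default 3) times
   the median matched distance are dropped — dropout holes and gross
   outliers otherwise drag the solve.
3. **Pose solve.** The remaining pairs enter a sparse lp solve
   (`p = 0.5`, penalty `mu = 10`) by ADMM: a proximal shrinkage of each
   residual, a closed-form weighted SVD (Procrustes) update against the
   shifted targets, and a multiplier ascent. Surface-matched pairs carry
   weight `surface_weight` (default 5): the mapped points and their
   neighbours get increased weight in the registration. Each of the
   `n2 = 2` solver blocks re-matches at the current intermediate pose
   (`ns = 3` inner passes per block).
4. **Convergence.** Outer iterations stop when the incremental motion
   falls below 0.005 degrees and 0.001 mm (or after `max_outer_iter`).
   A final refinement phase then polishes the pose on the
   surface-matched correspondences alone — the limiting case of the
   mapped-point weighting, driven purely by the feature regions.

The deviation presets bind the parameters: *small* initial deviations use
`gamma_max` 20 degrees and `r = r_s = 0.1`; *large* use 25 degrees and
0.3. Larger radii enlarge the matching range of each surface so that
free points can still find correct matches when the clouds start farther
apart.

### Solver normalisation

The proximal threshold of the lp shrinkage is scale-dependent: on raw
millimetre coordinates with `p = 0.5, mu = 10` it sits near 0.26 mm and
would classify the entire initial misalignment as "outliers", freezing
the solve. `admm_sparse_solve()` therefore normalises both clouds by the
target's circumscribed diameter before solving (the convention of
reference sparse-ICP implementations, whose published parameter values
presuppose it) and rescales the translation afterwards. The diameter is
rotation-invariant, so the solve commutes exactly with a common rigid
motion of both clouds. Multipliers are reset for each correspondence
set: persistent multipliers across correspondence updates were tested
and destabilise the loop.

### What the lp norm buys, and what it costs

With `p = 0.5` the objective's gradient vanishes for large residuals and
diverges for small ones: gross outliers are ignored, exact matches are
pinned. The flip side is a small capture basin — from a start several
degrees off, the point-point lp solve can freeze near its starting pose,
and plain least squares (classic ICP) then does better. This is visible
in the package's own baseline comparison and is consistent with
point-point sparse ICP scoring worst on crown–pulp orientation among the
four methods. PHMSR escapes the trap because its surface correspondences
and mapped-point weighting keep pulling along the informative feature
directions.

## 2. Accuracy metrics

`cloud_rmse()` implements the nearest-neighbour root-mean-square crown
residual, pairing each fixed CBCT point with its nearest registered scan
point (the printed pairing direction). `crown_pulp_deviation()` builds
PCA frames for the pulp, the truth-pose crown and the registered crown
(axes in descending variance order, signs canonicalised against the
global axes, third axis by cross product). CPPD is the norm of the
crown-centre displacement expressed in pulp-frame components; CPOD is
the norm of the differences of the ZYX-intrinsic Euler angles of each
crown frame taken relative to the pulp frame. The Euler convention is
not dictated by the metric's definition; ZYX-intrinsic was fixed for
determinism, and the invariance and symmetry properties (common-motion
invariance; swapping which pose is "truth") are enforced by tests.

## 3. CBCT preprocessing

**Hybrid filter.** Each axial slice is denoised by a multi-level Haar
wavelet soft shrinkage (universal threshold from the finest diagonal
band) followed by non-local means with patch radius 2, search-window
width 5 and bandwidth 10 — the published setting. The wavelet step and
the NL-means kernel are implemented in-package (no suitable R
implementations are available); output intensities are clamped to the
input range.

**Adaptive SCM.** Segmentation uses the spiking cortical model
recurrence

    U(n) = exp(-alpha_u) U(n-1) + S (1 + beta V_L (W * Y(n-1)))
    Y(n) = [ U(n) > E(n-1) ],   E(n) = exp(-alpha_e) E(n-1) + V_E Y(n)

with per-slice adaptive parameters `alpha_e = C / mu`, `V_E = 2 mu`,
`beta = a ln(mu)`, `alpha_u = log(1 / var(I))` (natural log) and
`E(0) = max(I)`. Pixels are labelled by the synchronised pulse they
first fire in. Two constants are "experimental" with no published
values; the package defaults are a deliberate choice:

* slices are unit-normalised before segmentation — on raw CT scales
  `var(I) >> 1` makes `alpha_u` strongly negative and the memory term
  divergent;
* `C = 0.01 * max(I)`: the threshold then decays a few percent per
  iteration, placing intensity classes 1.5x apart several firing pulses
  apart (40 iterations suffice; pixels whose threshold never falls to
  their intensity are background);
* `a = -0.02`: on unit-normalised slices `ln(mu) < 0`, so a small
  negative constant yields the weak *positive* neighbour coupling the
  model intends. Strong coupling (|beta| near 0.2) produces travelling
  autowaves that sweep one tissue class into the pulse of its brighter
  neighbour and must be avoided.

Pulse grouping is occupancy-aware: heavy firing bins separated by at
most one empty iteration form one pulse; sparse straggler bins (blurred
boundary pixels) join the nearest pulse but cannot bridge two pulses.
In 3-D, bright pulses gated by a hard-tissue threshold (0.45 of the
global intensity range) form connected components; the highest-mean
components are tooth, and the pulp is recovered *morphologically* as the
cavity enclosed by tooth — voxels unreachable from the volume border —
rather than by its own intensity, which in real CBCT is low and
unreliable. The cavity wall, blurred by filtering, is refined by
reassigning wall voxels to whichever class mean their intensity is
closer to.

**Surface extraction.** Isosurfaces of the binary masks are extracted by
marching tetrahedra (six-tetrahedron cube decomposition, vertices
interpolated at the 0.5 crossing and deduplicated) followed by uniform
Laplacian smoothing; every raw vertex lies on a tetrahedron edge of its
cell, i.e. within half a body diagonal (sqrt(3)/2 voxels) of the mask
boundary. Vertex normals average incident face normals and are oriented
away from the structure centroid.

## 4. MLS patch numerics

The quadric `z' = a0 + a1 x' + a2 y' + a3 x'^2 + a4 x' y' + a5 y'^2` is
fitted in a tangent frame from neighbourhood PCA with Gaussian weights
`exp(-(d/h)^2)`, `h = r/2`. Three safeguards make this robust on
voxel-limited clouds:

* the bandwidth is floored at the neighbourhood's median spacing, so the
  weighted normal equations keep enough effective support;
* a Tikhonov ridge (1e-7 of the trace) shrinks unsupported quadric terms
  toward the tangent plane instead of letting them blow up;
* a fitting radius below half the nearest-neighbour spacing resolves no
  surface at all: the patch degrades to point-point matching. This makes
  the stated small-radius degeneration exact — as `r`, `r_s`, `d_s` go to
  zero, matching returns the plain nearest neighbour.

The sampling span `d_s` defaults to `r/3`; the published guidance ties
it to the target cloud's average spacing and the accuracy requirement,
and it is exposed in `run_config()`.

## 5. The synthetic phantoms

`make_tooth_phantom()` builds a radially parameterised molar: a
rhomboidal crown (buccolingual width 0.85 of mesiodistal, occlusal
height 0.7 of the half-width) with `n_cusps` Gaussian cusps of unequal
height (amplitude jitter drawn per seed), occlusal developmental grooves
midway between cusps (depth 0.15 of the local radius, half-width about
0.6 mm — a fissure scale the 0.25 mm voxel grid can still resolve), and
a pulp at 0.45 scale with a conical horn under each cusp. The asymmetries
are not decoration: a crown close to a surface of revolution leaves the
azimuthal pose nearly unobservable, which no real molar does. Because
the phantom is a radial implicit surface, exact containment tests and
signed surface distances are available as oracles for every generator
property.

`make_scan_cloud()` samples the crown above the gingival-margin plane,
area-uniformly, with Gaussian noise along the normal (default 0.02 mm,
the intraoral scanner's accuracy class). `make_cbct_cloud()` emulates
the CBCT chain: voxelisation at 0.25 mm, marching-tetrahedra
re-extraction, Laplacian smoothing (10 iterations — the reconstruction
chain smooths before converting to points), residual isotropic noise of
0.02 mm (the voxelisation itself already models quantisation error, so a
larger iid term would double-count), outliers pushed 1–5 mm off-surface
along the normal (re-pushed if concave geometry leaves them nearer than
1 mm), and dropout in contiguous occlusal blotches. Pose perturbations
use presets of at most 5 degrees / 1 mm (small) and 25 degrees / 5 mm
(large).

What the phantoms do *not* emulate: metal artifacts, enamel/dentin
intensity structure within the crown, gingival soft tissue, carious
defects, and anatomical variation beyond cusp jitter. Passing the
phantom protocols therefore demonstrates the pipeline's correctness and
its relative robustness ordering, not clinical-grade accuracy on
pathological teeth.

## 6. Protocol sizes and tolerances

The test and acceptance protocols use scan density 20 points/mm^2
(about 2,800 crown points), equivalent-crown clouds of about 10,000
points, pulp clouds capped at 2,000 points, and 20 phantom seeds per
protocol; the four-method outlier comparison downsamples to
1,500/3,000/1,500 points so the Gaussian-mixture baseline (quadratic
cost) runs in the same harness. Registration stops at increments below
0.005 degrees / 0.001 mm with at most 150 outer iterations. These sizes
are the package's own choices for a desk-scale study; the method has no
intrinsic size limit.

## 7. Known limitations

* Pulp-horn extraction assumes the horns are the highest well-separated
  pulp points along the occlusal axis; heavily calcified or anatomically
  variant pulps may need the manual-override path
  (`pulp_horn_feature()` objects passed to
  `pulp_horn_feature_directions()`).
* The occlusal-axis estimate (mean outward normal of the cropped crown,
  PCA fallback for closed surfaces) presumes a crown-like open shell.
* Point-point sparse ICP inherits the lp small-capture-basin behaviour
  described above; it is provided as a faithful baseline, not as a
  recommended registration method.
* The minimal DICOM reader handles explicit-VR little-endian
  single-frame series only; NIfTI input goes through RNifti.
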