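---
title: "Geometric methods behind condylenav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric methods behind condylenav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

condylenav implements a marker-less navigation pipeline for femoral tunnel
placement in anterior cruciate ligament reconstruction (ACLR): a distal
femur model is reconstructed from CT, its lateral condyle is isolated by an
optimized sagittal cut, the capsular line reference (CLR) ridge is
extracted by curvature analysis, a Bernard-Hertel (BH) grid anchored on
Blumensaat's line yields the recommended footprint point, and the grid is
registered into arthroscopic-style frames and overlaid. This vignette
explains the models and the numerical choices; it states no result that the
package's tests and `scripts/acceptance.R` do not themselves compute.

## Surface reconstruction from CT

Bone is segmented by a global intensity threshold (user-supplied, Otsu by
default), refined by morphological closing with a ball element and
largest-component selection, and converted to a triangle mesh by marching
tetrahedra (six tetrahedra per cell, linear interpolation along cell
edges). Marching tetrahedra shares the marching-cubes contract - a
watertight surface with sub-voxel vertex placement - while avoiding the
256-case table.

One numerical choice matters here: iso-surfacing a *binary* mask produces a
terraced surface whose area overestimates smooth anatomy by roughly 8% on
a digitized sphere. `extract_surface()` therefore smooths the binary
indicator with a Gaussian (default sigma = 1 voxel, configurable) before
extracting the 0.5 level set. On the r = 10 mm sphere fixture this brings
the area error below 1% and keeps principal extents within 2 voxels, at
the cost of rounding genuinely sharp features at the sub-millimetre scale
(which is why a few recovery tolerances below are stated relative to the
smoothing support).

## The sagittal cutting plane

The initial sagittal plane contains the two intercondylar-notch landmarks
and the transverse-plane normal; its normal is oriented medially. The
orientation is then optimized so that parallel sections through both
condyles become as circular and concentric as possible: for each candidate
orientation the mesh is cut by a series of parallel planes, the articular
arc of each sectional contour is fitted with an ellipse, and two metrics
are pooled - the mean eccentricity and the focal dispersion (RMS distance
of all fitted foci from their common centroid, expressed in the shared
in-plane frame, which is equivalent to projecting the foci onto a common
plane parallel to the sections). When the cutting direction is
perpendicular to the epicondylar axis of an idealized condyle pair the
sections are circles and both terms vanish.

The two metrics are combined as

    objective = mean_eccentricity + lambda * focal_dispersion / span

with `lambda = 1` and `span` the mesh extent along the plane normal; the
normalization makes the dispersion term dimensionless and of comparable
magnitude to the eccentricity. The optimizer is a deterministic coordinate
descent over the two spherical angles of the plane normal with
step-halving: the four single-angle perturbations are scored, the best is
accepted only if it improves the objective (hence a monotone trace), and
the step is halved when none does. Randomized or multi-start search is
deliberately out of scope; determinism makes every run reproducible and
testable.

Sectional contours coming straight off an iso-surfaced mesh carry
sub-voxel jitter that overwhelms finite-difference curvature, so the
articular-arc selector first resamples each contour at uniform arc length
(200 points) and applies a circular moving average (window 7). Selection
then slides a window of 40% of the arc length, scores curvature variance,
anchors on the curvature prominence, and extends while the curvature stays
consistent with the window median (within max(5 MAD, 15%)). On a uniform
(circular) contour the whole contour is returned.

The ellipse fit itself is the direct constrained least-squares conic fit
(ellipse constraint B^2 - 4AC < 0 imposed through the partitioned
eigen-solve) on centered and scaled coordinates; it recovers noiseless
synthetic ellipses to 1e-6 and is invariant to translation, rotation and
scale of the input.

## Feature curves and the CLR

Per-vertex principal curvatures come from a quadric height field fitted in
the vertex tangent frame; the shape operator I^-1 II of the fitted patch
is eigen-decomposed for kappa1 >= kappa2 (convex positive), the Gaussian
curvature K = kappa1 kappa2, and the kappa1 direction. On clean parametric
meshes a one-ring fit reproduces analytic curvatures to about 0.1%; on
iso-surfaced binary volumes the one-ring estimator has errors of order
100% because the terracing noise dominates second derivatives at the
one-ring scale. The estimator therefore grows the neighbourhood
ring-by-ring until it covers a metric radius (default 2.5 mean edge
lengths; the CLR pipeline uses 1.5 mm at CT pitch), trading spatial
resolution for noise suppression.

Feature points are the vertices above a curvature threshold, given either
absolutely or as a percentile (default: the 90th). Two channels are
offered: the Gaussian curvature K (the classical ridge indicator) and the
maximum principal curvature kappa1. On digitized surfaces kappa1 separates
a planted sharp ridge from background noise much more cleanly than K
(ridge flanks are nearly developable, so K collapses toward zero there),
and the CLR pipeline (`extract_clr()`) therefore operates on kappa1 at the
95th percentile, resolved *within* the anatomical region so that sharp
structures outside it (shaft rim, roof edges, the resection cut) do not
inflate the cutoff.

Region growing connects feature points into ordered curves under three
criteria: spatial proximity (<= eps, default 2.5 mean edge lengths),
curvature consistency (|K_i - K_j| <= sigma_k, default the IQR over the
feature set), and directional continuity (<= 30 degrees). The continuity
criterion is applied to the angle between consecutive growth steps - the
discrete curve tangent - rather than to principal directions: on a feature
band several vertices wide, principal directions are parallel all across
the band and cannot prevent the greedy chain from weaving across it,
whereas step-direction continuity forces the chain to march along the
ridge. Ties are broken by ascending distance, making growth deterministic.

Curves are clipped to an oriented-box condylar region (axes from the
optimized sagittal frame; anteroposterior bounds shrunk 10%, a 2 mm margin
away from the resection cut, and a superior cap at the notch-roof level).
Among the substantial surviving segments (at least half the length of the
longest), the most posterior is labelled CLR and the most anterior the
anterior margin.

## The BH grid and the footprint point

The lateral condyle is projected orthographically along the epicondylar
axis - the "standard lateral position" in which the condyles overlap.
Blumensaat's line is the projected intercondylar-roof polyline, smoothed
by a moving average (window 5) and parameterized by arc length; its
direction is the first principal component of its points, oriented
anteriorly. The deep-shallow axis D(t) runs parallel to it across the
posterior-to-anterior silhouette extent; the height axis H(h) runs
perpendicular from the roof to the most inferior silhouette point. Both
are divided into 4 equal cells, and the recommended ACL footprint sits at
t = 24.8% from the posterior margin and h = 28.5% from the roof. The
normalized coordinates are exact by construction and invariant to rigid
motion and uniform scaling; what the phantom tests verify is that the
axis lengths and the footprint's absolute position agree with the
analytic silhouette construction.

## Registration and overlay

Frames are enhanced by contrast-limited adaptive histogram equalization
(8 x 8 tiles, output clamped to the input range) and edges extracted by
Canny with the fixed constants sigma = 1.2 px and hysteresis thresholds
0.3 / 0.7 on the normalized gradient magnitude. Normalization is robust -
the 99th percentile over the non-maximum-suppression candidates - because
scaling by the absolute maximum lets a single high-contrast silhouette
suppress every anatomical edge in the frame.

The initial alignment uses SIFT: difference-of-Gaussian extrema over 4
octaves with 3 intervals (k = 2^(1/3)), sub-pixel refinement, contrast and
edge-response rejection, orientation histograms, and 4x4x8 = 128-bin
descriptors over a 16 x 16 sample neighbourhood, matched by an exact
kd-tree 2-nearest-neighbour search under the ratio test with tau = 0.75.
Because difference-of-Gaussian keypoints are unstable on thin line
renderings, the two inputs are first brought into a common representation:
soft distance-transform images exp(-d / sigma) of the model curves and of
the frame edge map (sigma = 8 px). The matched keypoints give a
least-squares rigid fit with greedy residual trimming (drop the worst
correspondence until the RMSE improvement stalls or half are gone) - the
ratio-test survivors still contain outliers, and the original formulation
has no outlier stage.

ICP then refines the alignment between the model curve points and the
frame edge points: alternating exact nearest-neighbour correspondence and
the closed-form rigid update, with the RMSE recorded after each update
(provably non-increasing, asserted in every test run). Registration is
planar (2D rigid): the imagery is monocular, so the rotation lives in
SO(2) with the 3D-to-2D bridge supplied by the projection that produced
the model curves; the millimetre scale of the reported RMSE comes from an
explicit mm-per-px calibration input. Tracking across frames seeds each
frame's ICP with the previous transform and triggers a full SIFT
re-initialization when the RMSE exceeds twice the running median - a
bounded-drift rule with a testable trigger. The overlay itself rasterizes
the grid without anti-aliasing and alpha-blends only the rasterized
pixels, so every other pixel is bit-identical to the input frame.

## The synthetic phantom

The phantom is a constructive solid with full analytic ground truth: two
ellipsoidal condylar lobes on the mediolateral (epicondylar) axis, a
planar-roofed bridge joining them above the intercondylar notch (the roof
centerline stands in for Blumensaat's line, tilted 25 degrees so it rises
anteriorly), a shaft stub, and a capsular crease planted along an arc on
the lateral lobe. Intensities are two-level (bone 700, background 0) with
Gaussian noise (SD 15) and a threshold ground truth of 350; identical
spec/seed pairs give bit-identical volumes. Default lobe semi-axes are
(13, 26, 26) mm medially and (13, 28, 28) mm laterally with a 30 mm
separation at 0.5 mm voxel pitch - the equal transverse semi-axes make
sections perpendicular to the epicondylar axis exactly circular, which is
the geometric idealization the plane optimization exploits. Two spherical
lobes would make that objective flat (every sphere section is a circle
with coincident foci), so plane-recovery properties use the prolate
default lobes.

The crease is an *added* triangular wedge ridge (apex 2 mm, half-width
1.75 mm) whose apex is a C0 (discontinuous-normal) line lying exactly on
the lobe surface. An earlier subtractive design (a groove cut by a thin
half-cylinder) was abandoned: at CT pitch its two rims are
indistinguishable from voxel-terracing curvature noise, whereas the wedge
apex is recalled at 83% by the Gaussian channel and at 100% by the
kappa1 channel under the 90th-percentile threshold. The renderer draws
the crease brighter than bone (albedo 1 vs 0.55 over a 0.8 mm band),
emulating the "white line" appearance that makes the CLR a usable
landmark in arthroscopy, and headlight Lambertian shading emulates the
light-on-scope geometry.

What the phantom does *not* emulate: cartilage and soft tissue, fluid and
debris, specular wet-surface reflections, lens distortion, and the true
anatomical variability of condylar shape. Passing tests therefore
demonstrate the geometric correctness of the pipeline under a known,
idealized geometry - not clinical performance on patient data.

## Problem sizes and tolerances

Test fixtures use 1 mm voxel pitch (about 280k voxels, 60k-face meshes)
for pipeline-level checks and the default 0.5 mm pitch (about 2.3M
voxels, 240k vertices) for the CLR-recovery and grid properties; these
sizes keep the full suite to a few minutes while staying above the
feature scales being measured. Recovery tolerances follow the geometry:
cutting-plane orientation to within 1 degree, CLR mean distance under
1 mm at 0.5 mm pitch with at least 90% arc coverage and a directed
Hausdorff (curve to truth) under 2 mean edge lengths, grid axis lengths
within 2% of the analytic silhouette, and footprint fractions exact to
machine precision. The end-of-arc region of the planted crease is rounded
by the indicator smoothing (about one voxel diagonal), which is why
completeness is measured as coverage rather than as a symmetric
Hausdorff bound.

## Known limitations

- The registration is rigid and planar; perspective mismatch between the
  standard-lateral model projection and an oblique arthroscopic view is
  absorbed into the residual rather than modelled.
- The curvature threshold, growth bounds, and region margins are
  config-exposed heuristics; the defaults were chosen on the phantom
  geometry and will need revisiting for pathological anatomy.
- Multimodal SIFT matching on curve-versus-edge representations yields
  few (if well-placed) matches; the initial transform is correspondingly
  coarse and relies on ICP's basin of convergence.
- The expert-concordance module reproduces the published three-tier
  partition only from per-group summary statistics (CV-only mode); raw
  marking coordinates are not public, so per-group within-2 mm
  percentages cannot be recomputed from first principles.
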