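---
title: "Pupil detection and gaze mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupil detection and gaze mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupiltrack)
```

## The problem

A head-mounted video-oculography (VOG) eye tracker films the eye with an
infrared camera (nominally 640 x 480 px) and must, for every frame, locate
the pupil center, map it to a point on the user's screen, and turn stable
fixations into selections. Under infrared illumination with the dark-pupil
geometry, the pupil is the darkest region of the image, the iris is darker
than the sclera, and the corneal reflection of the illuminator (the
*glint*) is the brightest spot — often inside or on the edge of the pupil,
where it is the main obstacle to accurate segmentation.

`pupiltrack` implements this computational stack end to end: a synthetic
image generator with exact ground truth, the shared preprocessing front
end, six pupil-center detectors, the biquadratic gaze calibration with its
mapping-rate quality gate, and the evaluation metrics used for such
systems. Everything is testable without any recordings because the
generator *is* the data source.

## The synthetic eye model

`eye_scene()` describes one frame: a pupil ellipse (center, semi-axes
$a \ge b$, rotation $\tau$), an iris disk at 2.5 times the major semi-axis,
a sclera background, glint disks, an optional eyelid band, four 8-bit
intensity levels ordered pupil < iris < sclera < glint (defaults 30, 100,
180, 250), additive Gaussian noise (sd in grey levels), and salt-and-pepper
noise standing in for camera shot and line noise. Rasterization is hard —
a pixel takes the class of its center, with no anti-aliasing — so
set-based tests against the geometric ground truth are exact. Rendering is
bit-reproducible from the scene seed.

The generator's default study conditions, used by the test suite and by
`scripts/acceptance.R`, are: pupil radius uniform in [15, 35] px (circular
benchmark), axis ratio $b/a$ uniform in [0.5, 0.8] and $\tau$ uniform in
$[0, \pi)$ (elliptical benchmark), one glint of radius 4 px placed inside
the pupil or centered on its edge, and Gaussian noise with sd 8 grey
levels. These emulate the pupil-scale range, glint geometry, and noise
character of head-mounted IR recordings. What they deliberately do *not*
model: eyelashes, eyeglass reflections, off-axis perspective distortion
beyond an affine ellipse, illumination gradients, or motion blur — so a
detector passing here is validated for its geometric and noise robustness,
not for every pathology of real footage.

## Preprocessing front end

All detectors share the same four stages.

1. **Median denoising** (`denoise()`, default 3 x 3) suppresses impulse
   noise before the histogram is formed.
2. **Adaptive percentile binarization.** The fraction of pixels belonging
   to the pupil is nearly constant for a head-mounted camera; for a pupil
   of radius $r$ it is $t_0 = 100\,\pi r^2 / (WH)$ percent
   (`percentile_from_radius()`). The threshold $T$
   (`quantitative_threshold()`) is the smallest grey level whose
   cumulative pixel fraction reaches $t_0$, and the object mask is
   `intensity <= T`. Because $T$ is a quantile, the binarization is
   invariant to any illumination change that preserves intensity ordering.
   The `<=` polarity (rather than `<`) makes $T$ attainable directly from
   the cumulative histogram. The risk around $t_0$ is asymmetric:
   undershooting the true pupil fraction merely thins the mask inside the
   pupil, which the reconstruction refills, while overshooting floods the
   mask with iris pixels (the next-darkest region) — on a noiseless
   discrete histogram even an overshoot of a fraction of a pixel jumps
   $T$ to the iris level. The pipeline therefore deflates the
   radius-derived percentile by a safety factor (`t0_safety`, default
   0.95), and the calibration-measured pupil *area* (see below) is the
   preferred source for $t_0$.
3. **Largest component + morphological reconstruction.** For the
   centroid, projection, and ellipse-fitting detectors, the maximum-area
   8-connected component is kept (`largest_component()`; area ties go to
   the component containing the smallest row-major pixel index) and the
   glint artifacts are removed by dilation, border-flood hole filling, and
   erosion with the same disc structuring element
   (`reconstruct_pupil()`). The disc radius defaults to
   $\max(3, 0.2\,r)$, scaling with the typical glint-to-pupil size ratio;
   it closes interior glint holes of any size and boundary notches up to
   its own radius. The Hough-transform detectors skip the maximum-area
   step (voting tolerates clutter) but use the same reconstruction.
4. **Laplacian-of-Gaussian edges** (`log_edges()`, default sigma 2 px)
   feed the Hough detectors: zero-crossing pixels of the LoG response,
   keeping the member of each crossing pair closer to zero, and requiring
   a local response swing above 0.03 (on 0-1 intensities) to reject the
   numerically-zero oscillation of flat regions and the faint ripple at
   the kernel truncation radius (support 4 sigma).

## The six detectors

* **CENT** — center of gravity of the reconstructed mask. Fastest;
  sensitive to any residual artifact.
* **PROJ** — column and row sums of the mask; each profile is thresholded
  at the mean of its strictly positive entries and the center is the
  midpoint of the above-threshold index range. The comparison is `>=`
  because an ideal rectangle's positive entries all equal their mean — a
  strict `>` would empty the range.
* **CHT** — every edge pixel votes, per radius in the grid, for all
  centers at that radial distance; the global 3-D accumulator peak gives
  the circle. Center bins are at pixel resolution; an edge pixel votes for
  a center when its radial distance to the candidate boundary is within
  `tol` (default 1 px), which absorbs edge-localization and grid
  quantization error. Peak ties break toward smallest y, then x, then
  radius. The default radius grid spans $[0.6, 1.4]\,r$ in steps of 2 px.
* **EHT** — the elliptical generalization: votes are generated per
  $(a, b, \tau)$ triplet by rotating the boundary offset by $\tau$ about
  the edge pixel; the peak over all triplets wins. `dims = 4` neglects
  $\tau$ (the real-time trade-off); `dims = 5` adds a $\tau$ grid
  (default step 15 degrees). Grids with $a < b$ are normalized by an axis
  swap plus a 90-degree rotation. The voting loop is compiled (Rcpp) and
  the accumulator is evaluated only on the edge bounding box plus one
  max-axis margin, which is lossless because votes cannot land further
  away.
* **LSFE** — direct least-squares conic fit to the mask contour with the
  ellipse (negative-discriminant) constraint; non-ellipse outcomes are
  errors. Points are centered before fitting for conditioning.
* **RANSAC** — repeated 5-point LSFE fits; the consensus set counts
  points within `inlier_tol` (default 2 px, radial distance) of the
  candidate ellipse; the iteration budget shrinks adaptively with the
  observed inlier fraction (99 % confidence) and the search stops early
  after 20 iterations without consensus growth (cap 500). The final
  ellipse is refit on the winning consensus. The RNG seed is a mandatory
  argument: identical seeds give identical detections.

`detect(img, method, config)` wires the front end to any of the six.

## Calibration and the mapping rate

The eye-to-screen mapping is a biquadratic polynomial per screen axis over
the monomials $\{1, x, y, xy, x^2, y^2\}$, least-squares fitted to nine
calibration pairs (`fit_biquadratic()`); its nonlinearity compensates the
nonlinearity of eye rotation. The inverse map (`invert_map()`) is a damped
Newton iteration seeded at the inverse of the map's affine part
(tolerance 1e-6 px, cap 100 iterations); divergence far outside the
calibrated region is reported as an error.

The pupil radius needed by the binarization percentile is estimated from
the central-fixation image (`estimate_pupil_radius()`). Because the
percentile itself needs a radius, estimation is two-stage: an Otsu split
of the denoised histogram into three classes isolates the darkest class
(the pupil under the dark-pupil ordering; if that class is itself strongly
bimodal — a very small pupil merged with the iris — it is re-split), and
the equivalent radius $\sqrt{\text{area}/\pi}$ of its reconstructed
largest component gives the *effective radius* $r_0$; a circular Hough
pass over a narrow grid around $r_0$ then refines the circle radius.
Since the percentile is an area fraction, $r_0$ is the right input to
`percentile_from_radius()` even for elliptical pupils (where
$r_0 \approx \sqrt{ab}$); the benchmarks use it per image. A circle fit
to an ellipse can lock onto the flat, large-curvature arcs and
overestimate the radius, which is why the refined circle radius is not
used for the percentile.

Calibration quality is gated by the **mapping rate** (MR,
`compute_mapping_rate()`): each quadrant center of the 3 x 3 screen tiling
is pulled back into the eye image, circles of radius $r = 1..10$ px around
the pre-image are sampled at 64 angles and mapped forward, and the mapped
shape is approximated by a circle of radius $R_i(r)$ — the mean distance
of the mapped samples from their centroid, a rotation-invariant estimator
that is unbiased when the shape really is a circle. Then
$MR_i = \overline{R_i(r)/r}$, $MR = \overline{MR_i}$, and the linear model
$R(r) = MR \cdot r$ predicts the on-screen target size reachable for a
given raw-image pixel accuracy (exactly, for affine maps). Calibrations
with $MR \ge 16$ are rejected and must be repeated; the threshold is
configurable.

## Evaluation metrics

* Static accuracy: pixel error (Euclidean distance to truth),
  `detection_rate_curve()` with $DR(e) = 100\,\#\{d < e\}/n$ and the
  headline $DR_5$. Strict inequality follows the metric's definition; it
  is configurable only through the threshold grid.
* Scene (real-time) accuracy: `scene_detection_rate()` ($DR_{50}$ with a
  50 px target radius, pooled with equal weight per point) and
  `cluster_metrics()` (distances to the per-quadrant centroid; CDR and
  CDIR = 100 - CDR), separating accuracy from stability: a constant
  calibration bias hurts DR but not CDR.
* `stabilize_signal()`: rolling-median spike canceller (window 5,
  threshold 50 px by default; a causal variant for streaming). Spikes
  shorter than half the window are removed; persistent steps survive.
* `dwell_select()`: a selection fires after
  $\lceil \text{dwell}\cdot\text{fps}/1000\rceil$ consecutive in-target
  frames; the counter resets on exit and a selected target is locked until
  exit (the Midas-touch guard). Overlapping targets resolve to the
  smallest index.
* `typing_error_rates()`: TER, NCER, CER with denominator $C + INF + IF$,
  so TER = NCER + CER identically.

## Numerical choices and degenerate inputs

* Coordinates are 1-based with pixel centers at integer (x, y), x =
  column, y = row — the natural R convention, used uniformly across all
  modules; ground truth and detections are subpixel.
* A constant (blank) image makes the quantitative threshold degenerate
  (the mask would be the whole image); the pipeline reports a no-pupil
  error rather than detecting a fictitious center.
* Hough peak ties and component-area ties have documented deterministic
  tie-breaks (smallest y/x/parameter; smallest row-major index), so all
  detectors are enumeration-order independent.
* The Hough vote-band `tol` trades localization sharpness against
  robustness to grid quantization; 1 px is the default everywhere, and
  the brute-force oracle used in the tests applies the same band.
* RANSAC on fewer than 5 points, collinear contours, or non-elliptical
  consensus sets fails explicitly rather than returning a spurious shape.

## Problem sizes used by the tests

The accuracy benchmarks run 200 circular and 200 elliptical synthetic
eyes at the full 640 x 480 resolution with per-image radius calibration —
enough for detection-rate estimates with a binomial standard error around
2 % while keeping the whole suite comfortably fast on a single core. The
Hough-oracle equivalence check uses 20 images up to 64 x 64, where the
brute-force nested-loop accumulator is exact and cheap. Property checks
(metric identities, threshold minimality) use 1000 randomized cases.

## Known limitations

* The generator's eyelid is a horizontal sclera-intensity band — a cheap
  stand-in for the real failure mode of lid occlusion, not a lid model.
* CHT estimates of the *radius* are biased upward on elliptical pupils
  (circles hug the flat arcs); center estimates are the quantity the
  system consumes.
* The EHT 5-D search cost grows with the triplet grid; the defaults are
  sized for offline analysis, and the 4-D variant is the real-time
  choice.
* `estimate_pupil_radius()` assumes the dark-pupil intensity ordering; it
  will mis-lock on bright-pupil imagery, which is out of scope.
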