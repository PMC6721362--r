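# pupiltrack

Pupil detection and gaze mapping for dark-pupil video-oculography (VOG).

Head-mounted infrared eye trackers film the eye (nominally 640 × 480 px),
locate the pupil center in every frame, map it to screen coordinates, and
turn stable fixations into selections — the basis of gaze-controlled
interfaces such as eye-typing keyboards for users who cannot operate a
physical input device. Under IR illumination the pupil is the darkest
image region, and the bright corneal reflection (*glint*) sitting inside
or on the edge of the pupil is the main segmentation obstacle.

`pupiltrack` implements this stack for researchers comparing pupil
detection algorithms (PDAs) and building gaze interfaces:

* **Synthetic eye images with exact ground truth** (`eye_scene()`,
  `render_eye_image()`, `generate_dataset()`): pupil ellipse, iris,
  glints, eyelid occlusion, Gaussian + salt-and-pepper noise; seeded and
  bit-reproducible, so every downstream stage is testable without any
  recordings.
* **Shared preprocessing**: median denoising; adaptive percentile
  binarization, where the threshold *T* is the smallest grey level whose
  cumulative pixel fraction reaches the pupil's expected area percentile
  *t₀* = 100 π r² / (W·H) (`percentile_from_radius()`,
  `quantitative_threshold()`); maximum-area component selection; glint
  removal by dilation–fill–erosion (`reconstruct_pupil()`);
  Laplacian-of-Gaussian edges (`log_edges()`).
* **Six detectors** behind one interface (`detect()`): centroid (CENT),
  projection profiles (PROJ), circular and elliptical Hough transforms
  (CHT, EHT — 3-D, 4-D or 5-D accumulator, compiled voting core),
  direct least-squares ellipse fitting (LSFE), and seeded RANSAC ellipse
  fitting.
* **Calibration** (`fit_biquadratic()`, `invert_map()`,
  `estimate_pupil_radius()`): a per-axis biquadratic polynomial over
  {1, x, y, xy, x², y²} maps eye to screen coordinates; the **mapping
  rate** MR (`compute_mapping_rate()`) — the mean factor by which small
  raw-image circles inflate on screen, MRᵢ = mean(Rᵢ(r)/r) over r = 1..10
  px and MR = mean(MRᵢ) — gates calibration quality (accept when
  MR < 16), and R(r) = MR·r predicts the usable on-screen target size.
* **Evaluation** (`detection_rate_curve()`, `scene_detection_rate()`,
  `cluster_metrics()`, `stabilize_signal()`, `dwell_select()`,
  `typing_error_rates()`): DR₅ pixel-error rates, scene DR₅₀ within a
  50 px target, cluster dispersion CDIR = 100 − CDR, median spike
  cancelling, dwell-time selection with a Midas-touch guard, and the
  TER/NCER/CER text-entry error rates with denominator C + INF + IF.

## Worked example

```r
library(pupiltrack)

# a noisy synthetic eye: pupil radius 24 px, glint on the pupil edge
scene <- eye_scene(center = c(316.4, 243.8), axes = c(24, 24),
                   glints = glint(4, "on_edge"), gaussian_sigma = 8,
                   seed = 42)
img <- render_eye_image(scene)$image

# calibration-stage radius estimate drives the binarization percentile
est <- estimate_pupil_radius(img)
attr(est, "effective_radius")
#> [1] 23.86

detect(img, "cht", config = list(r_pupil = attr(est, "effective_radius")))
#> <pupil_detection CHT> center = (316.00, 244.00), score = 121
#>   shape: a = 24.00, b = 24.00, tau = 0.000 rad
```

The detected center lies 0.45 px from the ground truth, and the
accumulator peak collected 121 edge votes for the radius-24 circle.

```r
# fit a gaze map from 9 calibration pairs and check its quality
map <- fit_biquadratic(cal)     # cal: columns ex, ey, sx, sy
compute_mapping_rate(map)
#> <mapping_rate_report> MR = 3.203 (accepted; threshold 16)
#>    Q1    Q2    Q3    Q4    Q5    Q6    Q7    Q8    Q9
#> 2.598 3.253 3.759 2.596 3.252 3.758 2.598 3.253 3.759
```

MR ≈ 3.2 means a 1 px raw-image error becomes ≈ 3.2 px on screen: with a
5 px detector accuracy, targets of radius ≈ 16 px are reliably selectable
on this calibration. The per-quadrant rates show the map's mild
nonlinearity across the screen.

```r
typing_error_rates(C = 116, IF = 14, INF = 5)
#>       TER      NCER       CER
#> 14.074074  3.703704 10.370370
```

Of 135 scored inputs, 14.07 % were errors; 10.37 % were corrected during
entry (CER) and 3.70 % remained in the final text (NCER).

## Command line

A thin Rscript front end (`inst/exec/pupiltrack`) exposes the pipeline:

```sh
pupiltrack synth --n 200 --seed 1 --noise-sigma 8 --glint inside,on_edge --out ds/
pupiltrack detect --images ds/ --method cht --out detections.csv
pupiltrack calibrate --cal cal.csv --out map.json
pupiltrack map-rate --map map.json
pupiltrack evaluate --static detections.csv --truth ds/truth.csv --out metrics.json
pupiltrack benchmark --n 100 --seed 1 --out bench/
```

Every run writes a `manifest.json` (config, seed, version); identical
seeds give byte-identical outputs.

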