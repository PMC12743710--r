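---
title: "Prompt-guided lung field segmentation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-guided lung field segmentation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungprompt)
```

## The pipeline and its assumptions

`lungprompt` implements a text-prompt-guided segmentation chain for
frontal chest radiographs:

1. **Preprocess** — grayscale conversion, resize to a working resolution,
   and thresholding to a binary image.
2. **Prompt** — build a word-level anatomical phrase (`"right lung"`,
   `"right . lobe ."`).
3. **Detect** — a text-guided detector maps (image, phrase) to scored
   bounding boxes; detections below the confidence threshold are dropped.
   Detection can run on the raw grayscale image or on the binarized
   rendering (the *binary pathway*), in which case boxes are mapped back
   to original coordinates.
4. **Refine** (optional) — greedy local search over box moves maximizing a
   segmentation-quality objective.
5. **Segment** — a promptable segmenter maps (image, box) to candidate
   masks with self-reported quality scores; one candidate is selected by
   policy.
6. **Evaluate** — IoU, binarized-predicted IoU (BPIoU), soft Dice loss,
   stability score; batch runs add score histograms and a reliability
   table.

The central assumption is architectural, not anatomical: the detector and
segmenter are opaque scored functions behind two S3 contracts
(`backend_detect()`, `backend_segment()`). Everything this package is
responsible for — thresholding, prompt framing, box bookkeeping, the
refinement search, the metrics, the calibration procedure — operates on
boxes, masks and scores only. That is what makes an exact oracle test
harness possible.

## The synthetic phantom and the oracle backends

`phantom_spec()` / `generate_phantom()` draw two rotated ellipses of low
intensity (default 60) on a brighter background (default 180, 8-bit),
add seeded Gaussian noise (default sd 5, mild quantum mottle), and return
the exact ellipse rasterizations as per-lobe ground-truth masks. Under
the radiographic convention the patient's right lung sits on the image
left; the default geometry places a slightly larger right lobe and a
smaller left lobe (the cardiac silhouette encroaches on the left), both
strictly inside the frame and disjoint. 12-bit intensity ranges are
supported for computed-radiography-like data (stored via a 16-bit TIFF
container; 8-bit images use PNG).

The phantom is deliberately *not* anatomically textured: no ribs, no
mediastinum, no gradient vignetting. Every downstream stage consumes
boxes, masks and scores, so flat-intensity ellipses keep the oracles
exact — the oracle segmenter can be proven to return precisely the
ground-truth lobe from its tight box. The corresponding limitation is
stated below.

* `oracle_detector()` parses the prompt for a side token and an anatomy
  token and returns the tight ground-truth box, optionally translated by
  a seeded jitter of up to ±`jitter` px per axis with confidence
  `exp(-|offset|/scale)` (scale default 10 px, so a 10 px miss costs a
  factor `e`). A side-less prompt (`"lung"`) returns both lobes, matching
  the multi-detection behaviour of real text-guided detectors; a prompt
  with no anatomical token returns nothing.
* `oracle_segmenter()` thresholds *within the box* by Otsu, labels the
  connected dark components (EBImage), and returns one candidate per
  component overlapping the box, scored by the fraction of that component
  captured inside the box. The score is therefore maximized exactly when
  the box contains the whole lobe, giving the refinement search a
  verifiable objective landscape. Up to three candidates are returned
  (mirroring multi-mask output of promptable segmenters);
  `erode_px > 0` produces a deliberately under-segmenting,
  score-optimistic variant used to test quality orderings and
  calibration.
* `intensity_detector()` is a third, weightless image-driven backend: it
  boxes the largest dark components of whatever image it is shown. It is
  the natural detector for the binary pathway when no ground truth
  exists.

What passing tests on phantoms does **not** show: robustness to real
anatomy (overlapping soft tissue, pathology, tubes and implants), to
texture that breaks a single global threshold, or to the failure modes of
real text grounding. Those belong to the plugin backends, not to this
package's stages.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_size` | 224 × 224 | px | standard transformer-detector working resolution; `NULL` keeps native resolution |
| `threshold_mode` | `otsu` | — | automatic split of dark lung fields vs background |
| `fixed_threshold` | 127 | intensity | mid-scale fallback (and fixed mode) for 8-bit renderings |
| `binar_high_value` | 196 | intensity | foreground level of the detector-facing binary rendering |
| `box_threshold`, `text_threshold` | 0.25 | — | detection confidence / phrase-grounding cutoffs |
| `translation_steps` | 0, ±1, ±2, ±5, ±10 | px | multi-scale neighbourhood; see below |
| `max_iterations` | 10 | sweeps | with ±10 steps this crosses ~100 px of displacement |
| `min_improvement` | 1e-6 | objective | plateau detection; objectives are ratios of pixel counts, so genuine gains are ≫ 1e-6 |
| stability `magnitude`, `n` | 3 px, 5 | — | small perturbations, 10 mask pairs |
| calibration `iou_cutoff` | 0.5 | IoU | operational "good segmentation" judgment |
| calibration `n_bins` | 10 | — | standard reliability-diagram resolution |

## Numerical choices, conventions, degenerate inputs

* **Coordinates.** 0-based pixel indices; boxes are half-open
  `[x_min, x_max) × [y_min, y_max)`, so areas and mask slices are exact
  integer arithmetic. Mapping between resolutions floors minima and
  ceils maxima — coverage never shrinks, and an integer up-scale
  round-trips within one pixel.
* **Binarization.** Foreground is `I >= T`. The common library call this
  chain mirrors accepts both an automatic-threshold flag and a fixed
  value, ignoring the fixed value when the flag is set; `binarize()`
  reproduces that behaviour (mode `"otsu"` ignores `fixed_threshold`)
  while keeping the fixed form testable in mode `"fixed"`. A constant
  image has no Otsu split and falls back to the fixed threshold with a
  warning. The boolean mask is the canonical object; the 196-level
  rendering exists only for detector input.
* **Otsu.** Implemented over the integer histogram with cumulative
  moments — algebraically identical to exhaustively maximizing
  `w0 w1 (mu0 - mu1)^2` over every candidate threshold, which is exactly
  how the tests verify it (plus a cross-check against an independent
  library implementation, whose binning convention may shift the cut by
  one level). Ties break to the smallest threshold.
* **Resize.** Area-average downscaling is computed with exact integer
  overlap weights (every cell boundary is an integer once scaled by the
  output size), divided once after the separable product — so a constant
  image stays bit-exactly constant. Nearest-neighbour is available and is
  the identity at equal sizes.
* **Refinement.** The neighbourhood is every `(dx, dy, scale)`
  combination of the signed steps; the identity move is always included,
  making the objective trace non-decreasing and the final box never
  worse than the initial one. Ties resolve identity-first, then smallest
  offset magnitude, then x-axis before y-axis moves — termination and
  reproducibility are structural, not incidental. The step set includes
  ±1 because a coarse set such as {±2, ±5, ±10} strands the search one
  pixel from the optimum: from an odd offset, every move overshoots to a
  mirror position of equal score, the improvement is zero, and the
  search stops. With the unit step the greedy search settles
  pixel-exactly, and on noiseless phantoms it provably reaches the
  exhaustive-search optimum whenever the objective is unimodal over the
  explored basin. Two alternative objectives are provided —
  re-querying detector confidence for the moved box, and overlap with a
  reference mask — because the stage is equally well defined for either;
  the default is the segmenter's own quality score.
* **Metrics.** Two empty masks have IoU 1 and Dice loss 0 (perfect
  agreement on emptiness never scores worse than disagreement; the Dice
  case warns). BPIoU reads "binarized predicted mask" as thresholding a
  soft prediction (default 0.5, the `>=` side is foreground); the other
  reading — segmenting the binarized *input* image — is what the binary
  pathway computes end to end, and both are available. The squared-sum
  Dice denominator equals the plain sum on boolean masks (`v² = v`),
  asserted as an identity test. Stability perturbs the box prompt by
  default; an image-noise mode covers the perturbed-image reading of the
  score.
* **Calibration.** Scores are min-max scaled (a constant score vector is
  degenerate: everything maps to 1, with a warning; identity scaling is
  available for backends that already emit probabilities). Outcomes use
  an IoU cutoff with a `>=` boundary. Bins are equal-width on `[0, 1]`,
  the last bin right-closed; empty bins are reported with count 0 and
  `NA` means so bin counts always conserve the sample count.
* **Determinism.** Every stochastic component (phantom noise, detector
  jitter, stability perturbations) is a pure function of an explicit
  seed; batch runs derive per-image seeds from the master seed, and two
  runs with the same configuration produce byte-identical metric CSVs.

## Problem sizes used by the test suite

The suite verifies metrics against brute-force counting on 200 random
mask pairs up to 64 × 64; Otsu against exhaustive search on 50 random
8-bit images; refinement monotonicity on 100 jittered 64 × 64 phantom
runs (offsets to ±15 px); greedy-vs-exhaustive optimality on 20
56 × 56 noiseless phantoms whose target lobe sits with margins wider
than the ±8 px jitter — a displaced box that hits the border would be
clipped smaller than the lobe, the captured fraction could then never
reach 1, and the objective over the full sweep would no longer be
unimodal (the sweep can prefer the other, smaller lobe), which is a
property of the fixture rather than of the search. Calibration is
checked on 10,000 Bernoulli(score) outcomes against three binomial
standard errors per occupied bin. These sizes make every oracle exact
while keeping the suite fast to run routinely.

## Known limitations

* Phantoms are flat ellipses plus Gaussian noise; none of the texture,
  pathology or hardware of real ICU films is simulated, so results on
  phantoms bound only the pipeline's bookkeeping, not clinical accuracy.
* No real detector/segmenter weights ship with the package; the plugin
  adapters are contracts, and their behaviour (prompt grounding quality,
  mask head choice) is outside the test surface.
* Input formats are PNG (8-bit) and TIFF (deeper); masks are 0/255 PNG.
* No histogram equalization or denoising is applied in preprocessing,
  and no learned or gradient-based box regression is attempted — the
  refinement stage is deliberately a transparent search.
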