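# lungprompt

Text-prompt-guided lung field segmentation for chest radiographs, built so
that every stage of the pipeline is verifiable without pre-trained model
weights.

## The problem

Segmenting the lung fields on a frontal chest radiograph — especially
portable ICU films — normally requires models trained on large annotated
datasets. An alternative is a *zero-shot* chain: a text-grounded object
detector turns an anatomical phrase such as `"right lung"` into a bounding
box, and a promptable segmenter turns that box into a mask. The chain
needs several bespoke pieces around the two models: image binarization to
suppress background clutter before detection, word-level prompt
construction, an iterative bounding-box refinement search for cases where
the initial detection is off, overlap metrics to score the masks, and a
calibration analysis relating self-reported quality scores to actual
segmentation success.

`lungprompt` implements that full chain in R. The detector and segmenter
are *contracts* (S3 generics `backend_detect()` / `backend_segment()`);
the package ships deterministic **oracle backends** driven by a synthetic
chest-phantom generator with exact per-lobe ground truth, so the bespoke
stages — the actual subject of this package — can be tested to machine
precision. Real zero-shot models (a grounding detector, a promptable
segmenter) can be plugged in behind the same contracts.

## The core quantities

* **Binarization** (threshold `T`, Otsu by default):
  `B(x, y) = 1` if `I(x, y) >= T`, else `0`. Otsu's `T` maximizes the
  between-class variance `w0 w1 (mu0 - mu1)^2` of the split.
* **IoU** (Jaccard): `|A ∩ B| / |A ∪ B|`.
* **BPIoU** — IoU computed after binarizing the predicted mask:
  `|B ∩ G| / |B ∪ G|` for binarized prediction `B` and ground truth `G`.
* **Dice loss**, squared-sum (soft) form:
  `L = 1 − 2 Σ(M_gt · M_pred) / (Σ M_gt² + Σ M_pred²)`; on boolean masks
  this reduces to one minus the classic Dice coefficient, and relates to
  IoU by `Dice = 2·IoU / (1 + IoU)`.
* **Stability score** — mean pairwise IoU of masks produced under small
  seeded perturbations of the prompt (box jitter) or of the image (noise).
* **Refinement** — greedy local search over box translations (default
  steps 0, ±1, ±2, ±5, ±10 px per axis; scalings optional) maximizing a
  segmentation-quality objective; the identity move guarantees a monotone,
  never-worse trace.
* **Calibration** — quality scores are min-max scaled to `[0, 1]`,
  outcomes assigned by an IoU cutoff, and binned into a reliability table
  (observed positive fraction vs mean predicted probability per bin).

## Worked example

```r
library(lungprompt)

spec <- phantom_spec(noise_sd = 5, seed = 7)        # 224 x 224 phantom
ph   <- generate_phantom(spec)                      # image + exact masks

det <- oracle_detector(ph$masks, jitter = 8, seed = 7)  # imperfect detector
boxes <- detect(det, ph$image, "right lung")
boxes[[1]]
#> <box [27, 96) x [63, 186) conf=0.3977409 phrase="right lung" space=original>

seg <- oracle_segmenter()
trace <- refine_box(ph$image, boxes[[1]], seg)      # greedy box refinement
trace
#> <refine_trace: 3 iteration(s), objective 0.9292 -> 1.0000, converged>

mask <- select_candidate(segment_box(seg, ph$image, trace$final_box))
mask_iou(mask, ph$masks$right)                      # 1
bpiou(mask, ph$masks$right)                         # 1
dice_loss(mask, ph$masks$right)                     # 0
stability_score(seg, ph$image, trace$final_box,
                magnitude = 3, n = 5, seed = 1)     # 0.9803
```

The jittered detection starts 8 px off (confidence 0.398, decaying with
the offset); three refinement sweeps raise the segmenter's
captured-fraction objective from 0.9292 to 1.0 and the final mask matches
the ground-truth lobe exactly. The stability score of 0.98 says the
segmentation barely moves under ±3 px box jitter.

Batch runs, the binary-image detection pathway, reliability tables and
score histograms are driven by `run_config()` / `run_batch()`, or from
the shell via the CLI at
`system.file("cli", "lungprompt", package = "lungprompt")`
(subcommands `generate`, `run`, `evaluate`, `calibrate`).

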