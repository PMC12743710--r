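#' Intersection over union of two binary masks
#'
#' `|a ∩ b| / |a ∪ b|`. Two empty masks agree perfectly and score 1.
#'
#' @param a,b Logical matrices of equal dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ")
  stopifnot(is.logical(a), is.logical(b))
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Binarized-predicted IoU
#'
#' IoU computed after binarizing the predicted mask: a soft prediction
#' (values in `[0, 1]`) is thresholded (`>= threshold` is foreground) and
#' the result compared to the boolean ground truth; an already-boolean
#' prediction passes through unchanged, so the metric then coincides with
#' plain IoU.
#'
#' @param predicted Logical matrix, or numeric matrix with values in
#'   `[0, 1]`.
#' @param ground_truth Logical matrix of the same dimensions.
#' @param threshold Binarization threshold for soft predictions, in
#'   `[0, 1]`. Default 0.5.
#' @return Scalar in `[0, 1]`.
#' @export
bpiou <- function(predicted, ground_truth, threshold = 0.5) {
  if (!all(dim(predicted) == dim(ground_truth))) {
    stop("mask dimensions differ")
  }
  if (!is.logical(predicted)) {
    if (threshold < 0 || threshold > 1) {
      stop("`threshold` must lie in [0, 1] for soft predictions")
    }
    if (any(predicted < 0 | predicted > 1)) {
      stop("soft predictions must lie in [0, 1]")
    }
    predicted <- predicted >= threshold
  }
  mask_iou(predicted, ground_truth)
}

#' Soft Dice loss (squared-sum form)
#'
#' `1 - 2 * sum(g * p) / (sum(g^2) + sum(p^2))`, the squared-denominator
#' soft Dice. On boolean masks the squared sums equal the plain sums, so
#' this reduces to one minus the classic Dice coefficient. Two all-zero
#' masks agree perfectly: loss 0, with a warning.
#'
#' @param predicted Numeric or logical matrix (soft values in `[0, 1]`
#'   allowed).
#' @param ground_truth Logical (or 0/1 numeric) matrix of equal dimensions.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(predicted, ground_truth) {
  if (!all(dim(predicted) == dim(ground_truth))) {
    stop("mask dimensions differ")
  }
  p <- as.numeric(predicted)
  g <- as.numeric(ground_truth)
  denom <- sum(g^2) + sum(p^2)
  if (denom == 0) {
    warning("both masks empty: Dice loss defined as 0 (perfect agreement)")
    return(0)
  }
  1 - 2 * sum(g * p) / denom
}

#' Dice coefficient
#' @inheritParams dice_loss
#' @return `1 - dice_loss(predicted, ground_truth)`.
#' @export
dice_coefficient <- function(predicted, ground_truth) {
  1 - dice_loss(predicted, ground_truth)
}

#' Stability score under input perturbation
#'
#' Segments the same target `n` times under small seeded perturbations and
#' returns the mean pairwise IoU of the selected masks — 1 when the
#' segmenter is perfectly stable, lower as perturbations change the output.
#' `mode = "box"` jitters the box prompt by uniform integer offsets up to
#' `magnitude` pixels per axis; `mode = "image"` adds Gaussian pixel noise
#' of standard deviation `magnitude` to the image instead (perturbed-image
#' reading of the score) and keeps the box fixed.
#'
#' @param segmenter A `segmenter` backend.
#' @param image Matrix or `gray_image`.
#' @param box A [bounding_box()].
#' @param magnitude Perturbation size: pixels of box jitter, or noise
#'   standard deviation. Default 3.
#' @param n Number of perturbations, at least 2. Default 5.
#' @param seed Integer seed for the perturbations. Default 1.
#' @param mode `"box"` (default) or `"image"`.
#' @param policy Candidate selection policy passed to [select_candidate()].
#' @return Mean pairwise IoU in `[0, 1]`.
#' @export
stability_score <- function(segmenter, image, box, magnitude = 3, n = 5L,
                            seed = 1L, mode = c("box", "image"),
                            policy = "best_score") {
  mode <- match.arg(mode)
  if (n < 2L) stop("`n` must be at least 2")
  perturb <- with_seed(seed, {
    if (mode == "box") {
      matrix(sample(seq(-magnitude, magnitude), 2L * n, replace = TRUE),
             ncol = 2)
    } else {
      lapply(seq_len(n), function(i) {
        matrix(stats::rnorm(length(image), sd = magnitude),
               nrow(image), ncol(image))
      })
    }
  })
  masks <- lapply(seq_len(n), function(i) {
    res <- tryCatch({
      if (mode == "box") {
        b <- shift_box(box, perturb[i, 1], perturb[i, 2])
        segment_box(segmenter, image, b)
      } else {
        noisy <- pmin(pmax(as_plain_matrix(image) + perturb[[i]], 0),
                      image_max_value(image))
        segment_box(segmenter,
                    gray_image(round(noisy),
                               bit_depth = image_bit_depth(image)), box)
      }
    }, error = function(e) {
      stop(sprintf("segmentation failed for perturbation %d: %s",
                   i, conditionMessage(e)), call. = FALSE)
    })
    select_candidate(res, policy = policy)
  })
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p) mask_iou(masks[[p[1]]], masks[[p[2]]])))
}

#' Assemble a metrics report row
#'
#' The standard per-(image, prompt) record written to metric CSVs.
#'
#' @param image_id,prompt,backend_id Identifiers.
#' @param iou,bpiou,dice_loss,stability Metric values (`NA` when not
#'   computed).
#' @param n_detections Number of surviving detections.
#' @param refined Whether box refinement ran.
#' @return One-row data frame.
#' @export
metrics_row <- function(image_id, prompt, backend_id, iou = NA_real_,
                        bpiou = NA_real_, dice_loss = NA_real_,
                        stability = NA_real_, n_detections = 0L,
                        refined = FALSE) {
  data.frame(image_id = image_id, prompt = prompt, backend_id = backend_id,
             iou = iou, bpiou = bpiou, dice_loss = dice_loss,
             stability = stability, n_detections = n_detections,
             refined = refined, stringsAsFactors = FALSE)
}
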