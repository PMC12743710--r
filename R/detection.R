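#' Detector thresholds
#'
#' `box_threshold` filters detections by confidence; `text_threshold` is the
#' phrase-grounding cutoff applied inside text-guided backends (the oracle
#' backends do hard token matching, so it only reaches plugin backends).
#' Both default to 0.25, the operating point commonly used when applying
#' zero-shot grounding detectors to radiographs.
#'
#' @param box_threshold Minimum confidence for a detection to survive, in
#'   `[0, 1]`. Default 0.25.
#' @param text_threshold Phrase-grounding threshold, in `[0, 1]`.
#'   Default 0.25.
#' @return A `detector_config` list.
#' @export
detector_config <- function(box_threshold = 0.25, text_threshold = 0.25) {
  if (box_threshold < 0 || box_threshold > 1 ||
      text_threshold < 0 || text_threshold > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  structure(list(box_threshold = box_threshold,
                 text_threshold = text_threshold),
            class = "detector_config")
}

#' Run a detector with confidence thresholding
#'
#' Calls the backend, keeps detections with confidence at or above
#' `box_threshold`, and returns them sorted by descending confidence (ties
#' keep backend order). An empty result is a legitimate outcome — some
#' prompts simply fail to ground — and is distinct from a backend error,
#' which propagates.
#'
#' @param detector A `detector` backend (see [backend-contracts]).
#' @param image Matrix or `gray_image`.
#' @param prompt Nonempty prompt string.
#' @param config A [detector_config()].
#' @return List of [bounding_box()] objects, possibly empty.
#' @export
detect <- function(detector, image, prompt, config = detector_config()) {
  if (nrow(image) < 1L || ncol(image) < 1L) stop("image must be nonempty")
  if (!is.character(prompt) || !nzchar(prompt)) {
    stop("prompt must be a nonempty string")
  }
  raw <- backend_detect(detector, image, prompt)
  raw <- raw[raw$confidence >= config$box_threshold, , drop = FALSE]
  raw <- raw[order(-raw$confidence), , drop = FALSE]
  lapply(seq_len(nrow(raw)), function(i) {
    bounding_box(raw$x_min[i], raw$y_min[i], raw$x_max[i], raw$y_max[i],
                 confidence = raw$confidence[i], phrase = raw$phrase[i],
                 source_space = "original")
  })
}

#' Detect on the binarized rendering of an image
#'
#' The binary-image detection pathway: the image is resized to the working
#' resolution, thresholded ([binarize()]), rendered for the detector
#' ([render_binary()]), and detection runs on that rendering. Boxes are
#' tagged `source_space = "binary"` and mapped back to original-image
#' coordinates through the resize scale factors (coverage-preserving
#' floor/ceiling rounding).
#'
#' @inheritParams detect
#' @param preprocess A [preprocess_config()].
#' @return List of [bounding_box()] objects in original coordinates with
#'   `source_space = "binary"`.
#' @export
detect_on_binary <- function(detector, image, prompt,
                             preprocess = preprocess_config(),
                             config = detector_config()) {
  rs <- resize_image(image, preprocess)
  bin <- binarize(rs$image, preprocess)
  rendered <- render_binary(bin$mask, preprocess)
  boxes <- detect(detector, rendered, prompt, config)
  lapply(boxes, function(b) {
    b$source_space <- "binary"
    b <- clip_box(b, rendered)
    if (is.null(b)) return(NULL)
    map_box(b, 1 / rs$scale, target_space = "binary")
  })
}

#' Score an arbitrary box under a detector
#'
#' An optional capability used when box refinement optimizes detector
#' confidence rather than segmenter quality: given a candidate box, return
#' the confidence the detector assigns to it for this prompt.
#'
#' @param detector A `detector` backend implementing this generic.
#' @param image Matrix or `gray_image`.
#' @param box A [bounding_box()].
#' @param prompt Prompt string.
#' @return Confidence in `[0, 1]`.
#' @export
score_box <- function(detector, image, box, prompt) {
  UseMethod("score_box")
}

#' @export
score_box.oracle_detector <- function(detector, image, box, prompt) {
  side <- prompt_side(prompt)
  if (is.na(side)) side <- "right"
  ref <- tight_box(detector$gt_masks[[side]])
  d <- mean(abs(c(box$x_min - ref$x_min, box$y_min - ref$y_min,
                  box$x_max - ref$x_max, box$y_max - ref$y_max)))
  exp(-d / detector$confidence_scale)
}
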