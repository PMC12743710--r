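#' Detector and segmenter backend contracts
#'
#' A *detector* turns (image, text prompt) into scored, phrase-labelled
#' bounding boxes; a *segmenter* turns (image, box prompt) into one or more
#' candidate masks with self-reported quality scores. Both are S3 contracts:
#' a backend is any object of class `detector` (resp. `segmenter`) with a
#' [backend_detect()] (resp. [backend_segment()]) method and an `id` field.
#' The package ships deterministic oracle backends built on the phantom
#' generator so every downstream stage is testable without pre-trained
#' weights; adapters for real zero-shot models implement the same two
#' generics.
#'
#' @name backend-contracts
NULL

#' Raw backend detection call
#'
#' Returns every candidate detection, before confidence thresholding, as a
#' data frame with columns `x_min, y_min, x_max, y_max, confidence, phrase`.
#' Boxes are in the coordinate space of `image`.
#'
#' @param detector A `detector` backend.
#' @param image Matrix or `gray_image`.
#' @param prompt Prompt string.
#' @return Data frame of raw detections (possibly zero rows).
#' @export
backend_detect <- function(detector, image, prompt) {
  UseMethod("backend_detect")
}

#' Raw backend segmentation call
#'
#' @param segmenter A `segmenter` backend.
#' @param image Matrix or `gray_image`.
#' @param box A [bounding_box()] intersecting the image.
#' @return A `segmentation_result` (see [segment_box()]).
#' @export
backend_segment <- function(segmenter, image, box) {
  UseMethod("backend_segment")
}

empty_detections <- function() {
  data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
              y_max = numeric(), confidence = numeric(),
              phrase = character(), stringsAsFactors = FALSE)
}

#' Oracle detector backed by ground-truth masks
#'
#' A deterministic stand-in for a text-guided zero-shot detector. It parses
#' the prompt for a side token (`left`/`right`) and an anatomy token
#' (`lung`/`lobe`): a sided prompt yields the tight ground-truth box of that
#' lobe, a side-less anatomical prompt (e.g. `"lung"`) yields both lobes
#' (real detectors show the same multi-detection behaviour), and a prompt
#' with no anatomical token yields no detections. A seeded uniform jitter of
#' up to `jitter` pixels per axis can be applied to emulate imperfect
#' localization; the synthetic confidence decays with the jitter magnitude
#' as `exp(-|offset| / confidence_scale)`, so a zero-jitter detection has
#' confidence 1. When shown an image whose size differs from the mask
#' resolution, boxes are rescaled into the shown image's space.
#'
#' @param gt_masks Named list of logical matrices `right`, `left` (e.g. the
#'   `masks` element of [generate_phantom()]).
#' @param jitter Maximum per-axis translation in pixels (default 0: exact
#'   tight boxes).
#' @param seed Integer seed making the jitter reproducible; the same
#'   detector object always returns the same boxes.
#' @param confidence_scale Decay scale (pixels) of the synthetic confidence.
#' @return A `detector` backend.
#' @export
oracle_detector <- function(gt_masks, jitter = 0, seed = 1L,
                            confidence_scale = 10) {
  stopifnot(all(c("right", "left") %in% names(gt_masks)),
            jitter >= 0, confidence_scale > 0)
  structure(list(id = "oracle", gt_masks = gt_masks, jitter = jitter,
                 seed = as.integer(seed),
                 confidence_scale = confidence_scale),
            class = c("oracle_detector", "detector"))
}

#' @export
backend_detect.oracle_detector <- function(detector, image, prompt) {
  tokens <- prompt_tokens(prompt)
  anatomy <- intersect(c("lung", "lungs", "lobe", "lobes"), tokens)
  if (length(anatomy) == 0L) return(empty_detections())
  sides <- intersect(c("right", "left"), tokens)
  if (length(sides) == 0L) sides <- c("right", "left")
  rows <- lapply(sides, function(side) {
    mask <- detector$gt_masks[[side]]
    box <- tight_box(mask)
    scale <- c(nrow(image) / nrow(mask), ncol(image) / ncol(mask))
    if (any(scale != 1)) box <- map_box(box, scale)
    offset <- c(0, 0)
    if (detector$jitter > 0) {
      offset <- with_seed(detector$seed + match(side, c("right", "left")),
                          sample(-detector$jitter:detector$jitter, 2,
                                 replace = TRUE))
    }
    conf <- exp(-sqrt(sum(offset^2)) / detector$confidence_scale)
    box <- shift_box(box, dx = offset[1], dy = offset[2])
    box <- clip_box(box, image)
    if (is.null(box)) return(NULL)
    data.frame(x_min = box$x_min, y_min = box$y_min, x_max = box$x_max,
               y_max = box$y_max, confidence = conf,
               phrase = paste(side, anatomy[[1]]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_detections())
  do.call(rbind, rows)
}

#' Intensity-based detector
#'
#' A weightless image-driven detector for the binary pathway: it thresholds
#' the shown image (Otsu), labels connected dark components, and returns the
#' tight boxes of the largest dark regions — on a rendered binary chest
#' image these are the lung fields. Sides are assigned by centroid position
#' under the stated convention; confidence is the component's fraction of
#' the total dark area (two similar lungs each score near 0.5). A sided
#' prompt keeps only the matching box.
#'
#' @param max_regions Number of largest dark components to report (default 2).
#' @param min_area_frac Components smaller than this fraction of the image
#'   are ignored (noise specks). Default 0.005.
#' @param convention `"radiographic"` (patient right = image left, default)
#'   or `"viewer"`.
#' @return A `detector` backend.
#' @export
intensity_detector <- function(max_regions = 2L, min_area_frac = 0.005,
                               convention = c("radiographic", "viewer")) {
  convention <- match.arg(convention)
  structure(list(id = "intensity", max_regions = as.integer(max_regions),
                 min_area_frac = min_area_frac, convention = convention),
            class = c("intensity_detector", "detector"))
}

#' @export
backend_detect.intensity_detector <- function(detector, image, prompt) {
  tokens <- prompt_tokens(prompt)
  if (length(intersect(c("lung", "lungs", "lobe", "lobes"), tokens)) == 0L) {
    return(empty_detections())
  }
  thr <- otsu_threshold(image, max_value = image_max_value(image))
  if (is.na(thr)) return(empty_detections())
  dark <- as_plain_matrix(image) < thr
  labels <- EBImage::bwlabel(dark)
  sizes <- tabulate(labels[labels > 0])
  if (length(sizes) == 0L) return(empty_detections())
  keep <- which(sizes >= detector$min_area_frac * length(dark))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- utils::head(keep, detector$max_regions)
  if (length(keep) == 0L) return(empty_detections())
  rows <- lapply(keep, function(k) {
    m <- labels == k
    box <- tight_box(m)
    cx <- mean(which(m, arr.ind = TRUE)[, 2])
    side_left_half <- cx <= ncol(image) / 2
    side <- if (detector$convention == "radiographic") {
      if (side_left_half) "right" else "left"
    } else {
      if (side_left_half) "left" else "right"
    }
    data.frame(x_min = box$x_min, y_min = box$y_min, x_max = box$x_max,
               y_max = box$y_max, confidence = sizes[k] / sum(sizes[keep]),
               phrase = paste(side, "lung"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  wanted <- intersect(c("right", "left"), tokens)
  if (length(wanted) == 1L) {
    out <- out[grepl(wanted, out$phrase, fixed = TRUE), , drop = FALSE]
  }
  out
}

#' Oracle segmenter
#'
#' A deterministic stand-in for a promptable segmenter. Given a box prompt
#' it picks a threshold by Otsu *within the box*, takes the below-threshold
#' (dark) pixels as candidate foreground, and returns one candidate mask per
#' connected dark component overlapping the box (largest captured fraction
#' first, up to `max_candidates` — mirroring the multi-candidate output real
#' promptable segmenters produce for ambiguous prompts). Each candidate's
#' quality score is the fraction of its full connected component captured
#' inside the box, so the score is maximized exactly when the box contains
#' the whole structure — giving box refinement a verifiable objective
#' landscape. Degenerate boxes or boxes over constant background return one
#' empty candidate with score 0.
#'
#' @param max_candidates Maximum number of candidate masks (default 3).
#' @param erode_px Optional radius (pixels) by which returned masks are
#'   morphologically eroded *after* scoring — a deliberately miscalibrated
#'   under-segmenting variant used to exercise quality-ordering and
#'   calibration checks. Default 0 (exact).
#' @return A `segmenter` backend.
#' @export
oracle_segmenter <- function(max_candidates = 3L, erode_px = 0L) {
  stopifnot(max_candidates >= 1L, erode_px >= 0L)
  structure(list(id = if (erode_px > 0) sprintf("oracle_erode%d", erode_px)
                      else "oracle",
                 max_candidates = as.integer(max_candidates),
                 erode_px = as.integer(erode_px),
                 cache = new.env(parent = emptyenv())),
            class = c("oracle_segmenter", "segmenter"))
}

# Connected dark components of `image < thr`, memoized per (image, thr):
# refinement evaluates hundreds of boxes on one image with few distinct
# thresholds, so labelling once per threshold dominates the cost.
dark_components <- function(segmenter, image, thr) {
  key <- sprintf("t%g_%s", thr,
                 paste(dim(image), sum(image), collapse = "_"))
  if (!is.null(segmenter$cache[[key]])) return(segmenter$cache[[key]])
  labels <- EBImage::bwlabel(as_plain_matrix(image) < thr)
  sizes <- tabulate(labels[labels > 0])
  out <- list(labels = labels, sizes = sizes)
  segmenter$cache[[key]] <- out
  out
}

empty_candidate_result <- function(image, box, backend_id) {
  new_segmentation_result(
    candidates = list(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                           score = 0)),
    box_used = box, backend_id = backend_id)
}

#' @export
backend_segment.oracle_segmenter <- function(segmenter, image, box) {
  clipped <- clip_box(box, image)
  if (is.null(clipped) || box_area(clipped) < 2) {
    return(empty_candidate_result(image, box, segmenter$id))
  }
  rows <- (clipped$y_min + 1):clipped$y_max
  cols <- (clipped$x_min + 1):clipped$x_max
  vals <- as_plain_matrix(image)[rows, cols, drop = FALSE]
  thr <- otsu_threshold(vals, max_value = image_max_value(image))
  if (is.na(thr)) {
    return(empty_candidate_result(image, box, segmenter$id))
  }
  comp <- dark_components(segmenter, image, thr)
  in_box_labels <- comp$labels[rows, cols, drop = FALSE]
  overlap <- tabulate(in_box_labels[in_box_labels > 0],
                      nbins = length(comp$sizes))
  hit <- which(overlap > 0)
  if (length(hit) == 0L) {
    return(empty_candidate_result(image, box, segmenter$id))
  }
  scores <- overlap[hit] / comp$sizes[hit]
  ord <- order(scores, overlap[hit], decreasing = TRUE)
  hit <- utils::head(hit[ord], segmenter$max_candidates)
  scores <- utils::head(scores[ord], segmenter$max_candidates)
  inside <- box_mask(clipped, image)
  candidates <- mapply(function(k, s) {
    m <- (comp$labels == k) & inside
    if (segmenter$erode_px > 0) {
      brush <- EBImage::makeBrush(2L * segmenter$erode_px + 1L, shape = "box")
      m <- EBImage::erode(m * 1, brush) > 0
    }
    list(mask = m, score = s)
  }, hit, scores, SIMPLIFY = FALSE)
  new_segmentation_result(candidates = candidates, box_used = box,
                          backend_id = segmenter$id)
}
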