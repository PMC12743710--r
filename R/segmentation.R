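#' Segmentation result container
#'
#' Holds the candidate masks a promptable segmenter produced for one box
#' prompt. Candidates are `(mask, score)` pairs: the mask is a full-image
#' logical matrix and the score is the backend's self-reported quality in
#' `[0, 1]` (a predicted-overlap proxy for plugin models; the captured
#' component fraction for the oracle).
#'
#' @param candidates List of `list(mask = <logical matrix>, score =
#'   <scalar>)`, at least one.
#' @param box_used The [bounding_box()] prompt.
#' @param backend_id Backend identifier string.
#' @return A `segmentation_result`.
#' @export
new_segmentation_result <- function(candidates, box_used, backend_id) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  for (cand in candidates) {
    if (!is.logical(cand$mask) || !is.matrix(cand$mask)) {
      stop("candidate masks must be logical matrices")
    }
    if (cand$score < 0 || cand$score > 1) stop("scores must lie in [0, 1]")
  }
  structure(list(candidates = candidates, box_used = box_used,
                 backend_id = backend_id),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d candidate(s), backend %s, scores %s>\n",
              length(x$candidates), x$backend_id,
              paste(signif(vapply(x$candidates, `[[`, numeric(1), "score"), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Segment with a box prompt
#'
#' Validates that the box intersects the image, runs the backend, and
#' returns candidates sorted by descending quality score (ties keep backend
#' order).
#'
#' @param segmenter A `segmenter` backend (see [backend-contracts]).
#' @param image Matrix or `gray_image`.
#' @param box A [bounding_box()]; must intersect the image.
#' @return A [new_segmentation_result()].
#' @export
segment_box <- function(segmenter, image, box) {
  if (is.null(clip_box(box, image))) {
    stop("box lies fully outside the image")
  }
  res <- backend_segment(segmenter, image, box)
  scores <- vapply(res$candidates, `[[`, numeric(1), "score")
  res$candidates <- res$candidates[order(-scores)]
  res
}

#' Segment a list of box prompts
#'
#' One result per box, order preserved; a failing box aborts with its index
#' in the error message.
#'
#' @inheritParams segment_box
#' @param boxes Nonempty list of [bounding_box()] objects.
#' @return List of `segmentation_result` objects.
#' @export
segment_multi <- function(segmenter, image, boxes) {
  if (length(boxes) == 0L) stop("`boxes` must be nonempty")
  lapply(seq_along(boxes), function(i) {
    tryCatch(segment_box(segmenter, image, boxes[[i]]),
             error = function(e) {
               stop(sprintf("segmentation failed for box %d: %s",
                            i, conditionMessage(e)), call. = FALSE)
             })
  })
}

#' Select one mask from a segmentation result
#'
#' Automated selection policies standing in for a clinician's choice among
#' candidates: `"best_score"` takes the highest self-reported score,
#' `"largest"` the biggest mask, `"index"` the `index`-th candidate in the
#' result's order. All ties break towards the earliest index.
#'
#' @param result A `segmentation_result`.
#' @param policy `"best_score"` (default), `"largest"`, or `"index"`.
#' @param index Candidate position used by the `"index"` policy.
#' @return The selected logical mask.
#' @export
select_candidate <- function(result,
                             policy = c("best_score", "largest", "index"),
                             index = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(result, "segmentation_result"))
  cands <- result$candidates
  pick <- switch(policy,
    best_score = which.max(vapply(cands, `[[`, numeric(1), "score")),
    largest = which.max(vapply(cands, function(x) sum(x$mask), numeric(1))),
    index = {
      if (index < 1L || index > length(cands)) {
        stop("`index` out of range for this result")
      }
      index
    })
  cands[[pick]]$mask
}

#' Best self-reported quality score of a result
#' @param result A `segmentation_result`.
#' @return The maximum candidate score.
#' @export
result_score <- function(result) {
  max(vapply(result$candidates, `[[`, numeric(1), "score"))
}

#' Write an overlay rendering of a mask on an image
#'
#' Alpha-blends the mask (rendered in mid-gray boosted intensity) onto the
#' image for visual inspection and writes an RGB PNG: mask pixels are tinted
#' towards the top of the intensity range in the red channel.
#'
#' @param image Matrix or `gray_image`.
#' @param mask Logical matrix of the same size.
#' @param path Output PNG path.
#' @param alpha Blend weight of the tint in `[0, 1]`. Default 0.4.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, mask, path, alpha = 0.4) {
  stopifnot(all(dim(image) == dim(mask)))
  g <- as_plain_matrix(image) / image_max_value(image)
  r <- ifelse(mask, (1 - alpha) * g + alpha, g)
  arr <- array(c(r, g, g), dim = c(nrow(g), ncol(g), 3))
  png::writePNG(arr, target = path)
  invisible(path)
}
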