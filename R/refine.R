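#' Bounding-box refinement configuration
#'
#' The refinement stage improves an initial detection by greedy local search
#' over box translations (and optionally scalings) maximizing a
#' segmentation-quality objective. Each iteration evaluates the objective
#' for every move in the neighbourhood — all `(dx, dy, s)` combinations of
#' the signed translation steps and scale steps, clipped to image bounds —
#' and adopts the best; it stops when the best improvement falls below
#' `min_improvement` or after `max_iterations`.
#'
#' @param translation_steps Non-negative step magnitudes applied as both
#'   signs on each axis; 0 (the identity move) is always included. Default
#'   `c(0, 1, 2, 5, 10)`: the coarse steps cross large offsets quickly and
#'   the unit step lets the search settle pixel-exactly instead of stalling
#'   on a one-pixel plateau.
#' @param scale_steps Multiplicative box-size factors; 1 is always
#'   included. Default `1` (translations only).
#' @param max_iterations Maximum neighbourhood sweeps, at least 1.
#'   Default 10.
#' @param objective `"segmenter_score"` (default: best self-reported
#'   candidate score), `"detector_confidence"` (re-query via [score_box()]),
#'   or `"bpiou_vs_reference"` (overlap of the selected mask with
#'   `reference_mask`).
#' @param min_improvement Smallest objective gain counted as progress.
#'   Default 1e-6.
#' @param detector,prompt Needed for the `"detector_confidence"` objective.
#' @param reference_mask Needed for the `"bpiou_vs_reference"` objective.
#' @return A `refine_config` list.
#' @export
refine_config <- function(translation_steps = c(0, 1, 2, 5, 10),
                          scale_steps = 1,
                          max_iterations = 10L,
                          objective = c("segmenter_score",
                                        "detector_confidence",
                                        "bpiou_vs_reference"),
                          min_improvement = 1e-6,
                          detector = NULL, prompt = NULL,
                          reference_mask = NULL) {
  objective <- match.arg(objective)
  translation_steps <- sort(unique(c(0, abs(translation_steps))))
  scale_steps <- sort(unique(c(1, scale_steps)))
  if (max_iterations < 1L) stop("`max_iterations` must be at least 1")
  if (any(scale_steps <= 0)) stop("scale steps must be positive")
  structure(list(translation_steps = translation_steps,
                 scale_steps = scale_steps,
                 max_iterations = as.integer(max_iterations),
                 objective = objective,
                 min_improvement = min_improvement,
                 detector = detector, prompt = prompt,
                 reference_mask = reference_mask),
            class = "refine_config")
}

refine_objective_fn <- function(config, segmenter) {
  switch(config$objective,
    segmenter_score = function(image, box) {
      result_score(segment_box(segmenter, image, box))
    },
    detector_confidence = {
      if (is.null(config$detector) || is.null(config$prompt)) {
        stop("`detector_confidence` objective needs `detector` and `prompt`")
      }
      function(image, box) {
        score_box(config$detector, image, box, config$prompt)
      }
    },
    bpiou_vs_reference = {
      if (is.null(config$reference_mask)) {
        stop("`bpiou_vs_reference` objective needs `reference_mask`")
      }
      function(image, box) {
        mask <- select_candidate(segment_box(segmenter, image, box))
        bpiou(mask, config$reference_mask)
      }
    })
}

# Candidate moves in deterministic tie-break order: identity first, then
# ascending offset magnitude, then x-axis moves before y-axis moves.
refine_moves <- function(config) {
  steps <- config$translation_steps
  offs <- sort(unique(c(-steps, steps)))
  grid <- expand.grid(dx = offs, dy = offs, s = config$scale_steps)
  identity <- grid$dx == 0 & grid$dy == 0 & grid$s == 1
  mag <- sqrt(grid$dx^2 + grid$dy^2) + abs(log(grid$s)) * 100
  grid[order(!identity, mag, abs(grid$dy), abs(grid$dx),
             grid$dx, grid$dy, grid$s), , drop = FALSE]
}

#' Refine one bounding box by greedy local search
#'
#' Starting from `box`, repeatedly evaluates the objective for every move in
#' the configured neighbourhood (moves whose clipped box degenerates are
#' skipped; the identity move is always present, so the objective sequence
#' is non-decreasing and the final box is never worse than the initial one).
#' The argmax move is adopted; ties resolve to the identity move, then the
#' smallest offset magnitude, then x-axis before y-axis. The search stops
#' when the best improvement is below `min_improvement` (converged) or
#' after `max_iterations` sweeps.
#'
#' @param image Matrix or `gray_image`.
#' @param box Initial [bounding_box()].
#' @param segmenter A `segmenter` backend (used by the default objective).
#' @param config A [refine_config()].
#' @return A `refine_trace`: list with `iterations` (data frame of the box,
#'   objective value and move adopted at each sweep), `initial_box`,
#'   `initial_objective`, `final_box`, `final_objective`, `converged`.
#' @export
refine_box <- function(image, box, segmenter, config = refine_config()) {
  objective <- refine_objective_fn(config, segmenter)
  moves <- refine_moves(config)
  current <- clip_box(box, image)
  if (is.null(current)) stop("initial box lies fully outside the image")
  current_val <- objective(image, current)
  initial_box <- current
  initial_val <- current_val
  records <- vector("list", config$max_iterations)
  converged <- FALSE
  for (iter in seq_len(config$max_iterations)) {
    best_val <- -Inf
    best_idx <- NA_integer_
    best_box <- NULL
    for (m in seq_len(nrow(moves))) {
      cand <- shift_box(current, moves$dx[m], moves$dy[m], moves$s[m])
      cand <- clip_box(cand, image)
      if (is.null(cand)) next
      val <- objective(image, cand)
      if (val > best_val) {          # strict: first (tie-ordered) argmax wins
        best_val <- val
        best_idx <- m
        best_box <- cand
      }
    }
    if (is.na(best_idx)) stop("no admissible move from the current box")
    improvement <- best_val - current_val
    if (improvement >= config$min_improvement) {
      current <- best_box
      current_val <- best_val
      adopted <- moves[best_idx, ]
    } else {
      adopted <- data.frame(dx = 0, dy = 0, s = 1)   # stay put
      converged <- TRUE
    }
    records[[iter]] <- data.frame(
      iteration = iter, x_min = current$x_min, y_min = current$y_min,
      x_max = current$x_max, y_max = current$y_max,
      objective = current_val, dx = adopted$dx, dy = adopted$dy,
      scale = adopted$s)
    if (converged) break
  }
  structure(list(iterations = do.call(rbind, records[!vapply(records, is.null,
                                                             logical(1))]),
                 initial_box = initial_box, initial_objective = initial_val,
                 final_box = current, final_objective = current_val,
                 converged = converged),
            class = "refine_trace")
}

#' @export
print.refine_trace <- function(x, ...) {
  cat(sprintf(
    "<refine_trace: %d iteration(s), objective %.4f -> %.4f, %s>\n",
    nrow(x$iterations), x$initial_objective, x$final_objective,
    if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

#' Refine several boxes independently
#'
#' @inheritParams refine_box
#' @param boxes Nonempty list of [bounding_box()] objects.
#' @return List of `refine_trace` objects, order preserved; a failing box
#'   aborts with its index.
#' @export
refine_all <- function(image, boxes, segmenter, config = refine_config()) {
  if (length(boxes) == 0L) stop("`boxes` must be nonempty")
  lapply(seq_along(boxes), function(i) {
    tryCatch(refine_box(image, boxes[[i]], segmenter, config),
             error = function(e) {
               stop(sprintf("refinement failed for box %d: %s",
                            i, conditionMessage(e)), call. = FALSE)
             })
  })
}

#' Write a refinement trace as JSON lines
#'
#' One JSON record per iteration (box coordinates, objective, move), for
#' audit.
#'
#' @param trace A `refine_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(trace$iterations))) {
    writeLines(jsonlite::toJSON(as.list(trace$iterations[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
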