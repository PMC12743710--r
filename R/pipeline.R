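#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: inputs, prompts, backends,
#' pathway, and stage configurations. The stage order is fixed:
#' preprocess -> prompt -> detect (raw or binary pathway) -> refine
#' (optional) -> segment -> select -> evaluate -> report.
#'
#' @param inputs Either a list of in-memory items — each
#'   `list(id = <string>, image = <matrix>, masks = <named list right/left
#'   or NULL>)`, e.g. a [generate_phantom()] result plus an `id` — or a data
#'   frame with columns `image_id`, `image_path` and optional
#'   `right_mask_path`, `left_mask_path` (PNG files).
#' @param prompts List of [prompt_spec()] objects (or a character vector of
#'   plain terms).
#' @param detector,segmenter Backends; when `NULL` and ground-truth masks
#'   are available, per-image oracle backends are built (the phantom study
#'   setup). `detector` may also be the string `"intensity"` for the
#'   image-driven [intensity_detector()].
#' @param pathway `"raw"` (detect on the grayscale image, default) or
#'   `"binary"` (detect on the binarized rendering, boxes mapped back).
#' @param preprocess A [preprocess_config()]. For the default oracle study
#'   the working resolution equals the native phantom resolution.
#' @param detector_cfg A [detector_config()].
#' @param refine A [refine_config()] to enable box refinement, or `NULL`
#'   (off).
#' @param select_policy Candidate selection policy, see [select_candidate()].
#' @param stability_n Perturbations for the stability score; 0 disables it.
#'   Default 0.
#' @param stability_magnitude Box jitter (pixels) for the stability score.
#' @param iou_cutoff Outcome cutoff for calibration, see [assign_outcomes()].
#' @param n_bins Calibration bins. Default 10.
#' @param detector_jitter Jitter (pixels) for auto-built oracle detectors.
#'   Default 0.
#' @param output_dir Directory for artifacts, or `NULL` for in-memory runs.
#' @param seed Integer master seed fixing every stochastic component.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, prompts, detector = NULL, segmenter = NULL,
                       pathway = c("raw", "binary"),
                       preprocess = preprocess_config(target_size = NULL),
                       detector_cfg = detector_config(),
                       refine = NULL, select_policy = "best_score",
                       stability_n = 0L, stability_magnitude = 3,
                       iou_cutoff = 0.5, n_bins = 10L,
                       detector_jitter = 0, output_dir = NULL, seed = 1L) {
  pathway <- match.arg(pathway)
  if (is.character(prompts)) prompts <- lapply(prompts, prompt_spec)
  if (is.data.frame(inputs)) {
    stopifnot(all(c("image_id", "image_path") %in% names(inputs)))
    missing <- inputs$image_path[!file.exists(inputs$image_path)]
    if (length(missing) > 0L) {
      stop("missing input images: ", paste(missing, collapse = ", "))
    }
  } else if (length(inputs) == 0L) {
    stop("`inputs` must be nonempty")
  }
  structure(list(inputs = inputs, prompts = prompts, detector = detector,
                 segmenter = segmenter, pathway = pathway,
                 preprocess = preprocess, detector_cfg = detector_cfg,
                 refine = refine, select_policy = select_policy,
                 stability_n = as.integer(stability_n),
                 stability_magnitude = stability_magnitude,
                 iou_cutoff = iou_cutoff, n_bins = as.integer(n_bins),
                 detector_jitter = detector_jitter,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_input <- function(item) {
  if (!is.null(item$image)) {
    list(id = item$id, image = item$image, masks = item$masks)
  } else {
    masks <- NULL
    if (!is.null(item$right_mask_path) && !is.na(item$right_mask_path)) {
      masks <- list(right = read_mask_png(item$right_mask_path),
                    left = read_mask_png(item$left_mask_path))
    }
    list(id = item$image_id, image = read_image_png(item$image_path),
         masks = masks)
  }
}

config_inputs <- function(config) {
  if (is.data.frame(config$inputs)) {
    lapply(seq_len(nrow(config$inputs)),
           function(i) as.list(config$inputs[i, ]))
  } else {
    config$inputs
  }
}

resolve_backends <- function(config, input, image_seed) {
  detector <- config$detector
  if (is.null(detector)) {
    if (is.null(input$masks)) {
      stop("no detector configured and no ground-truth masks to build an ",
           "oracle from; pass `detector = \"intensity\"` or a backend")
    }
    detector <- oracle_detector(input$masks, jitter = config$detector_jitter,
                                seed = image_seed)
  } else if (identical(detector, "intensity")) {
    detector <- intensity_detector()
  }
  segmenter <- if (is.null(config$segmenter)) oracle_segmenter()
               else config$segmenter
  list(detector = detector, segmenter = segmenter)
}

slugify <- function(x) {
  x <- gsub("[^a-zA-Z0-9]+", "-", tolower(x))
  gsub("^-|-$", "", x)
}

#' Run the pipeline on one image
#'
#' Executes the full stage chain for every configured prompt on one input.
#' With ground-truth masks present, IoU / binarized-predicted IoU / Dice
#' loss (and optionally the stability score) are computed against the lobe
#' the prompt names (the union of both lobes for side-less prompts); without
#' ground truth only masks and quality scores are reported. Artifacts
#' (selected masks, box JSON, refinement traces, per-image metrics CSV) are
#' written under `output_dir` with deterministic names
#' `<image_id>__<prompt_slug>__<backend>__<pathway>.<ext>`.
#'
#' @param config A [run_config()].
#' @param input One input item (see [run_config()]); defaults to the first.
#' @return A per-image report: list with `image_id`, `rows` (metrics data
#'   frame), `boxes`, `traces`, `masks`, `scores`, and per-prompt `status`.
#' @export
run_single <- function(config, input = config_inputs(config)[[1]]) {
  input <- load_input(input)
  idx <- match(input$id,
               vapply(config_inputs(config),
                      function(x) if (!is.null(x$id)) x$id else x$image_id,
                      character(1)))
  image_seed <- config$seed + ifelse(is.na(idx), 0L, idx)
  backends <- resolve_backends(config, input, image_seed)
  detector <- backends$detector
  segmenter <- backends$segmenter
  out_rows <- list()
  out <- list(image_id = input$id, boxes = list(), traces = list(),
              masks = list(), scores = list(), status = list())
  for (spec in config$prompts) {
    prompt <- build_prompt(spec)
    status <- tryCatch({
      boxes <- if (config$pathway == "binary") {
        detect_on_binary(detector, input$image, prompt,
                         preprocess = config$preprocess,
                         config = config$detector_cfg)
      } else {
        detect(detector, input$image, prompt, config = config$detector_cfg)
      }
      boxes <- boxes[!vapply(boxes, is.null, logical(1))]
      refined <- FALSE
      traces <- NULL
      if (!is.null(config$refine) && length(boxes) > 0L) {
        traces <- refine_all(input$image, boxes, segmenter, config$refine)
        boxes <- lapply(traces, `[[`, "final_box")
        refined <- TRUE
      }
      if (length(boxes) == 0L) {
        out_rows[[prompt]] <- metrics_row(input$id, prompt, segmenter$id,
                                           n_detections = 0L,
                                           refined = refined)
        out$boxes[[prompt]] <- list()
        "no_detections"
      } else {
        results <- segment_multi(segmenter, input$image, boxes)
        masks <- lapply(results, select_candidate,
                        policy = config$select_policy)
        union_mask <- Reduce(`|`, masks)
        scores <- vapply(results, result_score, numeric(1))
        row <- metrics_row(input$id, prompt, segmenter$id,
                           n_detections = length(boxes), refined = refined)
        if (!is.null(input$masks)) {
          side <- prompt_side(prompt)
          gt <- if (is.na(side)) input$masks$right | input$masks$left
                else input$masks[[side]]
          row$iou <- mask_iou(union_mask, gt)
          row$bpiou <- bpiou(union_mask, gt)
          row$dice_loss <- dice_loss(union_mask, gt)
          if (config$stability_n >= 2L) {
            row$stability <- stability_score(
              segmenter, input$image, boxes[[1]],
              magnitude = config$stability_magnitude,
              n = config$stability_n, seed = image_seed)
          }
        }
        out_rows[[prompt]] <- row
        out$boxes[[prompt]] <- boxes
        out$traces[[prompt]] <- traces
        out$masks[[prompt]] <- union_mask
        out$scores[[prompt]] <- scores
        "ok"
      }
    }, error = function(e) paste0("error: ", conditionMessage(e)))
    out$status[[prompt]] <- status
  }
  out$rows <- do.call(rbind, out_rows)
  rownames(out$rows) <- NULL
  if (!is.null(config$output_dir)) write_single_artifacts(config, out)
  out
}

write_single_artifacts <- function(config, report) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  backend <- if (is.null(config$segmenter)) "oracle" else config$segmenter$id
  for (prompt in names(report$boxes)) {
    stem <- file.path(config$output_dir,
                      sprintf("%s__%s__%s__%s", report$image_id,
                              slugify(prompt), backend, config$pathway))
    if (length(report$boxes[[prompt]]) > 0L) {
      write_boxes_json(report$boxes[[prompt]], paste0(stem, "__boxes.json"))
    }
    if (!is.null(report$masks[[prompt]])) {
      write_mask_png(report$masks[[prompt]], paste0(stem, "__mask.png"))
    }
    if (!is.null(report$traces[[prompt]])) {
      for (i in seq_along(report$traces[[prompt]])) {
        write_trace_jsonl(report$traces[[prompt]][[i]],
                          sprintf("%s__trace%d.jsonl", stem, i))
      }
    }
  }
  if (!is.null(report$rows)) {
    utils::write.csv(report$rows,
                     file.path(config$output_dir,
                               sprintf("%s__metrics.csv", report$image_id)),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the pipeline over a batch of images
#'
#' Applies [run_single()] to every input with a skip-and-record failure
#' policy (one bad image does not abort the batch), then aggregates:
#' per-image metric rows, per-(prompt, backend) mean/median summaries, a
#' fixed-edge histogram of the binarized-predicted IoU scores, and a
#' reliability table built from the segmenters' quality scores against the
#' IoU-cutoff outcomes. With `output_dir` set, writes `metrics.csv`,
#' `summary.csv`, `calibration.csv`, `histogram__<backend>.png`,
#' `reliability.png` and a `manifest.yaml` tracing every artifact to
#' (image, prompt, backend, pathway, seed).
#'
#' @param config A [run_config()].
#' @return List with `metrics` (all rows), `summary`, `calibration` (a
#'   [calibration_table()] or `NULL`), `histogram` (counts per fixed bin),
#'   `failures` (named character vector), `reports` (per-image).
#' @export
run_batch <- function(config) {
  items <- config_inputs(config)
  reports <- list()
  failures <- character(0)
  for (item in items) {
    id <- if (!is.null(item$id)) item$id else item$image_id
    rep <- tryCatch(run_single(config, item), error = function(e) e)
    if (inherits(rep, "error")) {
      failures[[id]] <- conditionMessage(rep)
    } else {
      reports[[id]] <- rep
    }
  }
  if (length(reports) == 0L) {
    stop("all images failed: ",
         paste(sprintf("%s (%s)", names(failures), failures),
               collapse = "; "))
  }
  metrics <- do.call(rbind, c(lapply(reports, `[[`, "rows"),
                              make.row.names = FALSE))
  summary_df <- aggregate_metrics(metrics)
  # histogram of BPIoU with fixed, recorded edges
  edges <- seq(0, 1, by = 0.05)
  vals <- metrics$bpiou[!is.na(metrics$bpiou)]
  hist_counts <- if (length(vals) > 0L) {
    as.integer(table(cut(vals, breaks = edges, include.lowest = TRUE)))
  } else {
    integer(length(edges) - 1L)
  }
  # calibration from quality scores vs IoU-cutoff outcomes
  calib <- NULL
  all_scores <- unlist(lapply(reports, function(r) {
    vapply(names(r$scores), function(p) max(r$scores[[p]]), numeric(1))
  }))
  all_ious <- unlist(lapply(reports, function(r) {
    r$rows$iou[match(names(r$scores), r$rows$prompt)]
  }))
  ok <- !is.na(all_ious) & !is.na(all_scores)
  if (sum(ok) >= 2L) {
    probs <- suppressWarnings(scores_to_probabilities(all_scores[ok]))
    outcomes <- as.integer(all_ious[ok] >= config$iou_cutoff)
    calib <- calibration_table(probs, outcomes, n_bins = config$n_bins)
  }
  out <- list(metrics = metrics, summary = summary_df, calibration = calib,
              histogram = list(edges = edges, counts = hist_counts),
              failures = failures, reports = reports)
  if (!is.null(config$output_dir)) write_batch_artifacts(config, out)
  out
}

aggregate_metrics <- function(metrics) {
  key <- interaction(metrics$prompt, metrics$backend_id, drop = TRUE)
  rows <- lapply(split(metrics, key), function(df) {
    data.frame(prompt = df$prompt[1], backend_id = df$backend_id[1],
               n = nrow(df),
               mean_iou = mean(df$iou, na.rm = TRUE),
               median_iou = stats::median(df$iou, na.rm = TRUE),
               mean_bpiou = mean(df$bpiou, na.rm = TRUE),
               median_bpiou = stats::median(df$bpiou, na.rm = TRUE),
               mean_dice_loss = mean(df$dice_loss, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$prompt, out$backend_id), , drop = FALSE]
}

write_batch_artifacts <- function(config, batch) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(batch$metrics, file.path(config$output_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(batch$summary, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(batch$calibration)) {
    utils::write.csv(as.data.frame(batch$calibration),
                     file.path(config$output_dir, "calibration.csv"),
                     row.names = FALSE)
    plot_reliability(batch$calibration,
                     file.path(config$output_dir, "reliability.png"))
  }
  for (backend in unique(batch$metrics$backend_id)) {
    vals <- batch$metrics$bpiou[batch$metrics$backend_id == backend]
    vals <- vals[!is.na(vals)]
    path <- file.path(config$output_dir,
                      sprintf("histogram__%s.png", backend))
    grDevices::png(path, width = 600, height = 450)
    graphics::hist(vals, breaks = batch$histogram$edges,
                   include.lowest = TRUE, col = "steelblue",
                   xlab = "Binarized-predicted IoU", main = backend)
    grDevices::dev.off()
  }
  manifest <- list(
    seed = config$seed, pathway = config$pathway,
    prompts = vapply(config$prompts, build_prompt, character(1)),
    images = names(batch$reports),
    failures = as.list(batch$failures),
    histogram_edges = batch$histogram$edges,
    stage_order = c("preprocess", "prompt", "detect", "refine", "segment",
                    "select", "evaluate", "report"))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(NULL)
}
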