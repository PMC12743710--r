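# A scriptable stub backend used to test thresholding/sorting independently
# of the oracle.
stub_detector <- function(rows) {
  structure(list(id = "stub", rows = rows),
            class = c("stub_detector", "detector"))
}

backend_detect.stub_detector <- function(detector, image, prompt) {
  detector$rows
}
registerS3method("backend_detect", "stub_detector", backend_detect.stub_detector)

stub_rows <- function(confs) {
  n <- length(confs)
  if (n == 0L) {
    return(data.frame(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      confidence = numeric(), phrase = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(x_min = seq_len(n) * 10, y_min = 5, x_max = seq_len(n) * 10 + 5,
             y_max = 15, confidence = confs,
             phrase = paste0("p", seq_len(n)), stringsAsFactors = FALSE)
}

test_that("confidence thresholding keeps only detections at or above cutoff", {
  img <- matrix(0, 32, 32)
  boxes <- detect(stub_detector(stub_rows(c(0.30, 0.20))), img, "lung")
  expect_length(boxes, 1)
  expect_equal(boxes[[1]]$confidence, 0.30)
  # empty backend output is a legitimate empty result
  expect_length(detect(stub_detector(stub_rows(numeric(0))), img, "lung"), 0)
})

test_that("detections come back sorted by descending confidence", {
  img <- matrix(0, 32, 32)
  boxes <- detect(stub_detector(stub_rows(c(0.4, 0.9, 0.6))), img, "lung",
                  detector_config(box_threshold = 0.3))
  expect_equal(vapply(boxes, `[[`, numeric(1), "confidence"),
               c(0.9, 0.6, 0.4))
})

test_that("raising the box threshold only removes detections", {
  img <- matrix(0, 32, 32)
  confs <- c(0.15, 0.35, 0.55, 0.75, 0.95)
  det <- stub_detector(stub_rows(confs))
  prev <- length(confs)
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    boxes <- detect(det, img, "lung", detector_config(box_threshold = thr))
    survivors <- vapply(boxes, `[[`, numeric(1), "confidence")
    expect_true(all(survivors >= thr))
    expect_identical(sort(survivors, decreasing = TRUE),
                     sort(confs[confs >= thr], decreasing = TRUE))
    expect_lte(length(boxes), prev)
    prev <- length(boxes)
  }
})

test_that("detect validates its inputs", {
  det <- stub_detector(stub_rows(0.5))
  expect_error(detect(det, matrix(0, 32, 32), ""), "prompt")
})

test_that("map_box scales corners with coverage-preserving rounding", {
  b <- bounding_box(10, 10, 20, 20)
  out <- map_box(b, c(1, 1))
  expect_equal(unlist(out[1:4]), unlist(b[1:4]))
  doubled <- map_box(b, c(2, 2))
  expect_equal(unlist(doubled[1:4]),
               c(x_min = 20, y_min = 20, x_max = 40, y_max = 40))
  # floor/ceil rule on a fractional downscale
  shrunk <- map_box(bounding_box(3, 3, 5, 5), c(1 / 3, 1 / 3))
  expect_equal(unlist(shrunk[1:4]), c(x_min = 1, y_min = 1, x_max = 2,
                                      y_max = 2))
  expect_error(map_box(b, c(0, 1)), "positive")
})

test_that("integer upscale then downscale never shrinks coverage", {
  set.seed(9)
  for (i in 1:20) {
    x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
    b <- bounding_box(x0, y0, x0 + sample(1:30, 1), y0 + sample(1:30, 1))
    k <- sample(2:4, 1)
    up <- map_box(b, c(k, k))
    back <- map_box(up, c(1 / k, 1 / k))
    expect_lte(back$x_min, b$x_min)
    expect_lte(back$y_min, b$y_min)
    expect_gte(back$x_max, b$x_max)
    expect_gte(back$y_max, b$y_max)
    expect_lte(back$x_max - b$x_max, 1)
  }
})

test_that("binary-pathway detection matches the binarized dark extent", {
  ph <- generate_phantom(small_phantom_spec(64))
  det <- oracle_detector(ph$masks)
  cfg <- preprocess_config(target_size = NULL)
  raw_boxes <- detect(det, ph$image, "right lung")
  bin_boxes <- detect_on_binary(det, ph$image, "right lung",
                                preprocess = cfg)
  expect_length(bin_boxes, 1)
  expect_equal(bin_boxes[[1]]$source_space, "binary")
  # noiseless phantom: lobe/background straddle the threshold, so the box
  # equals the raw detection and the brute-force extent of the dark region
  expect_equal(unlist(bin_boxes[[1]][1:4]), unlist(raw_boxes[[1]][1:4]))
  dark <- as.matrix(ph$image) < binarize(ph$image, cfg)$threshold
  dark_right <- dark & ph$masks$right
  ref <- tight_box(dark_right)
  expect_equal(unlist(bin_boxes[[1]][1:4]), unlist(ref[1:4]))
})

test_that("binary pathway maps boxes back through the resize scale", {
  ph <- generate_phantom(small_phantom_spec(64))
  # image-driven detector sees the 32x32 rendering; boxes must come back
  # to 64x64 coordinates
  boxes <- detect_on_binary(intensity_detector(), ph$image, "lung",
                            preprocess = preprocess_config(
                              target_size = c(32, 32)))
  expect_length(boxes, 2)
  for (b in boxes) {
    side <- prompt_side(b$phrase)
    ref <- tight_box(ph$masks[[side]])
    expect_lte(abs(b$x_min - ref$x_min), 2)
    expect_lte(abs(b$y_min - ref$y_min), 2)
    expect_lte(abs(b$x_max - ref$x_max), 2)
    expect_lte(abs(b$y_max - ref$y_max), 2)
  }
  # a featureless image grounds nothing
  flat <- gray_image(matrix(180, 64, 64))
  expect_length(
    suppressWarnings(detect_on_binary(intensity_detector(), flat, "lung",
                                      preprocess = preprocess_config(
                                        target_size = NULL))), 0)
})

test_that("boxes serialize to JSON and back", {
  boxes <- list(bounding_box(1, 2, 3, 4, confidence = 0.5,
                             phrase = "right lung"),
                bounding_box(5, 6, 9, 8, confidence = 0.25,
                             phrase = "left lung", source_space = "binary"))
  path <- withr::local_tempfile(fileext = ".json")
  write_boxes_json(boxes, path)
  back <- read_boxes_json(path)
  expect_equal(back, boxes)
})
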