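test_that("noiseless phantom is an exact two-intensity construction", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  inside <- ph$masks$right | ph$masks$left
  expect_true(all(ph$image[inside] == 60))
  expect_true(all(ph$image[!inside] == 180))
  expect_false(any(ph$masks$right & ph$masks$left))
})

test_that("identical spec and seed reproduce the phantom bit-identically", {
  spec <- phantom_spec(noise_sd = 6, seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(as.vector(a$image), as.vector(b$image))
  expect_identical(a$masks, b$masks)
  c <- generate_phantom(phantom_spec(noise_sd = 6, seed = 12))
  expect_false(identical(as.vector(a$image), as.vector(c$image)))
})

test_that("mask pixel counts match brute-force point-in-ellipse tests", {
  spec <- phantom_spec(
    height = 224, width = 224,
    lobes = list(right = list(center = c(60, 110), semi = c(40, 70),
                              rotation = 0, intensity = 60),
                 left = list(center = c(165, 110), semi = c(30, 55),
                             rotation = 0.2, intensity = 70)),
    noise_sd = 0)
  ph <- generate_phantom(spec)
  for (side in c("right", "left")) {
    lb <- spec$lobes[[side]]
    expect_identical(sum(ph$masks[[side]]),
                     brute_ellipse_count(224, 224, lb$center, lb$semi,
                                         lb$rotation))
  }
})

test_that("mask extents match brute-force tight boxes", {
  ph <- generate_phantom(small_phantom_spec(64))
  for (side in c("right", "left")) {
    m <- ph$masks[[side]]
    idx <- which(m, arr.ind = TRUE)
    b <- tight_box(m)
    expect_equal(c(b$x_min, b$x_max), c(min(idx[, 2]) - 1, max(idx[, 2])))
    expect_equal(c(b$y_min, b$y_max), c(min(idx[, 1]) - 1, max(idx[, 1])))
  }
})

test_that("invalid phantom specs are rejected", {
  # lobe brighter than background
  expect_error(phantom_spec(lobes = list(
    right = list(center = c(60, 110), semi = c(20, 30), rotation = 0,
                 intensity = 200),
    left = list(center = c(160, 110), semi = c(20, 30), rotation = 0,
                intensity = 60))), "below the background")
  # ellipse out of bounds
  expect_error(phantom_spec(lobes = list(
    right = list(center = c(10, 110), semi = c(30, 30), rotation = 0,
                 intensity = 60),
    left = list(center = c(160, 110), semi = c(20, 30), rotation = 0,
                intensity = 60))), "outside the image")
  # overlapping lobes -> disjointness violated at generation time
  spec <- phantom_spec(lobes = list(
    right = list(center = c(100, 110), semi = c(40, 40), rotation = 0,
                 intensity = 60),
    left = list(center = c(130, 110), semi = c(40, 40), rotation = 0,
                intensity = 60)))
  expect_error(generate_phantom(spec), "disjoint")
})

test_that("phantom round-trips through PNG and YAML files", {
  ph <- generate_phantom(small_phantom_spec(48, noise_sd = 3))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir, id = "p1")
  img <- read_image_png(paths[["image"]])
  expect_equal(as.vector(img), as.vector(ph$image))
  expect_identical(read_mask_png(paths[["mask_right"]]), ph$masks$right)
  spec2 <- read_phantom_spec(paths[["spec"]])
  ph2 <- generate_phantom(spec2)
  expect_equal(as.vector(ph2$image), as.vector(ph$image))
})

test_that("12-bit phantoms survive the 16-bit image container", {
  spec <- small_phantom_spec(32)
  spec$bit_depth <- 12L
  spec$background_intensity <- 3000
  spec$lobes$right$intensity <- 900
  spec$lobes$left$intensity <- 900
  spec$noise_sd <- 20
  ph <- generate_phantom(spec)
  expect_gt(max(ph$image), 255)
  dir <- withr::local_tempdir()
  expect_equal(image_file_ext(ph$image), ".tif")
  write_image_png(ph$image, file.path(dir, "p.tif"))
  back <- read_image_png(file.path(dir, "p.tif"), bit_depth = 12L)
  expect_equal(as.vector(back), as.vector(ph$image))
})

test_that("oracle detector returns exact tight boxes at zero jitter", {
  ph <- generate_phantom(small_phantom_spec(64))
  det <- oracle_detector(ph$masks)
  boxes <- detect(det, ph$image, "right lung")
  expect_length(boxes, 1)
  ref <- tight_box(ph$masks$right)
  expect_equal(boxes[[1]][c("x_min", "y_min", "x_max", "y_max")],
               ref[c("x_min", "y_min", "x_max", "y_max")])
  expect_equal(boxes[[1]]$confidence, 1.0)
  expect_match(boxes[[1]]$phrase, "right")
})

test_that("side-less anatomical prompts detect both lobes", {
  ph <- generate_phantom(small_phantom_spec(64))
  det <- oracle_detector(ph$masks)
  expect_length(detect(det, ph$image, "lung"), 2)
  expect_length(detect(det, ph$image, "lobe"), 2)
  # non-anatomical prompt grounds nothing, without error
  expect_length(detect(det, ph$image, "rib cage"), 0)
})

test_that("jittered oracle detections are seeded and reproducible", {
  # right lobe placed with > 10 px margins so jitter never hits the border
  spec <- phantom_spec(
    height = 96, width = 96,
    lobes = list(right = list(center = c(38, 48), semi = c(16, 22),
                              rotation = 0, intensity = 60),
                 left = list(center = c(74, 48), semi = c(14, 20),
                             rotation = 0, intensity = 60)),
    noise_sd = 0)
  ph <- generate_phantom(spec)
  det <- oracle_detector(ph$masks, jitter = 10, seed = 5)
  b1 <- detect(det, ph$image, "right lung",
               detector_config(box_threshold = 0))[[1]]
  b2 <- detect(det, ph$image, "right lung",
               detector_config(box_threshold = 0))[[1]]
  expect_identical(b1, b2)
  ref <- tight_box(ph$masks$right)
  dx <- b1$x_min - ref$x_min
  dy <- b1$y_min - ref$y_min
  expect_lte(max(abs(c(dx, dy))), 10)
  # box is a pure translation and confidence decays with its magnitude
  expect_equal(b1$x_max - ref$x_max, dx)
  expect_equal(b1$y_max - ref$y_max, dy)
  expect_equal(b1$confidence, exp(-sqrt(dx^2 + dy^2) / 10))
})

test_that("oracle segmenter reproduces the lobe from its tight box", {
  ph <- generate_phantom(small_phantom_spec(64))
  seg <- oracle_segmenter()
  res <- segment_box(seg, ph$image, tight_box(ph$masks$right))
  expect_identical(select_candidate(res), ph$masks$right)
  expect_equal(result_score(res), 1.0)
})

test_that("oracle segmenter score is the brute-force captured fraction", {
  ph <- generate_phantom(small_phantom_spec(64))
  seg <- oracle_segmenter()
  full <- tight_box(ph$masks$right)
  half <- bounding_box(full$x_min, full$y_min,
                       floor((full$x_min + full$x_max) / 2), full$y_max)
  res <- segment_box(seg, ph$image, half)
  captured <- sum(ph$masks$right & box_mask(half, ph$image))
  expect_lt(result_score(res), 1)
  expect_equal(result_score(res), captured / sum(ph$masks$right))
  expect_equal(sum(select_candidate(res)), captured)
})

test_that("oracle segmenter returns an empty zero-score result in background", {
  ph <- generate_phantom(small_phantom_spec(64))
  seg <- oracle_segmenter()
  bg <- bounding_box(0, 0, 5, 5)   # corner: pure background
  res <- segment_box(seg, ph$image, bg)
  expect_equal(result_score(res), 0)
  expect_equal(sum(select_candidate(res)), 0)
})

test_that("oracle segmenter objective peaks at boxes containing the lobe", {
  # exhaustive translation sweep on a small phantom: the captured-fraction
  # score attains its maximum exactly when the box holds the whole lobe
  ph <- generate_phantom(small_phantom_spec(32))
  seg <- oracle_segmenter()
  ref <- tight_box(ph$masks$right)
  w <- ref$x_max - ref$x_min; h <- ref$y_max - ref$y_min
  score_at <- function(x0, y0) {
    result_score(segment_box(seg, ph$image, bounding_box(x0, y0, x0 + w,
                                                         y0 + h)))
  }
  vals <- outer(0:(32 - w), 0:(32 - h), Vectorize(score_at))
  expect_equal(max(vals), 1)
  expect_equal(vals[ref$x_min + 1, ref$y_min + 1], 1)
})
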