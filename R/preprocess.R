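#' Preprocessing configuration
#'
#' Controls the image preparation chain applied before detection: resize to a
#' working resolution, then threshold to a binary image. The defaults mirror
#' common practice for feeding radiographs to transformer detectors: a
#' 224 x 224 working grid, Otsu's automatic threshold with a fixed fallback
#' of 127, and foreground rendered at intensity 196.
#'
#' @param target_size Integer `(height, width)` of the working resolution,
#'   or `NULL` to keep the native resolution. Default `c(224, 224)`.
#' @param threshold_mode `"otsu"` (automatic, default) or `"fixed"`.
#' @param fixed_threshold Intensity used in fixed mode and as the fallback
#'   when Otsu degenerates on a constant image. Default 127.
#' @param binar_high_value Intensity that `TRUE` mask pixels receive when the
#'   binary image is rendered for a detector. Default 196.
#' @param interpolation `"area"` (block averaging, default — appropriate for
#'   downscaling) or `"nearest"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = c(224L, 224L),
                              threshold_mode = c("otsu", "fixed"),
                              fixed_threshold = 127,
                              binar_high_value = 196,
                              interpolation = c("area", "nearest")) {
  threshold_mode <- match.arg(threshold_mode)
  interpolation <- match.arg(interpolation)
  if (!is.null(target_size)) {
    if (length(target_size) != 2L || any(target_size < 1)) {
      stop("`target_size` must be two positive integers (height, width)")
    }
    target_size <- as.integer(target_size)
  }
  if (fixed_threshold < 0) stop("`fixed_threshold` must be non-negative")
  if (binar_high_value <= 0) stop("`binar_high_value` must be positive")
  structure(list(target_size = target_size, threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 binar_high_value = binar_high_value,
                 interpolation = interpolation),
            class = "preprocess_config")
}

#' Collapse a multi-channel image to grayscale
#'
#' 3-channel input is combined with the Rec.601 luminance weights
#' `0.299 R + 0.587 G + 0.114 B`; single-channel input passes through
#' unchanged.
#'
#' @param image A matrix (already grayscale) or an `H x W x C` array with
#'   `C` of 1 or 3.
#' @return A numeric matrix of the same height/width.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L) stop("expected a matrix or an H x W x C array")
  channel <- function(k) matrix(image[, , k], d[1], d[2])
  if (d[3] == 1L) return(channel(1))
  if (d[3] == 3L) {
    return(0.299 * channel(1) + 0.587 * channel(2) + 0.114 * channel(3))
  }
  stop(sprintf("unsupported channel count: %d (expected 1 or 3)", d[3]))
}

# Axis weights for exact area-average resampling: W[i_out, i_in] is the
# overlap of output cell i_out with input cell i_in, in units of
# 1/n_out (so every entry is an exact integer and each row sums to n_in).
# The caller divides by n_in once after the separable product, keeping
# constant images exactly constant.
area_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    # output cell i covers [(i-1) n_in, i n_in) on the n_out-scaled axis;
    # input cell j covers [(j-1) n_out, j n_out)
    j0 <- floor((i - 1) * n_in / n_out) + 1
    j1 <- min(ceiling(i * n_in / n_out), n_in)
    for (j in j0:j1) {
      ov <- min(i * n_in, j * n_out) - max((i - 1) * n_in, (j - 1) * n_out)
      if (ov > 0) w[i, j] <- ov
    }
  }
  w
}

#' Resize an image to the working resolution
#'
#' Returns both the resized image and the per-axis scale factors
#' `(sy, sx) = target size / original size`, which [map_box()] uses to move
#' boxes between the two coordinate spaces exactly.
#'
#' @param image Matrix or `gray_image`.
#' @param config A [preprocess_config()]; its `target_size` and
#'   `interpolation` are used. `target_size = NULL` returns the input with
#'   scale `(1, 1)`.
#' @return List with elements `image` (resized) and `scale` (`c(sy, sx)`).
#' @export
resize_image <- function(image, config = preprocess_config()) {
  h_in <- nrow(image); w_in <- ncol(image)
  if (h_in < 1L || w_in < 1L) stop("cannot resize an empty image")
  if (is.null(config$target_size)) {
    return(list(image = image, scale = c(1, 1)))
  }
  h_out <- config$target_size[1]; w_out <- config$target_size[2]
  m <- as_plain_matrix(image)
  if (h_out == h_in && w_out == w_in) {
    out <- m
  } else if (config$interpolation == "nearest") {
    rows <- pmin(h_in, floor((seq_len(h_out) - 0.5) * h_in / h_out) + 1)
    cols <- pmin(w_in, floor((seq_len(w_out) - 0.5) * w_in / w_out) + 1)
    out <- m[rows, cols, drop = FALSE]
  } else {
    out <- (area_weights(h_in, h_out) %*% m %*%
              t(area_weights(w_in, w_out))) / (h_in * w_in)
  }
  list(image = gray_image(pmin(pmax(out, 0), image_max_value(image)),
                          bit_depth = image_bit_depth(image)),
       scale = c(h_out / h_in, w_out / w_in))
}

#' Otsu's threshold over an integer histogram
#'
#' Selects the threshold `T` maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split `{I < T}` vs `{I >= T}`, evaluated
#' for every candidate `T`; ties are broken towards the smallest `T`. The
#' `>= T` convention matches [binarize()].
#'
#' @param values Numeric vector or matrix of integer intensities.
#' @param max_value Largest representable intensity (defines the candidate
#'   grid `1 .. max_value`).
#' @return The optimal threshold, or `NA` if the input is constant (no split
#'   separates two non-empty classes).
#' @export
otsu_threshold <- function(values, max_value = 255L) {
  v <- as.vector(values)
  counts <- tabulate(as.integer(round(v)) + 1L, nbins = max_value + 1L)
  n <- sum(counts)
  levels <- 0:max_value
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * levels)
  # split at T: class0 = levels < T (first T bins), class1 = rest
  t_cand <- seq_len(max_value)              # T in 1 .. max_value
  n0 <- cum_n[t_cand]
  n1 <- n - n0
  ok <- n0 > 0 & n1 > 0
  if (!any(ok)) return(NA_real_)
  s0 <- cum_s[t_cand]
  mu0 <- s0 / n0
  mu1 <- (cum_s[max_value + 1L] - s0) / n1
  bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  bcv[!ok] <- -Inf
  as.numeric(t_cand[which.max(bcv)])
}

#' Threshold an image to a binary mask
#'
#' A pixel is foreground when `I(x, y) >= T`. In `"otsu"` mode `T` is chosen
#' by [otsu_threshold()] and the configured fixed value is ignored; a
#' constant image (where no automatic split exists) falls back to the fixed
#' threshold with a warning. In `"fixed"` mode the configured value is used
#' directly.
#'
#' @param image Single-channel matrix or `gray_image`.
#' @param config A [preprocess_config()].
#' @return List with `mask` (logical matrix) and `threshold` (the `T`
#'   actually used).
#' @export
binarize <- function(image, config = preprocess_config()) {
  if (!is.matrix(image)) stop("binarize expects a single-channel image")
  if (config$threshold_mode == "otsu") {
    t_used <- otsu_threshold(image, max_value = image_max_value(image))
    if (is.na(t_used)) {
      warning("constant image: Otsu threshold undefined, using fixed fallback")
      t_used <- config$fixed_threshold
    }
  } else {
    t_used <- config$fixed_threshold
  }
  list(mask = as_plain_matrix(image) >= t_used, threshold = t_used)
}

#' Render a binary mask as a detector-facing grayscale image
#'
#' `TRUE` pixels get the configured high intensity (default 196), `FALSE`
#' pixels 0. This rendered image is what a detector receives on the
#' binary-image pathway.
#'
#' @param mask Logical matrix.
#' @param config A [preprocess_config()]; `binar_high_value` is used.
#' @return A [gray_image()] (8-bit).
#' @export
render_binary <- function(mask, config = preprocess_config()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  gray_image(ifelse(mask, config$binar_high_value, 0), bit_depth = 8L)
}
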