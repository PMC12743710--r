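#' Axis-aligned bounding box
#'
#' Boxes use 0-based half-open pixel intervals `[x_min, x_max) x
#' [y_min, y_max)`, so `area = (x_max - x_min) * (y_max - y_min)` exactly and
#' a box covering the full image has `x_max = width`, `y_max = height`.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates in pixels;
#'   `x_min < x_max`, `y_min < y_max`.
#' @param confidence Detection confidence in `[0, 1]` (`NA` when not scored).
#' @param phrase Text phrase the detection was matched to.
#' @param source_space One of `"original"`, `"resized"`, `"binary"` — the
#'   coordinate space the box lives in.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max,
                         confidence = NA_real_, phrase = "",
                         source_space = "original") {
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  }
  if (!is.na(confidence) && (confidence < 0 || confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  source_space <- match.arg(source_space, c("original", "resized", "binary"))
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 confidence = confidence, phrase = phrase,
                 source_space = source_space),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<box [%g, %g) x [%g, %g) conf=%s phrase=\"%s\" space=%s>\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              ifelse(is.na(x$confidence), "NA", format(x$confidence)),
              x$phrase, x$source_space))
  invisible(x)
}

#' Box area in pixels
#' @param box A [bounding_box()].
#' @return Numeric area.
#' @export
box_area <- function(box) (box$x_max - box$x_min) * (box$y_max - box$y_min)

#' Tight bounding box of a mask
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param ... Passed to [bounding_box()] (confidence, phrase, source_space).
#' @return The smallest box containing all `TRUE` pixels.
#' @export
tight_box <- function(mask, ...) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the tight box of an empty mask")
  bounding_box(x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
               x_max = max(idx[, 2]), y_max = max(idx[, 1]), ...)
}

#' Clip a box to image bounds
#'
#' @param box A [bounding_box()].
#' @param image Matrix whose extent defines the clip region.
#' @return The clipped box, or `NULL` if nothing remains.
#' @export
clip_box <- function(box, image) {
  x_min <- max(0, box$x_min); y_min <- max(0, box$y_min)
  x_max <- min(ncol(image), box$x_max); y_max <- min(nrow(image), box$y_max)
  if (x_min >= x_max || y_min >= y_max) return(NULL)
  bounding_box(x_min, y_min, x_max, y_max,
               confidence = box$confidence, phrase = box$phrase,
               source_space = box$source_space)
}

#' Translate (and optionally scale) a box
#'
#' Scaling is about the box centre; the result is rounded outward to integer
#' pixel coordinates.
#'
#' @param box A [bounding_box()].
#' @param dx,dy Translation in pixels.
#' @param scale Multiplicative size factor (1 = translation only).
#' @return A new `bounding_box`.
#' @export
shift_box <- function(box, dx = 0, dy = 0, scale = 1) {
  cx <- (box$x_min + box$x_max) / 2
  cy <- (box$y_min + box$y_max) / 2
  hw <- (box$x_max - box$x_min) / 2 * scale
  hh <- (box$y_max - box$y_min) / 2 * scale
  bounding_box(floor(cx - hw) + dx, floor(cy - hh) + dy,
               ceiling(cx + hw) + dx, ceiling(cy + hh) + dy,
               confidence = box$confidence, phrase = box$phrase,
               source_space = box$source_space)
}

#' Map a box between coordinate spaces
#'
#' Corner coordinates are multiplied by the per-axis scale factors, then
#' rounded coverage-preserving: floor for the minima, ceiling for the maxima.
#' A box detected on a downscaled image therefore never shrinks below its
#' true extent when mapped back to the original resolution.
#'
#' @param box A [bounding_box()].
#' @param scale Numeric length-2 `(sy, sx)` scale factors (target / source
#'   size per axis); must be positive.
#' @param target_space New `source_space` tag for the mapped box.
#' @return The mapped `bounding_box`.
#' @export
map_box <- function(box, scale, target_space = box$source_space) {
  if (length(scale) != 2L || any(!is.finite(scale)) || any(scale <= 0)) {
    stop("`scale` must be two positive factors (sy, sx)")
  }
  sy <- scale[[1]]; sx <- scale[[2]]
  bounding_box(floor(box$x_min * sx), floor(box$y_min * sy),
               ceiling(box$x_max * sx), ceiling(box$y_max * sy),
               confidence = box$confidence, phrase = box$phrase,
               source_space = target_space)
}

#' Convert a box to the logical mask it covers
#' @param box A [bounding_box()] (already within bounds or it is clipped).
#' @param image Matrix defining the extent.
#' @return Logical matrix, `TRUE` inside the box.
#' @export
box_mask <- function(box, image) {
  m <- matrix(FALSE, nrow(image), ncol(image))
  b <- clip_box(box, image)
  if (is.null(b)) return(m)
  m[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- TRUE
  m
}

box_to_row <- function(box) {
  data.frame(x_min = box$x_min, y_min = box$y_min,
             x_max = box$x_max, y_max = box$y_max,
             confidence = box$confidence, phrase = box$phrase,
             source_space = box$source_space, stringsAsFactors = FALSE)
}

#' Serialize boxes to a JSON file
#'
#' One JSON array of records `{x_min, y_min, x_max, y_max, confidence,
#' phrase, source_space}`.
#'
#' @param boxes List of [bounding_box()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_boxes_json <- function(boxes, path) {
  df <- do.call(rbind, lapply(boxes, box_to_row))
  if (is.null(df)) df <- data.frame()
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read boxes from a JSON file written by [write_boxes_json()]
#' @param path JSON file.
#' @return List of `bounding_box` objects.
#' @export
read_boxes_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0L || nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    bounding_box(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i],
                 confidence = if (is.null(df$confidence[i]) ||
                                  is.na(df$confidence[i])) NA_real_
                              else df$confidence[i],
                 phrase = df$phrase[i], source_space = df$source_space[i])
  })
}
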