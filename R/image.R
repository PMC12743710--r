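#' Grayscale image container
#'
#' Images are stored as plain numeric matrices in row-major raster layout:
#' `img[y + 1, x + 1]` is the pixel at 0-based raster coordinates `(x, y)`,
#' with `x` running left-to-right and `y` top-to-bottom. Intensities are
#' integers on the native scale of the stated bit depth (`0 .. 2^depth - 1`),
#' matching how radiographs are stored (8-bit screen renderings or 12-bit
#' computed-radiography pixel arrays). Bit depth and optional pixel spacing
#' (mm per pixel) travel as attributes.
#'
#' @param data Numeric matrix of intensities (rows = height, cols = width).
#' @param bit_depth Integer bit depth; intensities must fit in
#'   `[0, 2^bit_depth - 1]`. Default 8.
#' @param pixel_spacing Optional numeric length-2 `(row, col)` spacing in mm.
#' @return The matrix with class `gray_image` and metadata attributes.
#' @export
gray_image <- function(data, bit_depth = 8L, pixel_spacing = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) stop("image must be nonempty")
  maxv <- 2^bit_depth - 1
  if (any(data < 0 | data > maxv)) {
    stop(sprintf("intensities must lie in [0, %d] for bit depth %d",
                 maxv, bit_depth))
  }
  structure(data,
            bit_depth = as.integer(bit_depth),
            pixel_spacing = pixel_spacing,
            class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%g, %g]>\n",
              nrow(x), ncol(x), image_bit_depth(x), min(x), max(x)))
  invisible(x)
}

#' Bit depth of an image
#'
#' Plain matrices without metadata are treated as 8-bit.
#' @param image Matrix or `gray_image`.
#' @return Integer bit depth.
#' @export
image_bit_depth <- function(image) {
  bd <- attr(image, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

#' Maximum representable intensity of an image
#' @param image Matrix or `gray_image`.
#' @return `2^bit_depth - 1`.
#' @export
image_max_value <- function(image) 2L^image_bit_depth(image) - 1L

as_plain_matrix <- function(image) {
  attributes(image) <- list(dim = dim(image))
  image
}

#' Read a grayscale image file
#'
#' PNG holds 8-bit renderings; deeper images (12-bit computed-radiography
#' pixel arrays) use the 16-bit TIFF container, chosen by file extension.
#' Multi-channel files are collapsed to luminance via [to_grayscale()].
#' For depths between 8 and 16 the stored 16-bit samples are
#' right-justified back to the declared depth.
#'
#' @param path PNG or TIFF file path.
#' @param bit_depth Declared bit depth of the stored intensities (8, 12 or
#'   16). Default 8.
#' @return A [gray_image()].
#' @export
read_image_png <- function(path, bit_depth = 8L) {
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  arr <- if (is_tiff) tiff::readTIFF(path) else png::readPNG(path)
  container_bits <- if (is_tiff) 16L else 8L
  scale <- 2^container_bits - 1
  if (length(dim(arr)) == 3L) {
    img <- if (dim(arr)[3] >= 3L) {
      round(to_grayscale(arr[, , 1:3]) * scale)
    } else {
      round(arr[, , 1] * scale)
    }
  } else {
    img <- round(arr * scale)
  }
  # 12-bit samples occupy the high bits of a 16-bit container
  if (bit_depth < container_bits) {
    img <- img %/% 2^(container_bits - bit_depth)
  }
  gray_image(img, bit_depth = bit_depth)
}

#' Write a grayscale image file
#'
#' Images up to 8-bit are written as PNG; deeper images as 16-bit TIFF
#' with samples left-justified (the usual convention for storing 12-bit
#' radiograph data in a 16-bit container). The extension of `path` should
#' match (`.png` vs `.tif`); see [image_file_ext()].
#'
#' @param image Matrix or `gray_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  bd <- image_bit_depth(image)
  if (bd > 8L) {
    vals <- as_plain_matrix(image) * 2^(16L - bd)
    tiff::writeTIFF(vals / (2^16 - 1), path, bits.per.sample = 16L)
  } else {
    png::writePNG(as_plain_matrix(image) / (2^8 - 1), target = path)
  }
  invisible(path)
}

#' File extension matching an image's bit depth
#' @param image Matrix or `gray_image`.
#' @return `".png"` for depths up to 8, `".tif"` otherwise.
#' @export
image_file_ext <- function(image) {
  if (image_bit_depth(image) > 8L) ".tif" else ".png"
}

#' Read a binary mask from PNG
#'
#' Any strictly positive stored value is taken as foreground (masks are
#' conventionally written 0/255).
#'
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0
}

#' Write a binary mask as 0/255 PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
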