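#' Synthetic chest-phantom specification
#'
#' The phantom emulates the geometry a frontal chest radiograph presents to
#' a detection/segmentation pipeline: two roughly elliptical radiolucent
#' (dark) lung fields of unequal size and position on a brighter noisy
#' thoracic background. Under the default radiographic convention the
#' patient's right lung appears on the image's left side. Every structure is
#' analytic, so exact per-lobe ground-truth masks exist by construction.
#'
#' @param height,width Image size in pixels (default 224 x 224).
#' @param lobes Named list with elements `right` and `left`, each a list
#'   `center = c(x, y)` (0-based pixel coordinates), `semi = c(a, b)`
#'   (semi-axes in pixels, x then y), `rotation` (radians,
#'   counter-clockwise), `intensity` (interior intensity). Defaults scale
#'   with the image size and follow `convention`.
#' @param background_intensity Background intensity; must exceed every lobe
#'   intensity (lungs are dark on a radiograph). Default 180.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#'   Default 5 — mild quantum mottle; set 0 for a noiseless phantom.
#' @param seed Integer seed; identical spec + seed give bit-identical output.
#' @param bit_depth Intensity bit depth (8 default; 12 supported for
#'   computed-radiography-like ranges).
#' @param convention `"radiographic"` (patient right on image left, default)
#'   or `"viewer"` (mirrored). Only affects the default lobe placement.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 224L, width = 224L, lobes = NULL,
                         background_intensity = 180, noise_sd = 5,
                         seed = 1L, bit_depth = 8L,
                         convention = c("radiographic", "viewer")) {
  convention <- match.arg(convention)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 8L || width < 8L) stop("phantom must be at least 8 x 8")
  if (is.null(lobes)) {
    # anatomically plausible placement: right lung slightly larger/lower
    sx <- width / 224; sy <- height / 224
    right_c <- c(68 * sx, 118 * sy); left_c <- c(152 * sx, 112 * sy)
    if (convention == "viewer") { tmp <- right_c; right_c <- left_c; left_c <- tmp }
    lobes <- list(
      right = list(center = right_c, semi = c(34 * sx, 62 * sy),
                   rotation = 0.08, intensity = 60),
      left = list(center = left_c, semi = c(29 * sx, 57 * sy),
                  rotation = -0.08, intensity = 60))
  }
  if (!all(c("right", "left") %in% names(lobes))) {
    stop("`lobes` must name both `right` and `left`")
  }
  maxv <- 2^bit_depth - 1
  for (side in c("right", "left")) {
    lb <- lobes[[side]]
    if (lb$intensity >= background_intensity) {
      stop("lobe interior intensity must be below the background intensity")
    }
    if (lb$intensity < 0 || background_intensity > maxv) {
      stop("intensities must fit the stated bit depth")
    }
    th <- lb$rotation
    ext_x <- sqrt((lb$semi[1] * cos(th))^2 + (lb$semi[2] * sin(th))^2)
    ext_y <- sqrt((lb$semi[1] * sin(th))^2 + (lb$semi[2] * cos(th))^2)
    if (lb$center[1] - ext_x < 0 || lb$center[1] + ext_x > width - 1 ||
        lb$center[2] - ext_y < 0 || lb$center[2] + ext_y > height - 1) {
      stop(sprintf("%s lobe ellipse extends outside the image bounds", side))
    }
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(height = height, width = width, lobes = lobes,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 bit_depth = as.integer(bit_depth), convention = convention),
            class = "phantom_spec")
}

# Exact rasterization of a rotated ellipse: pixel (x, y) (0-based integer
# centres) is inside iff the rotated, axis-normalized radius is <= 1.
ellipse_mask <- function(height, width, center, semi, rotation = 0) {
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), times = width), height, width)
  dx <- x - center[1]; dy <- y - center[2]
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  (u / semi[1])^2 + (v / semi[2])^2 <= 1
}

#' Generate a synthetic chest phantom
#'
#' Renders the two lobe ellipses at their interior intensity on the
#' background, adds seeded Gaussian noise, clamps to the representable
#' range, and rounds to integer intensities. The ground-truth masks are the
#' exact ellipse rasterizations and must be disjoint (two separate lung
#' fields).
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]), `masks` (named list of
#'   logical matrices `right`, `left`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- lapply(spec$lobes[c("right", "left")], function(lb) {
    ellipse_mask(spec$height, spec$width, lb$center, lb$semi, lb$rotation)
  })
  if (any(masks$right & masks$left)) {
    stop("lobe ellipses overlap: ground-truth masks must be disjoint")
  }
  img <- matrix(spec$background_intensity, spec$height, spec$width)
  img[masks$right] <- spec$lobes$right$intensity
  img[masks$left] <- spec$lobes$left$intensity
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(spec$height * spec$width,
                                           sd = spec$noise_sd),
                              spec$height, spec$width))
    img <- img + noise
  }
  maxv <- 2^spec$bit_depth - 1
  img <- round(pmin(pmax(img, 0), maxv))
  list(image = gray_image(img, bit_depth = spec$bit_depth),
       masks = masks, spec = spec)
}

#' Write a phantom's image, masks and spec to disk
#'
#' Files: `<id>.png` (image), `<id>__mask_right.png`, `<id>__mask_left.png`
#' (0/255 masks), `<id>.yaml` (spec).
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @param id File stem.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_phantom <- function(phantom, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, paste0(id, image_file_ext(phantom$image))),
             mask_right = file.path(dir, paste0(id, "__mask_right.png")),
             mask_left = file.path(dir, paste0(id, "__mask_left.png")),
             spec = file.path(dir, paste0(id, ".yaml")))
  write_image_png(phantom$image, paths[["image"]])
  write_mask_png(phantom$masks$right, paths[["mask_right"]])
  write_mask_png(phantom$masks$left, paths[["mask_left"]])
  sp <- phantom$spec
  yaml::write_yaml(list(height = sp$height, width = sp$width,
                        lobes = sp$lobes,
                        background_intensity = sp$background_intensity,
                        noise_sd = sp$noise_sd, seed = sp$seed,
                        bit_depth = sp$bit_depth,
                        convention = sp$convention),
                   paths[["spec"]])
  invisible(paths)
}

#' Read a phantom specification from YAML
#' @param path YAML file written by [write_phantom()] or hand-authored.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  lobes <- lapply(y$lobes, function(lb) {
    list(center = unlist(lb$center), semi = unlist(lb$semi),
         rotation = lb$rotation, intensity = lb$intensity)
  })
  phantom_spec(height = y$height, width = y$width, lobes = lobes,
               background_intensity = y$background_intensity,
               noise_sd = y$noise_sd, seed = y$seed,
               bit_depth = if (is.null(y$bit_depth)) 8L else y$bit_depth,
               convention = if (is.null(y$convention)) "radiographic"
                            else y$convention)
}
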