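# Independent brute-force oracles and small fixtures shared across tests.
# Everything here is intentionally naive (double loops, exhaustive sweeps)
# and must stay independent of the package code paths it checks.

# Small two-lobe phantom spec scaled to `size` pixels.
small_phantom_spec <- function(size = 48L, noise_sd = 0, seed = 1L,
                               semi_frac = c(0.22, 0.30)) {
  s <- size
  phantom_spec(
    height = s, width = s,
    lobes = list(
      right = list(center = c(0.28 * s, 0.52 * s),
                   semi = c(semi_frac[1] * s, semi_frac[2] * s),
                   rotation = 0, intensity = 60),
      left = list(center = c(0.72 * s, 0.48 * s),
                  semi = c(0.9 * semi_frac[1] * s, 0.9 * semi_frac[2] * s),
                  rotation = 0, intensity = 60)),
    background_intensity = 180, noise_sd = noise_sd, seed = seed)
}

# Brute-force pixel-counting IoU over an explicit double loop.
brute_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) inter <- inter + 1L
      if (a[i, j] || b[i, j]) uni <- uni + 1L
    }
  }
  if (uni == 0L) 1 else inter / uni
}

# Plain-sum Dice coefficient by counting.
brute_dice <- function(a, b) {
  inter <- sum(a & b)
  tot <- sum(a) + sum(b)
  if (tot == 0L) 1 else 2 * inter / tot
}

# Naive Otsu: evaluate the between-class variance of the {< T} / {>= T}
# split for every candidate T with explicit means, return the argmax.
brute_otsu <- function(values, max_value = 255L) {
  v <- as.integer(round(as.vector(values)))
  best_t <- NA_real_; best_v <- -Inf
  for (t in 1:max_value) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_v + 1e-12) { best_v <- bcv; best_t <- t }
  }
  best_t
}

# Brute-force point-in-ellipse rasterization count.
brute_ellipse_count <- function(height, width, center, semi, rotation = 0) {
  count <- 0L
  for (y in 0:(height - 1)) {
    for (x in 0:(width - 1)) {
      dx <- x - center[1]; dy <- y - center[2]
      u <- dx * cos(rotation) + dy * sin(rotation)
      v <- -dx * sin(rotation) + dy * cos(rotation)
      if ((u / semi[1])^2 + (v / semi[2])^2 <= 1) count <- count + 1L
    }
  }
  count
}

# Exhaustive objective sweep: evaluate `objective` for every integer
# translation of `box` keeping it inside the image; returns the optimum.
exhaustive_translation_optimum <- function(image, box, objective) {
  w <- box$x_max - box$x_min; h <- box$y_max - box$y_min
  best <- -Inf
  for (x0 in 0:(ncol(image) - w)) {
    for (y0 in 0:(nrow(image) - h)) {
      b <- bounding_box(x0, y0, x0 + w, y0 + h)
      val <- objective(image, b)
      if (val > best) best <- val
    }
  }
  best
}

# Evaluate `expr` under a fixed seed (test-local convenience).
with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Replicates the documented seeded box-jitter draw of stability_score():
# 2n uniform integer offsets in [-magnitude, magnitude], filled column-wise
# as (dx, dy) pairs. Returns the i-th pair.
with_seed_like <- function(seed, i, n, magnitude) {
  set.seed(seed)
  m <- matrix(sample(seq(-magnitude, magnitude), 2L * n, replace = TRUE),
              ncol = 2)
  m[i, ]
}

random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}
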