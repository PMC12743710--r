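#' Scale quality scores to a probability range
#'
#' Min-max scaling of raw segmentation quality/stability scores onto
#' `[0, 1]`, the proxy-probability conversion used before reliability
#' binning. A constant input has no scale; every value maps to 1 (the
#' scores are all "the best seen") with a warning. `method = "identity"`
#' passes scores through for backends that already report probabilities.
#'
#' @param scores Nonempty numeric vector.
#' @param method `"minmax"` (default) or `"identity"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
scores_to_probabilities <- function(scores, method = c("minmax", "identity")) {
  method <- match.arg(method)
  if (length(scores) == 0L) stop("`scores` must be nonempty")
  if (method == "identity") {
    if (any(scores < 0 | scores > 1)) {
      stop("identity scaling requires scores already in [0, 1]")
    }
    return(as.numeric(scores))
  }
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    warning("constant scores: degenerate scale, mapping all to 1")
    return(rep(1, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Binary segmentation outcomes from mask pairs
#'
#' Operationalizes the qualitative "good segmentation" judgment as an IoU
#' cutoff: outcome 1 when `IoU(predicted, ground truth) >= cutoff`, else 0.
#'
#' @param pairs List of `list(predicted = <mask>, ground_truth = <mask>)`.
#' @param cutoff IoU cutoff in `(0, 1)`. Default 0.5.
#' @return Integer vector of 0/1 outcomes.
#' @export
assign_outcomes <- function(pairs, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must lie in (0, 1)")
  vapply(pairs, function(p) {
    iou <- if (is.logical(p$predicted)) {
      mask_iou(p$predicted, p$ground_truth)
    } else {
      bpiou(p$predicted, p$ground_truth)
    }
    as.integer(iou >= cutoff)
  }, integer(1))
}

#' Reliability (calibration) table
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on `[0, 1]`
#' (each bin `[lo, hi)`, the last closed at 1) and reports, per bin, the
#' mean predicted probability and the observed fraction of positive
#' outcomes. Empty bins are kept with count 0 and `NA` means. A perfectly
#' calibrated predictor puts every bin on the diagonal `fraction = mean`.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param outcomes 0/1 vector of the same length.
#' @param n_bins Number of bins, at least 1. Default 10.
#' @return A `calibration_table`: data frame with `bin`, `bin_lower`,
#'   `bin_upper`, `mean_predicted`, `fraction_positive`, `count`.
#' @export
calibration_table <- function(probabilities, outcomes, n_bins = 10L) {
  if (length(probabilities) != length(outcomes)) {
    stop("`probabilities` and `outcomes` must have equal length")
  }
  if (n_bins < 1L) stop("`n_bins` must be at least 1")
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  bin <- pmin(floor(probabilities * n_bins) + 1L, n_bins)  # 1.0 -> top bin
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin = seq_len(n_bins),
                    bin_lower = edges[-(n_bins + 1L)],
                    bin_upper = edges[-1L],
                    mean_predicted = NA_real_,
                    fraction_positive = NA_real_,
                    count = 0L)
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b
    out$count[b] <- sum(in_bin)
    if (out$count[b] > 0L) {
      out$mean_predicted[b] <- mean(probabilities[in_bin])
      out$fraction_positive[b] <- mean(outcomes[in_bin])
    }
  }
  structure(out, class = c("calibration_table", "data.frame"))
}

#' Write a reliability diagram
#'
#' Observed positive fraction against mean predicted probability per
#' occupied bin, with the diagonal perfect-calibration reference line.
#'
#' @param table A [calibration_table()].
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_reliability <- function(table, path, main = "Reliability diagram") {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  occupied <- table[table$count > 0L, ]
  graphics::plot(c(0, 1), c(0, 1), type = "n", asp = 1,
                 xlab = "Mean predicted probability",
                 ylab = "Fraction of positive outcomes", main = main)
  graphics::abline(0, 1, lty = 2, col = "gray50")
  graphics::lines(occupied$mean_predicted, occupied$fraction_positive,
                  type = "b", pch = 19, col = "steelblue")
  invisible(path)
}
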