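# Region, boundary, calibration and significance metrics.

as_binary_matrix <- function(x) {
  x <- as.matrix(x)
  (x > 0.5) * 1L
}

#' Region overlap metrics
#'
#' Dice, IoU, precision and sensitivity from confusion counts. When both
#' masks are empty all four are 1 (nothing to find, nothing found); when the
#' masks are disjoint and at least one is nonempty all four are 0.
#'
#' @param pred,target Binary matrices (values are thresholded at 0.5).
#' @return Named list with `dice`, `iou`, `precision`, `sensitivity`.
#' @export
region_metrics <- function(pred, target) {
  p <- as_binary_matrix(pred); t <- as_binary_matrix(target)
  stopifnot(all(dim(p) == dim(t)))
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    return(list(dice = 1, iou = 1, precision = 1, sensitivity = 1))
  }
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(dice = safe(2 * tp, 2 * tp + fp + fn),
       iou = safe(tp, tp + fp + fn),
       precision = safe(tp, tp + fp),
       sensitivity = safe(tp, tp + fn))
}

boundary_coords <- function(mask) {
  cpp_boundary_pixels(as_binary_matrix(mask))
}

#' Surface distance metrics (HD95 and ASSD)
#'
#' Boundary pixels are extracted by 8-connectivity erosion difference; the
#' directed Euclidean nearest-boundary distances of both directions are
#' pooled, and HD95 is the 95th percentile (linear interpolation) while ASSD
#' is the mean of that pooled multiset. If either mask is empty, both
#' metrics fall back to the image diagonal (with a warning).
#'
#' @param pred,target Binary matrices.
#' @return Named list with `hd95` and `assd` (pixels).
#' @export
surface_distances <- function(pred, target) {
  p <- as_binary_matrix(pred); t <- as_binary_matrix(target)
  stopifnot(all(dim(p) == dim(t)))
  bp <- boundary_coords(p); bt <- boundary_coords(t)
  if (nrow(bp) == 0 || nrow(bt) == 0) {
    warning("empty mask in surface_distances; returning the image diagonal")
    diag <- sqrt(sum(dim(p)^2))
    return(list(hd95 = diag, assd = diag))
  }
  d <- c(cpp_min_dists(bp + 0, bt + 0), cpp_min_dists(bt + 0, bp + 0))
  list(hd95 = as.numeric(stats::quantile(d, 0.95, type = 7)),
       assd = mean(d))
}

#' Boundary F1 within a distance tolerance
#'
#' Boundary precision (predicted boundary pixels within `tolerance` of the
#' reference boundary) and recall (vice versa), combined as their harmonic
#' mean. Empty-boundary conventions follow [region_metrics()].
#'
#' @param pred,target Binary matrices.
#' @param tolerance Match distance in pixels (default 2).
#' @return Scalar in `[0, 1]`.
#' @export
boundary_f1 <- function(pred, target, tolerance = 2) {
  stopifnot(tolerance >= 0)
  bp <- boundary_coords(pred); bt <- boundary_coords(target)
  if (nrow(bp) == 0 && nrow(bt) == 0) return(1)
  if (nrow(bp) == 0 || nrow(bt) == 0) return(0)
  prec <- mean(cpp_min_dists(bp + 0, bt + 0) <= tolerance)
  rec <- mean(cpp_min_dists(bt + 0, bp + 0) <= tolerance)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Expected calibration error
#'
#' Pixels are binned by confidence into `n_bins` equal-width, right-closed
#' bins over `[0, 1]`; ECE is the bin-size-weighted mean absolute gap
#' between bin accuracy and bin mean confidence.
#'
#' @param confidence Numeric vector/matrix of predicted confidences
#'   (`max(p, 1 - p)` for a binary segmenter, hence in `[0.5, 1]`).
#' @param correct Binary vector/matrix: was the thresholded prediction
#'   correct at that pixel.
#' @param n_bins Number of bins (default 10).
#' @return Scalar ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(confidence, correct, n_bins = 10) {
  conf <- as.numeric(confidence)
  corr <- as.numeric(correct) > 0.5
  stopifnot(length(conf) == length(corr))
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    ece <- ece + sum(sel) / n * abs(mean(corr[sel]) - mean(conf[sel]))
  }
  ece
}

#' Reliability diagram bin table
#'
#' The per-bin data behind [expected_calibration_error()], for plotting.
#'
#' @inheritParams expected_calibration_error
#' @return Tibble with bin, count, mean confidence, accuracy and gap.
#' @export
reliability_table <- function(confidence, correct, n_bins = 10) {
  conf <- as.numeric(confidence)
  corr <- as.numeric(correct) > 0.5
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    tibble::tibble(bin = b,
                   lower = (b - 1) / n_bins, upper = b / n_bins,
                   n = sum(sel),
                   confidence = mean(conf[sel]),
                   accuracy = mean(corr[sel]))
  })
  out <- do.call(rbind, rows)
  out$gap <- out$accuracy - out$confidence
  out
}

#' Uncertainty-error correlation (UEC)
#'
#' Pearson (point-biserial) correlation between the per-pixel uncertainty
#' and the 0/1 error indicator, pooled over the supplied pixels. If either
#' variable is constant the correlation is undefined; 0 is returned with
#' `attr(, "degenerate") = TRUE`.
#'
#' @param uncertainty Numeric vector/matrix in `[0, 1]`.
#' @param error Binary vector/matrix (1 = prediction wrong at that pixel).
#' @return Scalar in `[-1, 1]`.
#' @export
uncertainty_error_correlation <- function(uncertainty, error) {
  u <- as.numeric(uncertainty)
  e <- as.numeric(error) > 0.5
  stopifnot(length(u) == length(e))
  if (stats::sd(u) == 0 || stats::sd(e) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(u, as.numeric(e)), degenerate = FALSE)
}

#' Paired permutation test (sign-flip)
#'
#' Tests whether paired scores differ, using the absolute mean difference as
#' statistic. Signs of the paired differences are flipped; when the
#' `2^n` flip patterns are no more than `n_resamples` they are enumerated
#' exhaustively (`p = #{patterns with statistic >= observed} / 2^n`),
#' otherwise `n_resamples` random patterns are drawn and the add-one
#' corrected estimate `p = (1 + #{>= observed}) / (1 + n_resamples)` is used.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (>= 2 pairs).
#' @param n_resamples Number of random sign-flip resamples (default 1000).
#' @param seed Integer seed for the random resampling branch.
#' @return p-value in `(0, 1]`, with `attr(, "statistic")` the observed
#'   absolute mean difference and `attr(, "exhaustive")` a flag.
#' @export
paired_permutation_test <- function(scores_a, scores_b, n_resamples = 1000,
                                    seed = 0) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- as.numeric(scores_a) - as.numeric(scores_b)
  n <- length(d)
  obs <- abs(mean(d))
  if (2^n <= n_resamples) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d) / n
    p <- mean(stats >= obs - 1e-12)
    return(structure(p, statistic = obs, exhaustive = TRUE))
  }
  with_local_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_resamples)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (abs(mean(s * d)) >= obs - 1e-12) cnt <- cnt + 1L
    }
    structure((1 + cnt) / (1 + n_resamples), statistic = obs,
              exhaustive = FALSE)
  })
}
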