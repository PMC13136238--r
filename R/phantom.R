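# Synthetic ultrasound phantom generator.
#
# Emulates the statistical regimes of B-mode liver-fibrosis imaging that the
# segmentation network targets: multiplicative gamma speckle, gradual
# (Gaussian-blurred) nodule boundaries with grayscale overlap against the
# background, nodules occupying a small fraction of the field (default
# 3%-8%), optional dark acoustic-shadow bands, and four nodule
# morphologies: cord-like fragments, dispersed small particles, massive
# dense clusters (non-touching), and fusiform low-contrast spindles.

#' Phantom generator configuration
#'
#' @param height,width Image size in pixels (>= 32 each; the training
#'   protocol uses 320, tests use 64 or smaller).
#' @param scenario One of `"cord"`, `"particles"`, `"dense"`, `"fusiform"`,
#'   `"mixed"` (mixed draws a scenario per sample).
#' @param nodule_count_range Optional length-2 integer range overriding the
#'   per-scenario defaults (cord 2-6, particles 8-25, dense 4-10,
#'   fusiform 1-3).
#' @param foreground_fraction_range Admissible mask foreground fraction;
#'   enforced by rejection sampling with geometric rescaling.
#' @param contrast_delta Foreground-minus-background mean intensity in
#'   normalized units (halved for the fusiform scenario).
#' @param boundary_blur_sigma Gaussian blur (pixels) applied to the clean
#'   intensity field before speckle, producing gradual tissue transitions.
#' @param speckle_shape Shape of the mean-1 multiplicative gamma speckle
#'   field; smaller values give heavier speckle. The default 16 (~25%
#'   multiplicative noise) emulates displayed, log-compressed B-mode
#'   texture while keeping substantial foreground/background grayscale
#'   overlap.
#' @param shadow_probability Probability of a dark vertical acoustic-shadow
#'   band (intensity multiplier 0.5).
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(height = 320, width = 320,
                           scenario = c("mixed", "cord", "particles",
                                        "dense", "fusiform"),
                           nodule_count_range = NULL,
                           foreground_fraction_range = c(0.03, 0.08),
                           contrast_delta = 0.15,
                           boundary_blur_sigma = 2,
                           speckle_shape = 16,
                           shadow_probability = 0.2,
                           seed = 0) {
  scenario <- match.arg(scenario)
  stopifnot(height >= 32, width >= 32,
            length(foreground_fraction_range) == 2,
            foreground_fraction_range[1] > 0,
            foreground_fraction_range[2] < 1,
            diff(foreground_fraction_range) > 0,
            boundary_blur_sigma >= 0, speckle_shape > 0,
            shadow_probability >= 0, shadow_probability <= 1)
  if (!is.null(nodule_count_range)) {
    stopifnot(length(nodule_count_range) == 2,
              nodule_count_range[1] >= 1,
              nodule_count_range[1] <= nodule_count_range[2])
  }
  structure(list(height = height, width = width, scenario = scenario,
                 nodule_count_range = nodule_count_range,
                 foreground_fraction_range = foreground_fraction_range,
                 contrast_delta = contrast_delta,
                 boundary_blur_sigma = boundary_blur_sigma,
                 speckle_shape = speckle_shape,
                 shadow_probability = shadow_probability,
                 seed = seed),
            class = "phantom_config")
}

scenario_count_range <- function(scenario, cfg) {
  if (!is.null(cfg$nodule_count_range)) return(cfg$nodule_count_range)
  switch(scenario,
         cord = c(2, 6), particles = c(8, 25),
         dense = c(4, 10), fusiform = c(1, 3))
}

# coordinate grids (1-based pixel centers)
pixel_grid <- function(h, w) {
  list(i = matrix(seq_len(h), h, w), j = matrix(seq_len(w), h, w, byrow = TRUE))
}

stamp_ellipse <- function(mask, grid, ci, cj, a, b, theta, p_long = 2) {
  dx <- grid$i - ci; dy <- grid$j - cj
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  mask | (abs(u / a)^p_long + abs(v / b)^2 <= 1)
}

# Feature-size floors in absolute pixels. Geometry otherwise scales with
# the image side; at small test sizes (64 px) the floors keep nodules
# resolvable under the fixed boundary blur, mirroring how nodules in
# protocol-resized ultrasound stay several pixels wide. At 320 px the
# floors are inactive; below 64 px they relax proportionally so the
# 3%-8% foreground target stays reachable at the minimum 32 px size.
floor_px <- function(value, s) value * min(1, s / 64)
FLOOR_CORD_THICK <- 4
FLOOR_PARTICLE_R <- 3.5
FLOOR_DENSE_R <- 4
FLOOR_FUSIFORM_A <- 8
FLOOR_FUSIFORM_B <- 3

# pick a nodule count inside the scenario range so that the expected
# foreground area lands near the target fraction
n_for_target <- function(cr, target_px, shape_area) {
  n <- round(target_px / max(shape_area, 1))
  max(cr[1], min(cr[2], n))
}

draw_cord_mask <- function(h, w, n, scale) {
  s <- min(h, w)
  g <- pixel_grid(h, w)
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(n)) {
    len <- runif(1, 0.25, 0.5) * s * scale
    thick <- max(floor_px(FLOOR_CORD_THICK, s), runif(1, 0.015, 0.03) * s * scale)
    p0 <- c(runif(1, 0.15 * h, 0.85 * h), runif(1, 0.15 * w, 0.85 * w))
    ang <- runif(1, 0, 2 * pi)
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2
    bend <- runif(1, -0.25, 0.25) * len
    p1 <- mid + bend * c(-sin(ang), cos(ang))
    ts <- seq(0, 1, length.out = max(8, ceiling(len)))
    for (t in ts) {
      pt <- (1 - t)^2 * p0 + 2 * t * (1 - t) * p1 + t^2 * p2
      mask <- mask | ((g$i - pt[1])^2 + (g$j - pt[2])^2 <= (thick / 2)^2)
    }
  }
  mask
}

draw_particles_mask <- function(h, w, n, scale) {
  s <- min(h, w)
  g <- pixel_grid(h, w)
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(n)) {
    r <- max(floor_px(FLOOR_PARTICLE_R, s), runif(1, 0.015, 0.03) * s * scale)
    ci <- runif(1, r + 1, h - r)
    cj <- runif(1, r + 1, w - r)
    mask <- stamp_ellipse(mask, g, ci, cj, r * runif(1, 0.8, 1.2),
                          r * runif(1, 0.8, 1.2), runif(1, 0, pi))
  }
  mask
}

# closely packed but non-touching blobs: every pair separated by >= 1 px
draw_dense_mask <- function(h, w, n, scale) {
  s <- min(h, w)
  g <- pixel_grid(h, w)
  mask <- matrix(FALSE, h, w)
  cc <- c(runif(1, 0.35 * h, 0.65 * h), runif(1, 0.35 * w, 0.65 * w))
  placed <- 0
  guard <- 0
  while (placed < n && guard < 400) {
    guard <- guard + 1
    r <- max(floor_px(FLOOR_DENSE_R, s), runif(1, 0.03, 0.05) * s * scale)
    ci <- cc[1] + runif(1, -0.25, 0.25) * s
    cj <- cc[2] + runif(1, -0.25, 0.25) * s
    if (ci < r + 2 || ci > h - r - 1 || cj < r + 2 || cj > w - r - 1) next
    cand <- stamp_ellipse(matrix(FALSE, h, w), g, ci, cj,
                          r * runif(1, 0.8, 1.2), r * runif(1, 0.7, 1),
                          runif(1, 0, pi))
    if (!any(cand)) next
    if (any(mask & dilate1(cand)) || any(dilate1(mask) & cand)) next
    mask <- mask | cand
    placed <- placed + 1
  }
  if (placed < n) return(NULL)
  mask
}

draw_fusiform_mask <- function(h, w, n, scale) {
  s <- min(h, w)
  g <- pixel_grid(h, w)
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(n)) {
    a <- max(floor_px(FLOOR_FUSIFORM_A, s), runif(1, 0.08, 0.15) * s * scale)
    b <- max(floor_px(FLOOR_FUSIFORM_B, s), a / runif(1, 3, 5))
    ci <- runif(1, 0.25 * h, 0.75 * h)
    cj <- runif(1, 0.25 * w, 0.75 * w)
    # exponent 1.5 on the long axis tapers the ends into a spindle
    mask <- stamp_ellipse(mask, g, ci, cj, a, b, runif(1, 0, pi), p_long = 1.5)
  }
  mask
}

# 3x3 (8-connected) dilation, so a 1-px gap also excludes diagonal adjacency
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[-h, ] <- out[-h, ] | m[-1, ]
  v <- out
  out[, -1] <- out[, -1] | v[, -w]
  out[, -w] <- out[, -w] | v[, -1]
  out
}

draw_scenario_mask <- function(scenario, h, w, n, scale) {
  switch(scenario,
         cord = draw_cord_mask(h, w, n, scale),
         particles = draw_particles_mask(h, w, n, scale),
         dense = draw_dense_mask(h, w, n, scale),
         fusiform = draw_fusiform_mask(h, w, n, scale))
}

#' Generate one synthetic ultrasound phantom
#'
#' Draws a scenario-specific nodule mask (rejection-sampled into the
#' configured foreground-fraction range, with geometric rescaling between
#' attempts), then synthesizes the image: smooth background field +
#' `contrast_delta` inside nodules, Gaussian-blurred boundary, multiplied by
#' mean-1 gamma speckle, optional shadow band, clipped to `[0, 1]`.
#' Bit-identical output for identical `(config, sample_seed)`.
#'
#' @param config A [phantom_config()].
#' @param sample_seed Non-negative integer; combined with `config$seed`.
#' @return A list of class `ultrasound_sample`: `image` (matrix in `[0, 1]`),
#'   `mask` (binary 0/1 matrix), `meta` (scenario, seeds, nodule count).
#' @export
generate_phantom <- function(config, sample_seed = 0) {
  stopifnot(inherits(config, "phantom_config"), sample_seed >= 0)
  h <- config$height; w <- config$width
  derived <- (config$seed * 1000003 + sample_seed * 7919 + 17) %% 2147483647
  with_local_seed(derived, {
    scenario <- config$scenario
    if (scenario == "mixed") {
      scenario <- sample(c("cord", "particles", "dense", "fusiform"), 1)
    }
    cr <- scenario_count_range(scenario, config)
    ffr <- config$foreground_fraction_range
    target <- mean(ffr)
    scale <- 1
    mask <- NULL
    n_nodules <- NA_integer_
    s_px <- min(h, w)
    for (attempt in seq_len(100)) {
      area_est <- switch(scenario,
        cord = 0.375 * s_px * scale *
          max(floor_px(FLOOR_CORD_THICK, s_px), 0.0225 * s_px * scale),
        particles = pi *
          max(floor_px(FLOOR_PARTICLE_R, s_px), 0.0225 * s_px * scale)^2,
        dense = 0.85 * pi *
          max(floor_px(FLOOR_DENSE_R, s_px), 0.04 * s_px * scale)^2,
        fusiform = {
          a <- max(floor_px(FLOOR_FUSIFORM_A, s_px), 0.115 * s_px * scale)
          0.8 * pi * a * max(floor_px(FLOOR_FUSIFORM_B, s_px), a / 4)
        })
      n_est <- n_for_target(cr, target * h * w, area_est)
      n <- max(cr[1], min(cr[2], round(n_est * runif(1, 0.8, 1.2))))
      m <- draw_scenario_mask(scenario, h, w, n, scale)
      if (is.null(m)) next
      frac <- mean(m)
      if (frac >= ffr[1] && frac <= ffr[2]) {
        mask <- m
        n_nodules <- n
        break
      }
      if (frac > 0) scale <- min(4, max(0.25, scale * sqrt(target / frac)))
    }
    if (is.null(mask)) {
      stop("could not reach foreground fraction [", ffr[1], ", ", ffr[2],
           "] after 100 attempts for scenario '", scenario, "' at ",
           h, "x", w, "; the configuration is infeasible")
    }
    delta <- config$contrast_delta * (if (scenario == "fusiform") 0.5 else 1)
    bg <- 0.35 + smooth_background(h, w)
    clean <- bg + delta * mask
    clean <- cpp_gaussian_blur(clean, config$boundary_blur_sigma)
    k <- config$speckle_shape
    speckle <- matrix(rgamma(h * w, shape = k, rate = k), h, w)
    img <- clean * speckle
    if (runif(1) < config$shadow_probability) {
      bw <- max(2, round(0.1 * w))
      j0 <- sample.int(w - bw + 1, 1)
      img[, j0:(j0 + bw - 1)] <- img[, j0:(j0 + bw - 1)] * 0.5
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask * 1L,
                   meta = list(scenario = scenario, seed = sample_seed,
                               derived_seed = derived, n_nodules = n_nodules,
                               split = NA_character_)),
              class = "ultrasound_sample")
  })
}

smooth_background <- function(h, w) {
  g <- pixel_grid(h, w)
  f <- matrix(0, h, w)
  s <- min(h, w)
  for (k in 1:3) {
    amp <- runif(1, -0.05, 0.05)
    ci <- runif(1, 1, h); cj <- runif(1, 1, w)
    sig <- runif(1, 0.25, 0.6) * s
    f <- f + amp * exp(-((g$i - ci)^2 + (g$j - cj)^2) / (2 * sig^2))
  }
  f
}

#' @export
print.ultrasound_sample <- function(x, ...) {
  cat("<ultrasound_sample>", nrow(x$image), "x", ncol(x$image),
      "scenario:", x$meta$scenario,
      sprintf("foreground: %.1f%%", 100 * mean(x$mask)), "\n")
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a CSV manifest and a JSON sidecar
#' embedding the full configuration. Split sizes are `round(n * ratio)` for
#' validation and test, with the remainder assigned to train (so 100 samples
#' at 7:1:2 give 70/10/20). Per-sample seeds derive deterministically from
#' the master seed, so regeneration reproduces identical files.
#'
#' @param config A [phantom_config()].
#' @param n Number of samples (>= 10).
#' @param split_ratios Train/val/test proportions summing to 1.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides `config$seed`.
#' @return A tibble manifest (id, image, mask, split) of class
#'   `espd_manifest`, with the output directory in `attr(, "out_dir")`.
#' @export
generate_dataset <- function(config, n, split_ratios = c(0.7, 0.1, 0.2),
                             out_dir, seed = config$seed) {
  stopifnot(n >= 10, length(split_ratios) == 3,
            abs(sum(split_ratios) - 1) < 1e-8)
  config$seed <- seed
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  n_val <- round(n * split_ratios[2])
  n_test <- round(n * split_ratios[3])
  n_train <- n - n_val - n_test
  splits <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  ids <- sprintf("s%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- generate_phantom(config, sample_seed = i)
    ipath <- file.path("images", paste0(ids[i], ".png"))
    mpath <- file.path("masks", paste0(ids[i], ".png"))
    png::writePNG(smp$image, file.path(out_dir, ipath))
    png::writePNG(smp$mask + 0, file.path(out_dir, mpath))
    rows[[i]] <- tibble::tibble(id = ids[i], image = ipath, mask = mpath,
                                split = splits[i],
                                scenario = smp$meta$scenario)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config), n = n, split_ratios = split_ratios,
         seed = seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  attr(manifest, "out_dir") <- out_dir
  class(manifest) <- c("espd_manifest", class(manifest))
  manifest
}

#' Read a dataset manifest
#'
#' @param dir Directory written by [generate_dataset()].
#' @return The manifest tibble with `attr(, "out_dir")` set.
#' @export
read_manifest <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                                stringsAsFactors = FALSE))
  attr(manifest, "out_dir") <- dir
  class(manifest) <- c("espd_manifest", class(manifest))
  manifest
}

#' Load one image/mask pair referenced by a manifest row
#'
#' @param manifest An `espd_manifest`.
#' @param id Sample id.
#' @return List with `image` (matrix in `[0, 1]`) and `mask` (0/1 matrix).
#' @export
load_sample <- function(manifest, id) {
  row <- manifest[manifest$id == id, ]
  if (nrow(row) != 1) stop("id not found in manifest: ", id)
  dir <- attr(manifest, "out_dir")
  img <- png::readPNG(file.path(dir, row$image))
  msk <- png::readPNG(file.path(dir, row$mask))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  list(image = img, mask = (msk > 0.5) * 1L)
}
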