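# shared fixtures: everything is generated in code at test time

tiny_phantom_cfg <- function(scenario = "mixed", seed = 7, size = 64, ...) {
  phantom_config(height = size, width = size, scenario = scenario,
                 seed = seed, ...)
}

make_samples <- function(idx, cfg = tiny_phantom_cfg()) {
  lapply(idx, function(i) {
    s <- generate_phantom(cfg, i)
    list(image = s$image, mask = s$mask)
  })
}

# numeric-vs-analytic gradient check of a scalar-valued tape computation.
# build(tape, x) must return a scalar node; x is an ag_param.
check_grad <- function(build, x0, n_checks = 4, eps = 1e-6, tol = 1e-5,
                      seed = 1) {
  x <- ag_param(x0)
  tape <- ag_tape()
  loss <- build(tape, x)
  ag_backward(tape, loss)
  withr::with_seed(seed, {
    idx <- sample(length(x0), min(n_checks, length(x0)))
  })
  for (i in idx) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    fp <- ag_val(build(ag_tape(), ag_const(xp)))
    fm <- ag_val(build(ag_tape(), ag_const(xm)))
    num <- (fp - fm) / (2 * eps)
    an <- if (is.null(x$grad)) 0 else x$grad[i]
    expect_equal(an, num, tolerance = tol)
  }
  invisible(NULL)
}

# independent brute-force oracle for surface distances: boundary pixels via
# direct neighbourhood inspection in R, all-pairs Euclidean distances
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 0) next
      nb <- expand.grid(di = -1:1, dj = -1:1)
      nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
      on_border <- FALSE
      for (k in seq_len(nrow(nb))) {
        ii <- i + nb$di[k]; jj <- j + nb$dj[k]
        if (ii < 1 || ii > h || jj < 1 || jj > w || mask[ii, jj] == 0) {
          on_border <- TRUE
          break
        }
      }
      if (on_border) pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

oracle_surface_distances <- function(pred, target) {
  bp <- oracle_boundary(pred); bt <- oracle_boundary(target)
  dmat <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(x, y) {
      sqrt((a[x, 1] - b[y, 1])^2 + (a[x, 2] - b[y, 2])^2)
    })
  }
  d1 <- apply(dmat(bp, bt), 1, min)
  d2 <- apply(dmat(bt, bp), 1, min)
  pooled <- c(d1, d2)
  list(hd95 = unname(stats::quantile(pooled, 0.95, type = 7)),
       assd = mean(pooled))
}

random_blob_mask <- function(h, w, seed) {
  withr::with_seed(seed, {
    m <- matrix(0L, h, w)
    for (k in seq_len(sample(1:3, 1))) {
      ci <- runif(1, 4, h - 3); cj <- runif(1, 4, w - 3)
      r <- runif(1, 1.5, 5)
      ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, TRUE)
      m[(ii - ci)^2 + (jj - cj)^2 <= r^2] <- 1L
    }
    m
  })
}
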