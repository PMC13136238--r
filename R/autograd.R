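# Reverse-mode autodiff tape over dense arrays.
#
# Tensors are plain R arrays laid out (H, W, C); vectors and matrices are
# used for channel descriptors and attention blocks. A forward pass records
# every differentiable op on a tape; ag_backward() walks the tape in reverse
# and accumulates gradients into parameter environments, which persist
# across tapes until ag_zero_grad().

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

ag_node <- function(tape, val, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$bw <- bw
  n$track <- TRUE
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- n
  }
  n
}

#' @noRd
ag_param <- function(val, kh = NULL, kw = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$track <- TRUE
  p$param <- TRUE
  if (!is.null(kh)) p$kh <- kh
  if (!is.null(kw)) p$kw <- kw
  class(p) <- "ag_param"
  p
}

ag_const <- function(val) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$track <- FALSE
  n
}

ag_val <- function(x) if (is.environment(x)) x$val else x

ag_accum <- function(x, g) {
  if (!is.environment(x) || !isTRUE(x$track)) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

ag_collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "ag_param")) {
      out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- convolution ops ----

ag_conv2d <- function(tape, x, w, b) {
  xv <- ag_val(x)
  fc <- cpp_conv2d_fwdcol(xv, w$val, as.numeric(b$val), w$kh, w$kw)
  cin <- dim(xv)[3]
  ag_node(tape, fc$y, function(nd) {
    r <- cpp_conv2d_bwd_col(fc$col, w$val, nd$grad, w$kh, w$kw, cin)
    ag_accum(x, r$gx)
    ag_accum(w, matrix(r$gw, nrow(w$val), ncol(w$val)))
    ag_accum(b, as.numeric(r$gb))
  })
}

ag_deform_conv <- function(tape, x, off, w, b) {
  xv <- ag_val(x)
  offv <- ag_val(off)
  val <- cpp_deform_conv(xv, offv, w$val, as.numeric(b$val), w$kh, w$kw)
  ag_node(tape, val, function(nd) {
    r <- cpp_deform_conv_bwd(xv, offv, w$val, nd$grad, w$kh, w$kw)
    ag_accum(x, r$gx)
    ag_accum(off, r$goff)
    ag_accum(w, matrix(r$gw, nrow(w$val), ncol(w$val)))
    ag_accum(b, as.numeric(r$gb))
  })
}

ag_avgpool2 <- function(tape, x) {
  ag_node(tape, cpp_avgpool2(ag_val(x)), function(nd) {
    ag_accum(x, cpp_avgpool2_bwd(nd$grad))
  })
}

ag_upsample2_bilinear <- function(tape, x) {
  ag_node(tape, cpp_upsample2_bilinear(ag_val(x)), function(nd) {
    ag_accum(x, cpp_upsample2_bilinear_bwd(nd$grad))
  })
}

ag_upsample2 <- function(tape, x) {
  ag_node(tape, cpp_upsample2(ag_val(x)), function(nd) {
    ag_accum(x, cpp_upsample2_bwd(nd$grad))
  })
}

# ---- elementwise ops (any shape; shapes of both operands must match) ----

ag_relu <- function(tape, x) {
  xv <- ag_val(x)
  pos <- (xv > 0) + 0  # numeric mask: avoids logical->double coercion twice
  ag_node(tape, xv * pos, function(nd) ag_accum(x, nd$grad * pos))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-ag_val(x)))
  ag_node(tape, s, function(nd) ag_accum(x, nd$grad * s * (1 - s)))
}

ag_softplus <- function(tape, x) {
  xv <- ag_val(x)
  val <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  attributes(val) <- attributes(xv)
  ag_node(tape, val, function(nd) ag_accum(x, nd$grad / (1 + exp(-xv))))
}

ag_tanh <- function(tape, x) {
  v <- tanh(ag_val(x))
  ag_node(tape, v, function(nd) ag_accum(x, nd$grad * (1 - v * v)))
}

ag_clamp01 <- function(tape, x) {
  xv <- ag_val(x)
  v <- pmin(pmax(xv, 0), 1)
  ag_node(tape, v, function(nd) ag_accum(x, nd$grad * (xv >= 0 & xv <= 1)))
}

ag_abs <- function(tape, x) {
  xv <- ag_val(x)
  ag_node(tape, abs(xv), function(nd) ag_accum(x, nd$grad * sign(xv)))
}

ag_add <- function(tape, x, y) {
  ag_node(tape, ag_val(x) + ag_val(y), function(nd) {
    ag_accum(x, nd$grad)
    ag_accum(y, nd$grad)
  })
}

ag_sub <- function(tape, x, y) {
  ag_node(tape, ag_val(x) - ag_val(y), function(nd) {
    ag_accum(x, nd$grad)
    ag_accum(y, -nd$grad)
  })
}

ag_mul <- function(tape, x, y) {
  xv <- ag_val(x); yv <- ag_val(y)
  ag_node(tape, xv * yv, function(nd) {
    ag_accum(x, nd$grad * yv)
    ag_accum(y, nd$grad * xv)
  })
}

ag_add_const <- function(tape, x, k) {
  ag_node(tape, ag_val(x) + k, function(nd) ag_accum(x, nd$grad))
}

ag_mul_const <- function(tape, x, k) {
  ag_node(tape, ag_val(x) * k, function(nd) ag_accum(x, nd$grad * k))
}

# scalar (length-1 parameter) times array
ag_scalar_mul <- function(tape, x, s) {
  xv <- ag_val(x); sv <- as.numeric(ag_val(s))
  ag_node(tape, xv * sv, function(nd) {
    ag_accum(x, nd$grad * sv)
    ag_accum(s, sum(nd$grad * xv))
  })
}

# ---- channel broadcasting ----

# x: (H, W, C); a: (H, W, 1) broadcast over channels
ag_mul_bchan <- function(tape, x, a) {
  xv <- ag_val(x); av <- ag_val(a)
  d <- dim(xv); hw <- d[1] * d[2]
  val <- xv * as.vector(av)
  ag_node(tape, val, function(nd) {
    ag_accum(x, nd$grad * as.vector(av))
    ga <- array(rowSums(matrix(nd$grad * xv, hw, d[3])), c(d[1], d[2], 1))
    ag_accum(a, ga)
  })
}

# x / s with s: (H, W, 1)
ag_div_bchan <- function(tape, x, s) {
  xv <- ag_val(x); sv <- ag_val(s)
  d <- dim(xv); hw <- d[1] * d[2]
  val <- xv / as.vector(sv)
  ag_node(tape, val, function(nd) {
    ag_accum(x, nd$grad / as.vector(sv))
    gs <- -rowSums(matrix(nd$grad * xv, hw, d[3])) / as.vector(sv)^2
    ag_accum(s, array(gs, c(d[1], d[2], 1)))
  })
}

# per-channel gates: s is a length-C vector node
ag_scale_channels <- function(tape, x, s) {
  xv <- ag_val(x); sv <- as.numeric(ag_val(s))
  d <- dim(xv); hw <- d[1] * d[2]
  val <- xv * rep(sv, each = hw)
  ag_node(tape, val, function(nd) {
    ag_accum(x, nd$grad * rep(sv, each = hw))
    ag_accum(s, colSums(matrix(nd$grad * xv, hw, d[3])))
  })
}

# ---- reductions / descriptors ----

ag_mean_all <- function(tape, x) {
  xv <- ag_val(x)
  n <- length(xv)
  ag_node(tape, mean(xv), function(nd) {
    g <- array(nd$grad / n, dim(xv) %||% length(xv))
    ag_accum(x, g)
  })
}

ag_chan_sum <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  val <- array(rowSums(matrix(xv, hw, d[3])), c(d[1], d[2], 1))
  ag_node(tape, val, function(nd) {
    ag_accum(x, array(rep(as.vector(nd$grad), d[3]), d))
  })
}

ag_chan_mean <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  val <- array(rowMeans(matrix(xv, hw, d[3])), c(d[1], d[2], 1))
  ag_node(tape, val, function(nd) {
    ag_accum(x, array(rep(as.vector(nd$grad) / d[3], d[3]), d))
  })
}

ag_chan_max <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  m <- matrix(xv, hw, d[3])
  idx <- max.col(m, ties.method = "first")
  val <- array(m[cbind(seq_len(hw), idx)], c(d[1], d[2], 1))
  ag_node(tape, val, function(nd) {
    g <- matrix(0, hw, d[3])
    g[cbind(seq_len(hw), idx)] <- as.vector(nd$grad)
    ag_accum(x, array(g, d))
  })
}

# population variance across channels, per pixel -> (H, W, 1)
ag_chan_var <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  m <- matrix(xv, hw, d[3])
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu * mu
  ag_node(tape, array(v, c(d[1], d[2], 1)), function(nd) {
    g <- 2 * (m - mu) / d[3] * as.vector(nd$grad)
    ag_accum(x, array(g, d))
  })
}

ag_gap <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  ag_node(tape, colMeans(matrix(xv, hw, d[3])), function(nd) {
    ag_accum(x, array(rep(nd$grad / hw, each = hw), d))
  })
}

ag_gmp <- function(tape, x) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]
  m <- matrix(xv, hw, d[3])
  idx <- apply(m, 2, which.max)
  ag_node(tape, m[cbind(idx, seq_len(d[3]))], function(nd) {
    g <- matrix(0, hw, d[3])
    g[cbind(idx, seq_len(d[3]))] <- nd$grad
    ag_accum(x, array(g, d))
  })
}

ag_dense <- function(tape, v, w, b = NULL) {
  vv <- as.numeric(ag_val(v))
  val <- drop(vv %*% w$val)
  if (!is.null(b)) val <- val + as.numeric(b$val)
  ag_node(tape, val, function(nd) {
    g <- as.numeric(nd$grad)
    ag_accum(v, drop(w$val %*% g))
    ag_accum(w, outer(vv, g))
    if (!is.null(b)) ag_accum(b, g)
  })
}

ag_slice_chan <- function(tape, x, k) {
  xv <- ag_val(x); d <- dim(xv)
  val <- xv[, , k, drop = FALSE]
  ag_node(tape, val, function(nd) {
    g <- array(0, d)
    g[, , k] <- nd$grad
    ag_accum(x, g)
  })
}

ag_concat_c <- function(tape, xs) {
  vals <- lapply(xs, ag_val)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  val <- array(unlist(vals, use.names = FALSE), c(d1[1], d1[2], sum(cs)))
  ends <- cumsum(cs)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(tape, val, function(nd) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], nd$grad[, , starts[i]:ends[i], drop = FALSE])
    }
  })
}

# ---- matrix ops for attention blocks ----

ag_matmul <- function(tape, a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(tape, av %*% bv, function(nd) {
    ag_accum(a, nd$grad %*% t(bv))
    ag_accum(b, t(av) %*% nd$grad)
  })
}

# dense layer applied to a tokens x C matrix: X %*% W (+ b per column)
ag_matdense <- function(tape, x, w, b = NULL) {
  xv <- ag_val(x)
  val <- xv %*% w$val
  if (!is.null(b)) val <- sweep(val, 2, as.numeric(b$val), "+")
  ag_node(tape, val, function(nd) {
    ag_accum(x, nd$grad %*% t(w$val))
    ag_accum(w, t(xv) %*% nd$grad)
    if (!is.null(b)) ag_accum(b, colSums(nd$grad))
  })
}

ag_transpose <- function(tape, x) {
  ag_node(tape, t(ag_val(x)), function(nd) ag_accum(x, t(nd$grad)))
}

ag_softmax_rows <- function(tape, x) {
  xv <- ag_val(x)
  e <- exp(xv - apply(xv, 1, max))
  s <- e / rowSums(e)
  ag_node(tape, s, function(nd) {
    g <- s * (nd$grad - rowSums(nd$grad * s))
    ag_accum(x, g)
  })
}

ag_add_mat <- function(tape, x, m) {
  # add a (learnable) matrix parameter to a same-shape matrix node
  ag_node(tape, ag_val(x) + ag_val(m), function(nd) {
    ag_accum(x, nd$grad)
    ag_accum(m, nd$grad)
  })
}

# extract a W x W window starting at (ri, cj) as a (W*W) x C token matrix
ag_extract_window <- function(tape, x, ri, cj, w) {
  xv <- ag_val(x); d <- dim(xv)
  rows <- ri:(ri + w - 1); cols <- cj:(cj + w - 1)
  sub <- xv[rows, cols, , drop = FALSE]
  ag_node(tape, matrix(sub, w * w, d[3]), function(nd) {
    g <- array(0, d)
    g[rows, cols, ] <- array(nd$grad, c(w, w, d[3]))
    ag_accum(x, g)
  })
}

# inverse of ag_extract_window over a full non-overlapping tiling
ag_merge_windows <- function(tape, parts, h, w, c, win) {
  val <- array(0, c(h, w, c))
  pos <- list()
  k <- 0
  for (cj in seq(1, w, by = win)) {
    for (ri in seq(1, h, by = win)) {
      k <- k + 1
      val[ri:(ri + win - 1), cj:(cj + win - 1), ] <-
        array(ag_val(parts[[k]]), c(win, win, c))
      pos[[k]] <- c(ri, cj)
    }
  }
  ag_node(tape, val, function(nd) {
    for (k in seq_along(parts)) {
      ri <- pos[[k]][1]; cj <- pos[[k]][2]
      g <- nd$grad[ri:(ri + win - 1), cj:(cj + win - 1), , drop = FALSE]
      ag_accum(parts[[k]], matrix(g, win * win, c))
    }
  })
}

# ---- group normalization ----

ag_groupnorm <- function(tape, x, gamma, beta, groups, eps = 1e-5) {
  xv <- ag_val(x); d <- dim(xv); hw <- d[1] * d[2]; C <- d[3]
  stopifnot(C %% groups == 0)
  ng <- hw * C / groups  # elements per group
  gm <- matrix(xv, ng, groups)
  mu <- colMeans(gm)
  sdv <- sqrt(colMeans(gm * gm) - mu * mu + eps)
  mu_e <- rep(mu, each = ng); sd_e <- rep(sdv, each = ng)
  xhat <- (as.vector(xv) - mu_e) / sd_e
  gv <- as.numeric(ag_val(gamma)); bv <- as.numeric(ag_val(beta))
  g_e <- rep(gv, each = hw)
  val <- array(xhat * g_e + rep(bv, each = hw), d)
  ag_node(tape, val, function(nd) {
    gy <- as.vector(nd$grad)
    gyx <- gy * xhat
    ag_accum(gamma, colSums(matrix(gyx, hw, C)))
    ag_accum(beta, colSums(matrix(gy, hw, C)))
    dxhat <- gy * g_e
    mh <- colMeans(matrix(dxhat, ng, groups))
    mx <- colMeans(matrix(dxhat * xhat, ng, groups))
    dx <- (dxhat - rep(mh, each = ng) - xhat * rep(mx, each = ng)) / sd_e
    ag_accum(x, array(dx, d))
  })
}

# ---- loss heads (closed-form gradients) ----

ag_dice_loss <- function(tape, pred, target, eps = 1) {
  pv <- as.vector(ag_val(pred)); tv <- as.vector(target)
  spt <- sum(pv * tv); sp <- sum(pv); st <- sum(tv)
  den <- sp + st + eps
  val <- 1 - (2 * spt + eps) / den
  ag_node(tape, val, function(nd) {
    g <- -(2 * tv * den - (2 * spt + eps)) / den^2
    ag_accum(pred, array(nd$grad * g, dim(ag_val(pred))))
  })
}

ag_focal_loss <- function(tape, pred, target, gamma = 2, alpha_f = 0.25,
                          eps = 1e-7) {
  pv0 <- as.vector(ag_val(pred))
  clipped <- pv0 < eps | pv0 > 1 - eps
  p <- pmin(pmax(pv0, eps), 1 - eps)
  y <- as.vector(target)
  n <- length(p)
  lfg <- -alpha_f * (1 - p)^gamma * log(p)
  lbg <- -(1 - alpha_f) * p^gamma * log(1 - p)
  val <- mean(ifelse(y > 0.5, lfg, lbg))
  ag_node(tape, val, function(nd) {
    dfg <- -alpha_f * (-gamma * (1 - p)^(gamma - 1) * log(p) + (1 - p)^gamma / p)
    dbg <- -(1 - alpha_f) * (gamma * p^(gamma - 1) * log(1 - p) - p^gamma / (1 - p))
    g <- ifelse(y > 0.5, dfg, dbg) / n
    g[clipped] <- 0
    ag_accum(pred, array(nd$grad * g, dim(ag_val(pred))))
  })
}

ag_boundary_loss <- function(tape, pred, phi) {
  pv <- ag_val(pred)
  n <- length(pv)
  phv <- as.vector(phi)
  val <- sum(as.vector(pv) * phv) / n
  ag_node(tape, val, function(nd) {
    ag_accum(pred, array(nd$grad * phv / n, dim(pv)))
  })
}

# Evidential digamma loss; alpha: (H, W, K), target_fg: binary (H, W) with
# 1 = foreground = class 2 by package convention (class 1 is background).
ag_edl_loss <- function(tape, alpha, target_fg) {
  av <- ag_val(alpha); d <- dim(av); hw <- d[1] * d[2]; K <- d[3]
  m <- matrix(av, hw, K)
  s <- rowSums(m)
  k_true <- ifelse(as.vector(target_fg) > 0.5, 2L, 1L)
  a_true <- m[cbind(seq_len(hw), k_true)]
  val <- mean(digamma(s) - digamma(a_true))
  ag_node(tape, val, function(nd) {
    g <- matrix(trigamma(s), hw, K)
    g[cbind(seq_len(hw), k_true)] <-
      g[cbind(seq_len(hw), k_true)] - trigamma(a_true)
    ag_accum(alpha, array(nd$grad * g / hw, d))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- AdamW ----

ag_adamw_step <- function(params, lr, weight_decay = 0, t = 1,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    if (weight_decay > 0 && !isTRUE(p$no_decay)) {
      p$val <- p$val - lr * weight_decay * p$val
    }
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# ---- initializers ----

he_conv_param <- function(kh, kw, cin, cout, zero = FALSE) {
  fan_in <- kh * kw * cin
  w <- if (zero) {
    matrix(0, kh * kw * cin, cout)
  } else {
    matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
           kh * kw * cin, cout)
  }
  ag_param(w, kh = kh, kw = kw)
}

bias_param <- function(n, value = 0) {
  p <- ag_param(rep(value, n))
  p$no_decay <- TRUE
  p
}

dense_param <- function(cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, cin, cout) else
    matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  ag_param(w)
}

scalar_param <- function(value = 0) {
  p <- ag_param(value)
  p$no_decay <- TRUE
  p
}
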