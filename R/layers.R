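# Layer constructors and forward functions built on the autodiff tape.
# new_* functions allocate parameters (caller controls the RNG seed);
# fwd_* functions record the forward pass on a tape and return a node.

gn_groups <- function(c) {
  for (g in c(8, 4, 2, 1)) if (c %% g == 0) return(g)
  1
}

new_conv <- function(cin, cout, k = 3, zero = FALSE) {
  list(w = he_conv_param(k, k, cin, cout, zero = zero), b = bias_param(cout))
}

fwd_conv <- function(tape, x, p) ag_conv2d(tape, x, p$w, p$b)

new_gn <- function(c) {
  g <- ag_param(rep(1, c)); g$no_decay <- TRUE
  b <- ag_param(rep(0, c)); b$no_decay <- TRUE
  list(gamma = g, beta = b, groups = gn_groups(c))
}

fwd_gn <- function(tape, x, p) ag_groupnorm(tape, x, p$gamma, p$beta, p$groups)

new_conv_block <- function(cin, cout, k = 3) {
  list(c1 = new_conv(cin, cout, k), n1 = new_gn(cout),
       c2 = new_conv(cout, cout, k), n2 = new_gn(cout))
}

fwd_conv_block <- function(tape, x, p) {
  h <- ag_relu(tape, fwd_gn(tape, fwd_conv(tape, x, p$c1), p$n1))
  ag_relu(tape, fwd_gn(tape, fwd_conv(tape, h, p$c2), p$n2))
}

# ---- squeeze-and-excitation ----

new_se <- function(c, reduction) {
  stopifnot(c %% reduction == 0)
  list(fc1 = dense_param(c, c / reduction), b1 = bias_param(c / reduction),
       fc2 = dense_param(c / reduction, c), b2 = bias_param(c))
}

fwd_se <- function(tape, x, p) {
  z <- ag_gap(tape, x)
  z <- ag_relu(tape, ag_dense(tape, z, p$fc1, p$b1))
  g <- ag_sigmoid(tape, ag_dense(tape, z, p$fc2, p$b2))
  ag_scale_channels(tape, x, g)
}

# ---- CBAM: channel attention then spatial attention ----

new_cbam <- function(c, reduction = 4, spatial_k = 7) {
  r <- max(1, c %/% reduction)
  list(fc1 = dense_param(c, r), fc2 = dense_param(r, c),
       sp = new_conv(2, 1, spatial_k))
}

fwd_cbam <- function(tape, x, p) {
  za <- ag_dense(tape, ag_relu(tape, ag_dense(tape, ag_gap(tape, x), p$fc1)), p$fc2)
  zm <- ag_dense(tape, ag_relu(tape, ag_dense(tape, ag_gmp(tape, x), p$fc1)), p$fc2)
  gc <- ag_sigmoid(tape, ag_add(tape, za, zm))
  xc <- ag_scale_channels(tape, x, gc)
  sp <- ag_concat_c(tape, list(ag_chan_mean(tape, xc), ag_chan_max(tape, xc)))
  gs <- ag_sigmoid(tape, fwd_conv(tape, sp, p$sp))
  ag_mul_bchan(tape, xc, gs)
}

# ---- windowed attention ----

new_window_attn <- function(c, win) {
  list(wq = dense_param(c, c), wk = dense_param(c, c), wv = dense_param(c, c),
       wo = dense_param(c, c),
       pos = {
         p <- ag_param(matrix(0, win * win, win * win)); p$no_decay <- TRUE; p
       },
       win = win)
}

# Self-attention computed independently in non-overlapping win x win windows.
fwd_window_self_attn <- function(tape, x, p) {
  d <- dim(ag_val(x)); h <- d[1]; w <- d[2]; c <- d[3]; win <- p$win
  stopifnot(h %% win == 0, w %% win == 0)
  scale <- 1 / sqrt(c)
  parts <- list(); k <- 0
  for (cj in seq(1, w, by = win)) {
    for (ri in seq(1, h, by = win)) {
      k <- k + 1
      tok <- ag_extract_window(tape, x, ri, cj, win)
      q <- ag_matdense(tape, tok, p$wq)
      ke <- ag_matdense(tape, tok, p$wk)
      v <- ag_matdense(tape, tok, p$wv)
      sc <- ag_mul_const(tape, ag_matmul(tape, q, ag_transpose(tape, ke)), scale)
      a <- ag_softmax_rows(tape, ag_add_mat(tape, sc, p$pos))
      parts[[k]] <- ag_matdense(tape, ag_matmul(tape, a, v), p$wo)
    }
  }
  ag_merge_windows(tape, parts, h, w, c, win)
}

# Cross-attention within windows: queries from `qsrc`, keys/values from `kvsrc`.
new_window_cross_attn <- function(cq, ckv, c, win) {
  list(wq = dense_param(cq, c), wk = dense_param(ckv, c), wv = dense_param(ckv, c),
       wo = dense_param(c, c), win = win)
}

fwd_window_cross_attn <- function(tape, qsrc, kvsrc, p) {
  d <- dim(ag_val(qsrc)); h <- d[1]; w <- d[2]; win <- p$win
  c <- ncol(p$wq$val)
  scale <- 1 / sqrt(c)
  parts <- list(); k <- 0
  for (cj in seq(1, w, by = win)) {
    for (ri in seq(1, h, by = win)) {
      k <- k + 1
      qt <- ag_extract_window(tape, qsrc, ri, cj, win)
      kt <- ag_extract_window(tape, kvsrc, ri, cj, win)
      q <- ag_matdense(tape, qt, p$wq)
      ke <- ag_matdense(tape, kt, p$wk)
      v <- ag_matdense(tape, kt, p$wv)
      sc <- ag_mul_const(tape, ag_matmul(tape, q, ag_transpose(tape, ke)), scale)
      a <- ag_softmax_rows(tape, sc)
      parts[[k]] <- ag_matdense(tape, ag_matmul(tape, a, v), p$wo)
    }
  }
  ag_merge_windows(tape, parts, h, w, c, win)
}

# pointwise FFN with expansion ratio
new_ffn <- function(cin, cout, expansion = 2) {
  hid <- max(4, round(cin * expansion))
  list(c1 = new_conv(cin, hid, 1), c2 = new_conv(hid, cout, 1))
}

fwd_ffn <- function(tape, x, p) {
  fwd_conv(tape, ag_relu(tape, fwd_conv(tape, x, p$c1)), p$c2)
}

fwd_upsample_to <- function(tape, x, target_hw) {
  while (dim(ag_val(x))[1] < target_hw) x <- ag_upsample2(tape, x)
  x
}
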