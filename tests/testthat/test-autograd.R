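# Autodiff tape: every composite op is validated against central finite
# differences through a scalar loss.

test_that("convolution ops are correct and differentiable", {
  withr::with_seed(1, {
    x0 <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
    w <- espdnet:::he_conv_param(3, 3, 2, 3)
    b <- espdnet:::bias_param(3, 0.1)
    check_grad(function(tp, x) {
      y <- espdnet:::ag_conv2d(tp, x, w, b)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0)

    # deformable conv with zero offsets equals the standard conv
    off0 <- array(0, c(6, 5, 18))
    tp <- ag_tape()
    y1 <- espdnet:::ag_conv2d(tp, ag_const(x0), w, b)
    y2 <- espdnet:::ag_deform_conv(tp, ag_const(x0), ag_const(off0), w, b)
    expect_equal(ag_val(y1), ag_val(y2), tolerance = 1e-12)

    # gradients through data, offsets and weights
    offr <- array(rnorm(6 * 5 * 18, sd = 0.3), c(6, 5, 18))
    check_grad(function(tp, x) {
      y <- espdnet:::ag_deform_conv(tp, x, ag_const(offr), w, b)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0)
    check_grad(function(tp, o) {
      y <- espdnet:::ag_deform_conv(tp, ag_const(x0), o, w, b)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, offr)
  })
})

test_that("pooling, upsampling and broadcasting ops differentiate", {
  withr::with_seed(2, {
    x0 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    for (op in list(espdnet:::ag_avgpool2, espdnet:::ag_upsample2,
                    espdnet:::ag_relu, espdnet:::ag_sigmoid,
                    espdnet:::ag_softplus, espdnet:::ag_tanh,
                    espdnet:::ag_abs)) {
      check_grad(function(tp, x) {
        y <- op(tp, x)
        espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
      }, x0)
    }
    a0 <- array(rnorm(8 * 8 * 1), c(8, 8, 1))
    check_grad(function(tp, x) {
      y <- espdnet:::ag_mul_bchan(tp, x, ag_const(a0))
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0)
    check_grad(function(tp, a) {
      y <- espdnet:::ag_mul_bchan(tp, ag_const(x0), a)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, a0)
    s0 <- array(2 + rexp(64), c(8, 8, 1))
    check_grad(function(tp, s) {
      y <- espdnet:::ag_div_bchan(tp, ag_const(abs(x0) + 1), s)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, s0)
    check_grad(function(tp, x) {
      y <- espdnet:::ag_chan_var(tp, x)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0)
  })
})

test_that("descriptor and dense ops differentiate", {
  withr::with_seed(3, {
    x0 <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    w <- espdnet:::dense_param(4, 3)
    b <- espdnet:::bias_param(3)
    check_grad(function(tp, x) {
      v <- espdnet:::ag_gap(tp, x)
      z <- espdnet:::ag_dense(tp, v, w, b)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, z, z))
    }, x0)
    check_grad(function(tp, x) {
      v <- espdnet:::ag_gmp(tp, x)
      z <- espdnet:::ag_dense(tp, v, w, b)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, z, z))
    }, x0, eps = 1e-7)  # max is piecewise; small eps avoids argmax flips
    check_grad(function(tp, x) {
      y <- espdnet:::ag_concat_c(tp, list(espdnet:::ag_chan_mean(tp, x),
                                          espdnet:::ag_chan_max(tp, x)))
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0, eps = 1e-7)
  })
})

test_that("windowed self- and cross-attention differentiate", {
  withr::with_seed(4, {
    x0 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    attn <- espdnet:::new_window_attn(4, 4)
    check_grad(function(tp, x) {
      y <- espdnet:::fwd_window_self_attn(tp, x, attn)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, x0, tol = 1e-4)

    q0 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    kv0 <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
    ca <- espdnet:::new_window_cross_attn(3, 6, 4, 4)
    check_grad(function(tp, q) {
      y <- espdnet:::fwd_window_cross_attn(tp, q, ag_const(kv0), ca)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, q0, tol = 1e-4)
    check_grad(function(tp, kv) {
      y <- espdnet:::fwd_window_cross_attn(tp, ag_const(q0), kv, ca)
      espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, y, y))
    }, kv0, tol = 1e-4)
  })
})

test_that("windowed attention is invariant to content outside the window", {
  withr::with_seed(5, {
    x0 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    attn <- espdnet:::new_window_attn(4, 4)
    tp <- ag_tape()
    y0 <- ag_val(espdnet:::fwd_window_self_attn(tp, ag_const(x0), attn))
    x1 <- x0
    x1[5:8, 5:8, ] <- rnorm(4 * 4 * 4)  # perturb a different window
    y1 <- ag_val(espdnet:::fwd_window_self_attn(tp, ag_const(x1), attn))
    expect_equal(y0[1:4, 1:4, ], y1[1:4, 1:4, ], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(y0[5:8, 5:8, ], y1[5:8, 5:8, ])))
  })
})

test_that("AdamW takes finite steps and decays weights decoupled", {
  withr::with_seed(6, {
    p <- ag_param(c(1, -2, 3))
    p$grad <- c(0.1, -0.2, 0.3)
    espdnet:::ag_adamw_step(list(p), lr = 0.1, weight_decay = 0.5, t = 1)
    expect_true(all(is.finite(p$val)))
    # decay shrinks magnitudes; Adam step moves against the gradient sign
    expect_lt(p$val[1], 1)
    expect_gt(p$val[2], -2)
  })
})
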