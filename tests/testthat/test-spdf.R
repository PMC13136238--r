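# Semantic-probabilistic dual-path fusion bottleneck.

make_spdf <- function(c2 = 8, c3 = 16, cbott = 12, seed = 1) {
  withr::with_seed(seed, espdnet:::new_spdf(c2, c3, cbott, spdf_config()))
}

test_that("semantic path preserves shape; zero offsets equal plain conv", {
  withr::with_seed(1, {
    sp <- make_spdf()
    s2 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
    y <- ag_val(espdnet:::fwd_spdf_semantic(ag_tape(), ag_const(s2), sp))
    expect_equal(dim(y), c(8, 8, 8))

    # offset-predicting convs are zero-initialized, so the first deformable
    # conv equals an ordinary convolution with the same kernel
    tp <- ag_tape()
    off <- espdnet:::fwd_conv(tp, ag_const(s2), sp$off1)
    expect_true(all(ag_val(off) == 0))
    d1 <- espdnet:::ag_deform_conv(tp, ag_const(s2), off, sp$d1$w, sp$d1$b)
    c1 <- espdnet:::ag_conv2d(tp, ag_const(s2), sp$d1$w, sp$d1$b)
    expect_equal(ag_val(d1), ag_val(c1), tolerance = 1e-12)
  })
})

test_that("zero-offset deformable conv is translation-equivariant inside", {
  withr::with_seed(9, {
    sp <- make_spdf()
    x <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
    xs <- array(0, c(10, 10, 8))
    xs[2:10, , ] <- x[1:9, , ]  # shift down by one pixel
    tp <- ag_tape()
    off <- ag_const(array(0, c(10, 10, 18)))
    y <- ag_val(espdnet:::ag_deform_conv(tp, ag_const(x), off,
                                         sp$d1$w, sp$d1$b))
    ys <- ag_val(espdnet:::ag_deform_conv(tp, ag_const(xs), off,
                                          sp$d1$w, sp$d1$b))
    # interior rows (away from the zero-padded border) shift identically
    expect_equal(ys[3:9, 2:9, ], y[2:8, 2:9, ], tolerance = 1e-12)
  })
})

test_that("probabilistic path: windowed attention with variance density", {
  withr::with_seed(2, {
    sp <- make_spdf()
    s3 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
    pr <- espdnet:::fwd_spdf_prob(ag_tape(), ag_const(s3), sp)
    expect_equal(dim(ag_val(pr$f_prob)), c(8, 8, 8))
    expect_equal(dim(ag_val(pr$a_prob)), c(8, 8, 1))

    # attention-score bookkeeping: non-overlapping W x W windows mean
    # N * W^2 score entries instead of N^2 for full attention
    n_tokens <- 8 * 8
    win <- spdf_config()$window
    n_windows <- n_tokens / win^2
    expect_equal(n_windows * (win^2)^2, n_tokens * win^2)
    expect_equal(n_tokens * win^2, 1024)  # vs 4096 for full attention

    # channel-constant features have zero variance
    xc <- array(rep(rnorm(16), times = 16), c(4, 4, 16))
    v <- ag_val(espdnet:::ag_chan_var(ag_tape(), ag_const(xc)))
    expect_equal(v, array(0, c(4, 4, 1)), tolerance = 1e-12)
  })
})

test_that("probability-guided fusion follows the stated modulation", {
  tp <- ag_tape()
  f_sem <- ag_const(array(2, c(4, 4, 3)))
  a_prob <- ag_const(array(0, c(4, 4, 1)))

  # alpha = 0: exact identity
  y0 <- espdnet:::fwd_probability_guided_fusion(tp, f_sem, a_prob,
                                                espdnet:::scalar_param(0))
  expect_identical(ag_val(y0), ag_val(f_sem))

  # alpha = 1, A_prob = 0: 2 * (1 + 0.5) = 3
  y1 <- espdnet:::fwd_probability_guided_fusion(tp, f_sem, a_prob,
                                                espdnet:::scalar_param(1))
  expect_equal(ag_val(y1), array(3, c(4, 4, 3)), tolerance = 1e-12)

  # A_prob -> -Inf limit: sigmoid -> 0, output -> F_sem
  am <- ag_const(array(-1e4, c(4, 4, 1)))
  ym <- espdnet:::fwd_probability_guided_fusion(tp, f_sem, am,
                                                espdnet:::scalar_param(1))
  expect_equal(ag_val(ym), ag_val(f_sem), tolerance = 1e-12)

  # multiplier bounded in [1, 1 + alpha] for alpha >= 0
  withr::with_seed(3, {
    ar <- ag_const(array(rnorm(16, sd = 5), c(4, 4, 1)))
    y <- ag_val(espdnet:::fwd_probability_guided_fusion(
      tp, ag_const(array(1, c(4, 4, 1))), ar, espdnet:::scalar_param(0.7)))
    expect_true(all(y >= 1 & y <= 1.7))
  })
})

test_that("fusion: residual identity with zero FFN, both paths live", {
  withr::with_seed(4, {
    sp <- make_spdf()
    s2 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
    s3 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))

    # zero FFN output layer: s_final reduces to the projected residual
    sp0 <- make_spdf(seed = 5)
    sp0$ffn$c2$w$val[] <- 0
    sp0$ffn$c2$b$val[] <- 0
    tp <- ag_tape()
    out <- espdnet:::fwd_spdf(tp, ag_const(s2), ag_const(s3), sp0)
    res <- espdnet:::fwd_conv(tp, ag_const(s2), sp0$resproj)
    expect_equal(ag_val(out$s_final), ag_val(res), tolerance = 1e-12)

    # output channel count equals the configured bottleneck width
    out2 <- espdnet:::fwd_spdf(ag_tape(), ag_const(s2), ag_const(s3), sp)
    expect_equal(dim(ag_val(out2$s_final)), c(8, 8, 12))

    # gradients reach parameters of both paths
    tp <- ag_tape()
    o <- espdnet:::fwd_spdf(tp, ag_const(s2), ag_const(s3), sp)
    L <- espdnet:::ag_mean_all(tp, espdnet:::ag_mul(tp, o$s_final, o$s_final))
    espdnet:::ag_backward(tp, L)
    expect_gt(sum(abs(sp$d1$w$grad)), 0)      # semantic path
    expect_gt(sum(abs(sp$attn$wq$grad)), 0)   # probabilistic path
  })
})
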