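# Loss functions: closed-form values, invariants, and agreement between
# the pure implementations and the differentiable tape ops.

test_that("dice loss matches closed forms", {
  t <- matrix(0, 10, 10); t[2:5, 2:5] <- 1
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-12)

  # disjoint masks of area 100 each on a large grid
  p <- matrix(0, 30, 30); p[1:10, 1:10] <- 1
  t2 <- matrix(0, 30, 30); t2[20:29, 20:29] <- 1
  expect_equal(dice_loss(p, t2), 1 - 1 / 201, tolerance = 1e-12)

  # pred covers half of a 4-pixel target plus 2 extra pixels (eps -> 0)
  t3 <- matrix(0, 6, 6); t3[2, 2:5] <- 1
  p3 <- matrix(0, 6, 6); p3[2, 2:3] <- 1; p3[5, 1:2] <- 1
  expect_equal(dice_loss(p3, t3, eps = 1e-9), 0.5, tolerance = 1e-6)
})

test_that("focal loss matches closed forms", {
  # perfectly classified pixels contribute ~0
  t <- matrix(1, 4, 4)
  expect_lt(focal_loss(matrix(1, 4, 4), t), 1e-5)

  # p_t = 0.5 foreground, gamma 2, alpha 0.25
  expect_equal(focal_loss(matrix(0.5, 3, 3), matrix(1, 3, 3),
                          gamma = 2, alpha_f = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-9)

  # gamma = 0, alpha = 0.5 reduces to half the binary cross-entropy
  withr::with_seed(1, {
    p <- matrix(runif(64, 0.05, 0.95), 8, 8)
    y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    expect_equal(focal_loss(p, y, gamma = 0, alpha_f = 0.5), 0.5 * bce,
                 tolerance = 1e-9)
  })
})

test_that("boundary loss has the stated sign structure", {
  t <- matrix(0, 9, 9); t[3:7, 3:7] <- 1
  expect_equal(boundary_loss(matrix(0, 9, 9), t), 0)
  expect_lt(boundary_loss(t, t), 0)     # mass only on the interior
  expect_gt(boundary_loss(1 - t, t), 0) # mass only outside

  # empty target: documented degenerate rule mean(pred) * diagonal
  p <- matrix(0.5, 4, 4)
  expect_equal(boundary_loss(p, matrix(0, 4, 4)), 0.5 * sqrt(32))
})

test_that("signed distance map is negative inside, zero on boundary", {
  t <- matrix(0, 9, 9); t[3:7, 3:7] <- 1
  phi <- signed_distance_map(t)
  expect_equal(phi[5, 5], -2)  # center of a 5x5 square
  expect_equal(phi[3, 5], 0)   # boundary pixel
  expect_equal(phi[1, 5], 2)   # two rows outside
  expect_true(all(phi[t == 0] > 0))
})

test_that("liver loss is the stated weighted sum", {
  t <- matrix(0, 12, 12); t[4:8, 4:8] <- 1
  withr::with_seed(2, p <- matrix(runif(144), 12, 12))
  lv <- liver_loss(p, t, loss_config(alpha_w = 1, beta_w = 0, gamma_w = 0))
  expect_equal(lv$liver, lv$dice)
  lv0 <- liver_loss(p, t, loss_config(alpha_w = 0, beta_w = 0, gamma_w = 0))
  expect_equal(lv0$liver, 0)
  # weighted-sum arithmetic on fixed components
  cfg <- loss_config(alpha_w = 1, beta_w = 1, gamma_w = 0.5)
  expect_equal(cfg$alpha_w * 0.2 + cfg$beta_w * 0.04 + cfg$gamma_w * (-0.1),
               0.19)
  lv2 <- liver_loss(p, t, cfg)
  expect_equal(lv2$liver, lv2$dice + lv2$focal + 0.5 * lv2$boundary,
               tolerance = 1e-12)
})

test_that("EDL loss matches the digamma recurrence", {
  # psi(x + 1) = psi(x) + 1/x gives 1, 0.5, 0.1 for these cases
  y <- matrix(1, 1, 1)  # foreground
  a <- function(fg, bg) array(c(bg, fg), c(1, 1, 2))
  expect_equal(edl_loss(a(1, 1), y), 1, tolerance = 1e-6)
  expect_equal(edl_loss(a(2, 1), y), 0.5, tolerance = 1e-6)
  expect_equal(edl_loss(a(10, 1), y), 0.1, tolerance = 1e-6)
  expect_error(edl_loss(a(0.5, 1), y), ">= 1")
})

test_that("EDL loss is non-negative and rewards true-class evidence", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      a <- array(1 + rexp(2 * 9), c(3, 3, 2))
      y <- matrix(rbinom(9, 1, 0.5), 3, 3)
      l0 <- edl_loss(a, y)
      expect_gte(l0, 0)
      # adding true-class evidence decreases the loss, wrong-class increases
      i <- sample(3, 1); j <- sample(3, 1)
      kt <- if (y[i, j] > 0.5) 2 else 1
      up <- a; up[i, j, kt] <- up[i, j, kt] + 0.5
      down <- a; down[i, j, 3 - kt] <- down[i, j, 3 - kt] + 0.5
      expect_lt(edl_loss(up, y), l0)
      expect_gt(edl_loss(down, y), l0)
    }
  })
})

test_that("total loss anneals the evidential term linearly", {
  cfg <- loss_config(edl_weight = 1, edl_anneal_epochs = 10)
  expect_equal(total_loss(0.7, 0.3, epoch = 0, cfg), 0.7)
  expect_equal(total_loss(0.7, 0.3, epoch = 10, cfg), 1.0)
  expect_equal(total_loss(0.7, 0.3, epoch = 25, cfg), 1.0)
  expect_equal(edl_anneal(5, cfg), 0.5)
})

test_that("tape loss ops agree with the pure implementations", {
  withr::with_seed(4, {
    t <- matrix(rbinom(256, 1, 0.2), 16, 16)
    p <- matrix(runif(256, 0.02, 0.98), 16, 16)
    tgt <- array(t, c(16, 16, 1))
    pn <- array(p, c(16, 16, 1))
    tape <- ag_tape()
    expect_equal(ag_val(espdnet:::ag_dice_loss(tape, ag_const(pn), tgt)),
                 dice_loss(p, t), tolerance = 1e-12)
    expect_equal(ag_val(espdnet:::ag_focal_loss(tape, ag_const(pn), tgt,
                                                2, 0.25)),
                 focal_loss(p, t, 2, 0.25), tolerance = 1e-12)
    phi <- signed_distance_map(t)
    expect_equal(ag_val(espdnet:::ag_boundary_loss(tape, ag_const(pn),
                                                   array(phi, dim(tgt)))),
                 boundary_loss(p, t), tolerance = 1e-12)
    al <- array(1 + rexp(512), c(16, 16, 2))
    expect_equal(ag_val(espdnet:::ag_edl_loss(tape, ag_const(al), t)),
                 edl_loss(al, t), tolerance = 1e-12)
  })
})

test_that("loss tape ops have correct gradients", {
  withr::with_seed(5, {
    t <- matrix(rbinom(36, 1, 0.3), 6, 6)
    tgt <- array(t, c(6, 6, 1))
    p0 <- array(runif(36, 0.1, 0.9), c(6, 6, 1))
    check_grad(function(tp, x) espdnet:::ag_dice_loss(tp, x, tgt), p0)
    check_grad(function(tp, x) espdnet:::ag_focal_loss(tp, x, tgt, 2, 0.75),
               p0)
    phi <- signed_distance_map(t)
    check_grad(function(tp, x) {
      espdnet:::ag_boundary_loss(tp, x, array(phi, c(6, 6, 1)))
    }, p0)
    a0 <- array(1 + rexp(72), c(6, 6, 2))
    check_grad(function(tp, x) espdnet:::ag_edl_loss(tp, x, t), a0)
  })
})

test_that("loss breakdown satisfies the composition identity", {
  withr::with_seed(6, {
    t <- matrix(rbinom(64, 1, 0.25), 8, 8)
    p <- matrix(runif(64), 8, 8)
    a <- array(1 + rexp(128), c(8, 8, 2))
    cfg <- loss_config()
    bd <- loss_breakdown(p, t, alpha = a, epoch = 3, config = cfg)
    expect_equal(bd$liver,
                 cfg$alpha_w * bd$dice + cfg$beta_w * bd$focal +
                   cfg$gamma_w * bd$boundary, tolerance = 1e-6)
    expect_true(all(is.finite(unlist(bd))))
    expect_true(bd$dice >= 0 && bd$dice < 1)
    expect_gte(bd$focal, 0)
  })
})
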