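# Region, boundary, calibration and significance metrics.

test_that("region metrics follow confusion-count arithmetic", {
  t <- matrix(0, 8, 8); t[2:4, 2:4] <- 1
  r <- region_metrics(t, t)
  expect_equal(unlist(r), c(dice = 1, iou = 1, precision = 1,
                            sensitivity = 1))

  p <- matrix(0, 8, 8); p[6:8, 6:8] <- 1
  r2 <- region_metrics(p, t)
  expect_equal(unlist(r2), c(dice = 0, iou = 0, precision = 0,
                             sensitivity = 0))

  # TP = 2, FP = 2, FN = 2
  t3 <- matrix(0, 4, 4); t3[1, 1:4] <- 1
  p3 <- matrix(0, 4, 4); p3[1, 1:2] <- 1; p3[2, 1:2] <- 1
  r3 <- region_metrics(p3, t3)
  expect_equal(r3$dice, 0.5)
  expect_equal(r3$iou, 1 / 3, tolerance = 1e-12)
  expect_equal(r3$precision, 0.5)
  expect_equal(r3$sensitivity, 0.5)

  # empty-empty convention
  r4 <- region_metrics(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(unlist(r4), c(dice = 1, iou = 1, precision = 1,
                             sensitivity = 1))
})

test_that("surface distances: identity, 3-4-5 offset, empty sentinel", {
  t <- matrix(0, 12, 12); t[3:7, 4:9] <- 1
  sd0 <- surface_distances(t, t)
  expect_equal(sd0$hd95, 0)
  expect_equal(sd0$assd, 0)

  a <- matrix(0, 12, 12); a[2, 2] <- 1
  b <- matrix(0, 12, 12); b[5, 6] <- 1  # offset (3, 4)
  sd1 <- surface_distances(a, b)
  expect_equal(sd1$hd95, 5)
  expect_equal(sd1$assd, 5)

  expect_warning(sde <- surface_distances(matrix(0, 5, 5), t[1:5, 1:5]),
                 "empty")
  expect_equal(sde$hd95, sqrt(50))
})

test_that("surface distances equal the brute-force oracle on random masks", {
  for (s in 1:100) {
    p <- random_blob_mask(32, 32, seed = s)
    t <- random_blob_mask(32, 32, seed = s + 1000)
    if (sum(p) == 0 || sum(t) == 0) next
    got <- surface_distances(p, t)
    want <- oracle_surface_distances(p, t)
    expect_equal(got$hd95, want$hd95, tolerance = 1e-9)
    expect_equal(got$assd, want$assd, tolerance = 1e-9)
  }
})

test_that("boundary F1 respects the matching tolerance", {
  t <- matrix(0, 16, 16); t[4:12, 4:12] <- 1
  expect_equal(boundary_f1(t, t), 1)

  shift1 <- matrix(0, 16, 16); shift1[5:13, 4:12] <- 1  # 1 px shift
  expect_equal(boundary_f1(shift1, t, tolerance = 2), 1)

  # straight-line boundaries 5 px apart, tolerance 2 -> no matches
  a <- matrix(0, 12, 20); a[, 1:5] <- 1
  b <- matrix(0, 12, 20); b[, 1:10] <- 1
  # boundaries: column 5 vs column 10 plus shared image-border columns;
  # restrict to interior rows to get clean straight lines
  a2 <- matrix(0, 12, 20); a2[1:12, 5] <- 1
  b2 <- matrix(0, 12, 20); b2[1:12, 10] <- 1
  expect_equal(boundary_f1(a2, b2, tolerance = 2), 0)
  expect_equal(boundary_f1(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(boundary_f1(a2, matrix(0, 12, 20)), 0)
})

test_that("ECE matches hand-binned examples", {
  expect_equal(expected_calibration_error(rep(1, 10), rep(1, 10)), 0)

  # 4 pixels: (0.9 correct), (0.9 wrong), (0.6 correct), (0.6 correct)
  ece <- expected_calibration_error(c(0.9, 0.9, 0.6, 0.6), c(1, 0, 1, 1))
  expect_equal(ece, 0.5 * abs(0.5 - 0.9) + 0.5 * abs(1 - 0.6),
               tolerance = 1e-12)
  expect_equal(ece, 0.4)

  # constant confidence c, accuracy a -> |a - c|
  withr::with_seed(1, {
    corr <- rbinom(200, 1, 0.7)
    expect_equal(expected_calibration_error(rep(0.85, 200), corr),
                 abs(mean(corr) - 0.85), tolerance = 1e-12)
  })
})

test_that("ECE is order-invariant and bounded by the max bin gap", {
  withr::with_seed(2, {
    conf <- runif(500, 0.5, 1)
    corr <- rbinom(500, 1, conf)
    e1 <- expected_calibration_error(conf, corr)
    ord <- sample(500)
    expect_equal(expected_calibration_error(conf[ord], corr[ord]), e1,
                 tolerance = 1e-12)
    rt <- reliability_table(conf, corr)
    expect_lte(e1, max(abs(rt$gap)) + 1e-12)
  })
})

test_that("UEC is the point-biserial correlation with degenerate guard", {
  e <- c(1, 1, 0, 0)
  expect_equal(as.numeric(uncertainty_error_correlation(e, e)), 1)

  u0 <- uncertainty_error_correlation(rep(0.4, 4), e)
  expect_equal(as.numeric(u0), 0)
  expect_true(attr(u0, "degenerate"))

  u <- c(0.9, 0.8, 0.1, 0.2)
  got <- uncertainty_error_correlation(u, e)
  expect_equal(as.numeric(got), stats::cor(u, e), tolerance = 1e-12)
  expect_equal(as.numeric(got), 0.98995, tolerance = 1e-5)
  expect_false(attr(got, "degenerate"))
})

test_that("paired permutation test: identity, exhaustive enumeration", {
  a <- c(0.8, 0.7, 0.9, 0.6)
  expect_equal(as.numeric(paired_permutation_test(a, a)), 1)

  p <- paired_permutation_test(c(2, 2, 2), c(1, 1, 1))
  expect_true(attr(p, "exhaustive"))
  expect_equal(as.numeric(p), 0.25)  # 2 of the 8 sign patterns reach |1|
})

test_that("permutation p-values are valid and roughly uniform under null", {
  withr::with_seed(3, {
    ps <- replicate(100, {
      a <- rnorm(20); b <- rnorm(20)
      as.numeric(paired_permutation_test(a, b, n_resamples = 200,
                                         seed = sample.int(1e6, 1)))
    })
    expect_true(all(ps > 0 & ps <= 1))
    expect_gte(mean(ps > 0.05), 0.9)
  })
})
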