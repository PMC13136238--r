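# Training pipeline: augmentation, determinism, variants, prediction,
# checkpoints, evaluation plumbing. Uses 32 px inputs to stay fast.

small_data <- function(n_train = 6, n_val = 2, seed = 5) {
  cfg <- tiny_phantom_cfg(seed = seed, size = 32)
  list(train = make_samples(seq_len(n_train), cfg),
       val = make_samples(n_train + seq_len(n_val), cfg))
}

fast_tc <- function(...) {
  train_config("tiny", input_size = 32, batch_size = 2, augment = FALSE,
               loss = loss_config(focal_alpha = 0.75), ...)
}

test_that("augmentation is synchronized, deterministic, binarity-preserving", {
  withr::with_seed(1, {
    img <- matrix(runif(64 * 64), 64, 64)
    msk <- matrix(0L, 64, 64); msk[20:30, 35:45] <- 1L
    a1 <- augment_pair(img, msk, seed = 11)
    a2 <- augment_pair(img, msk, seed = 11)
    expect_identical(a1, a2)
    a3 <- augment_pair(img, msk, seed = 12)
    expect_false(identical(a1$image, a3$image))
    expect_true(all(a1$mask %in% c(0L, 1L)))
    expect_true(all(a1$image >= 0 & a1$image <= 1))

    # geometric transform is identical for image and mask: a bright marker
    # inside the mask stays inside the transformed mask
    img2 <- matrix(0, 64, 64); img2[25, 40] <- 1
    msk2 <- matrix(0L, 64, 64); msk2[24:26, 39:41] <- 1L
    for (s in 1:10) {
      a <- augment_pair(img2, msk2, seed = s)
      peak <- which(a$image == max(a$image), arr.ind = TRUE)[1, ]
      expect_equal(a$mask[peak[1], peak[2]], 1L)
    }
  })
})

test_that("training runs are reproducible from the master seed", {
  d <- small_data()
  tc <- fast_tc(model_variant = "softmax_baseline", max_epochs = 2, seed = 3)
  f1 <- espd_train(d, tc)
  f2 <- espd_train(d, tc)
  cols <- setdiff(names(f1$history), "seconds")  # wall time may differ
  expect_equal(f1$history[cols], f2$history[cols], tolerance = 1e-12)
  expect_equal(f1$best_val_dice, f2$best_val_dice)
})

test_that("early stopping halts when validation Dice stalls", {
  d <- small_data(n_train = 4, n_val = 1)
  tc <- fast_tc(max_epochs = 8, seed = 2, early_stop_patience = 2,
                learning_rate = 1e-6)  # tiny lr: no improvement expected
  fit <- espd_train(d, tc)
  expect_lt(nrow(fit$history), 8)
})

test_that("plateau scheduler halves the learning rate", {
  d <- small_data(n_train = 4, n_val = 1)
  tc <- fast_tc(max_epochs = 6, seed = 2, early_stop_patience = 100,
                scheduler_patience = 2, learning_rate = 1e-6)
  fit <- espd_train(d, tc)
  expect_lt(min(fit$history$lr), 1e-6)
})

test_that("ablation switches change parameter counts in the stated way", {
  n_of <- function(v) n_parameters(espd_model(espd_config("tiny", v), seed = 1))
  full <- n_of("espd_full")
  expect_gt(full, n_of("no_dbar"))      # DBAR adds the refinement stack
  expect_gt(full, n_of("no_spdf"))      # SPDF outweighs a plain bottleneck
  expect_gt(full, n_of("no_degd"))      # evidential machinery adds weights
  expect_gt(n_of("no_degd"), n_of("softmax_baseline"))  # ... and DBAR again
  expect_gt(n_of("no_dbar"), n_of("softmax_baseline"))
})

test_that("prediction is deterministic with consistent outputs", {
  withr::with_seed(4, {
    img <- matrix(runif(32 * 32), 32, 32)
    model <- espd_model(espd_config("tiny", input_size = 32), seed = 6)
    p1 <- espd_predict(model, img)
    p2 <- espd_predict(model, img)
    expect_identical(p1$m_refined, p2$m_refined)
    expect_equal(dim(p1$m_refined), dim(img))
    expect_true(all(p1$m_refined >= 0 & p1$m_refined <= 1))
    expect_length(p1$uncertainty_pyramid, 4)  # S0..S3 maps
    expect_equal(unname(vapply(p1$uncertainty_pyramid, nrow, numeric(1))),
                 c(2, 4, 8, 16))
  })
})

test_that("checkpoints round-trip weights and configuration", {
  withr::with_seed(5, {
    img <- matrix(runif(32 * 32), 32, 32)
    model <- espd_model(espd_config("tiny", input_size = 32), seed = 7)
    path <- withr::local_tempfile(fileext = ".rds")
    save_checkpoint(model, path)
    model2 <- load_checkpoint(path)
    expect_equal(espd_predict(model2, img)$m_refined,
                 espd_predict(model, img)$m_refined, tolerance = 1e-12)
    expect_equal(model2$config$variant, model$config$variant)
  })
})

test_that("evaluation report has per-sample, pooled and aggregate parts", {
  d <- small_data(n_train = 4, n_val = 3)
  tc <- fast_tc(model_variant = "softmax_baseline", max_epochs = 1, seed = 8)
  fit <- espd_train(d, tc)
  ev <- espd_evaluate(fit, d$val, split = "val")
  expect_s3_class(ev$per_sample, "tbl_df")
  expect_true(all(c("dice", "iou", "hd95", "assd", "boundary_f1",
                    "hd95_coarse") %in% names(ev$per_sample)))
  expect_true(ev$pooled$ece >= 0 && ev$pooled$ece <= 1)
  expect_true(abs(as.numeric(ev$pooled$uec)) <= 1)
  expect_true(all(c("mean", "sd") %in% names(ev$aggregate)))

  g <- glance(ev)
  expect_equal(g$n, 3)
  t <- tidy(fit)
  expect_true(all(c("epoch", "loss", "val_dice") %in% names(t)))
  expect_s3_class(glance(fit), "tbl_df")

  # comparison via the paired permutation test
  cmp <- espd_compare(fit, fit, d$val, split = "val",
                      metrics = "dice", n_resamples = 50)
  expect_equal(cmp$p_value, 1)  # identical models: zero difference

  # multi-seed aggregation reports mean and sd per metric
  fit2 <- espd_train(d, fast_tc(model_variant = "softmax_baseline",
                                max_epochs = 1, seed = 9))
  ss <- espd_seed_summary(list(fit, fit2), d$val, split = "val")
  expect_true(all(c("metric", "mean", "sd") %in% names(ss)))
  expect_true(all(c("dice", "hd95", "ece", "uec") %in% ss$metric))
  expect_true(all(is.finite(ss$mean)))
})

test_that("autoplot methods return ggplot objects", {
  s <- generate_phantom(tiny_phantom_cfg(size = 32), 1)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  d <- small_data(n_train = 4, n_val = 1)
  fit <- espd_train(d, fast_tc(model_variant = "softmax_baseline",
                               max_epochs = 1, seed = 9))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  ev <- espd_evaluate(fit, d$val, split = "val")
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})

test_that("the CLI generates datasets and writes predictions", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "data")
  espd_cli(c("generate", "--n", "10", "--out", out, "--size", "32",
             "--seed", "4"))
  man <- read_manifest(out)
  expect_equal(nrow(man), 10)

  ck <- file.path(dir, "ck.rds")
  save_checkpoint(espd_model(espd_config("tiny", input_size = 32), seed = 1),
                  ck)
  pdir <- file.path(dir, "pred")
  espd_cli(c("predict", "--checkpoint", ck,
             "--image", file.path(out, man$image[1]),
             "--out", pdir, "--export-uncertainty", "--export-edges"))
  expect_true(file.exists(file.path(pdir, "mask_refined.png")))
  expect_equal(sum(grepl("uncertainty_s", list.files(pdir))), 4)
  expect_true(file.exists(file.path(pdir, "e_boundary.png")))
})
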