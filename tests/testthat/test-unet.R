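# Encoder-decoder segmenter: architecture contracts, losses, schedule,
# gradients, early stopping and a small end-to-end overfit check.

test_that("model output obeys the shape and probability contracts", {
  m <- build_model(depth = 3, base_channels = 8, input_size = c(128, 128),
                   seed = 1)
  pm <- suppressWarnings(
    predict_probmap(m, matrix(runif(128 * 128, 0, 255), 128, 128)))
  expect_s3_class(pm, "prob_map")
  expect_equal(dim(pm$values), c(128, 128))
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  expect_true(attr(pm, "untrained"))
  expect_warning(
    predict_probmap(m, matrix(0, 128, 128)), "trained")

  expect_error(build_model(depth = 3, input_size = c(100, 100)),
               "divisible")
  expect_error(build_model(encoder_id = "resnet34"), "weights")
  expect_error(build_model(pretrained = TRUE), "pretrained")
})

test_that("parameter count grows with base channel width", {
  n <- vapply(c(4, 8, 16), function(b)
    n_parameters(build_model(depth = 3, base_channels = b)), 0)
  expect_true(all(diff(n) > 0))
})

test_that("inference pads/upscales back to the native grid", {
  m <- build_model(depth = 3, base_channels = 4, input_size = c(64, 64),
                   seed = 2)
  m$trained <- TRUE
  img <- matrix(runif(100 * 90, 0, 255), 100, 90)  # not a multiple of 8
  pm <- predict_probmap(m, img, resize_factor = 0.5)
  expect_equal(dim(pm$values), c(100, 90))
  expect_true(all(pm$values >= 0 & pm$values <= 1))
})

test_that("loss functions match their closed forms", {
  t <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  perfect <- matrix(as.numeric(t), 2, 2)
  expect_lt(dice_loss(perfect, t), 0.2)          # eps-order with eps = 1
  expect_lt(cross_entropy_loss(perfect, t), 1e-5)
  expect_lt(focal_loss(perfect, t), 1e-5)
  expect_gte(dice_loss(1 - perfect, t), 0.8)  # -> 1 as eps/N -> 0

  # uniform 0.5 over a half-foreground raster: dice -> 0.5 as eps -> 0
  n <- 200
  t2 <- matrix(rep(c(TRUE, FALSE), each = n / 2), n, 1)
  u <- matrix(0.5, n, 1)
  expect_equal(dice_loss(u, t2), 1 - (2 * 0.25 * n + 1) / (n + 1))
  expect_lt(abs(dice_loss(u, t2) - 0.5), 0.01)

  # focal with gamma 0 is cross-entropy
  set.seed(12)
  p <- matrix(runif(64), 8, 8); tt <- random_mask(8, 8)
  expect_equal(focal_loss(p, tt, gamma = 0), cross_entropy_loss(p, tt))

  # single pixel, p_true = 0.5, gamma = 2 -> 0.25 * ln 2
  expect_equal(focal_loss(matrix(0.5), matrix(TRUE), gamma = 2),
               0.25 * log(2), tolerance = 1e-12)

  # extreme probabilities are clipped, never NaN/Inf
  expect_true(is.finite(cross_entropy_loss(matrix(0), matrix(TRUE))))
  expect_true(is.finite(focal_loss(matrix(1), matrix(FALSE))))

  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("the 1-cycle schedule ramps linearly between its bounds", {
  lr <- one_cycle_schedule(c(1e-4, 1e-2), 100)
  expect_equal(lr(0), 1e-4)
  expect_equal(lr(50), 1e-2)
  expect_equal(lr(100), 1e-4)
  expect_equal(lr(25), (1e-4 + 1e-2) / 2)
  expect_equal(lr(75), (1e-4 + 1e-2) / 2)
})

test_that("analytic gradients match finite differences", {
  fw_loss <- function(model, x, t, kind) {
    fw <- spheroseg:::unet_forward(model, x)
    spheroseg:::loss_with_grad(kind, fw$prob, t)$loss
  }
  set.seed(31)
  m <- build_model(depth = 2, base_channels = 4, input_size = c(16, 16),
                   seed = 2)
  x <- matrix(runif(256), 16, 16)
  t <- matrix(runif(256) > 0.6, 16, 16)
  for (kind in c("dice", "ce", "focal")) {
    fw <- spheroseg:::unet_forward(m, x, keep_cache = TRUE)
    lw <- spheroseg:::loss_with_grad(kind, fw$prob, t)
    g <- spheroseg:::unet_backward(m, fw$cache, lw$dprob)
    for (nm in c("enc1.conv1.w", "bot.conv2.w", "dec2.conv.w",
                 "final.b")) {
      i <- sample(length(m$par[[nm]]), 1)
      eps <- 1e-5
      up <- m; up$par[[nm]][i] <- up$par[[nm]][i] + eps
      dn <- m; dn$par[[nm]][i] <- dn$par[[nm]][i] - eps
      num <- (fw_loss(up, x, t, kind) - fw_loss(dn, x, t, kind)) /
        (2 * eps)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("early stopping restores the best epoch on a stubbed metric", {
  cfg <- clean_cfg(seed = 51, n = 32)
  tr <- make_samples(cfg, 2, prefix = "TR")
  va <- make_samples(cfg, 1, offset = 10, prefix = "VA")
  # best at epoch 3, never improves afterwards
  stub_vals <- c(0.5, 0.4, 0.3, 0.3, 0.31, 0.32, 0.33, 0.34, 0.35, 0.36)
  m <- build_model(depth = 2, base_channels = 2, input_size = c(32, 32),
                   seed = 1)
  tc <- train_config(epochs = 10, patience = 2, seed = 1,
                     augment = FALSE, batch_size = 2)
  m <- train(m, tr, va, tc,
             val_metric_fn = function(model, epoch) stub_vals[epoch])
  expect_equal(m$best_epoch, 3L)
  expect_equal(nrow(m$history), 3L + 2L)  # stops patience epochs later
  expect_equal(m$history$val_jcd, stub_vals[1:5])
})

test_that("training is deterministic and refuses leaking spheroid IDs", {
  cfg <- clean_cfg(seed = 61, n = 32)
  tr <- make_samples(cfg, 2, prefix = "A")
  va <- make_samples(cfg, 1, offset = 10, prefix = "B")
  run <- function() {
    m <- build_model(depth = 2, base_channels = 2,
                     input_size = c(32, 32), seed = 7)
    train(m, tr, va, train_config(epochs = 3, patience = 3, seed = 7,
                                  augment = TRUE))$history
  }
  expect_identical(run(), run())

  leaky <- va
  leaky[[1]]$spheroid_id <- "A001"
  m <- build_model(depth = 2, base_channels = 2, input_size = c(32, 32))
  expect_error(train(m, tr, leaky, train_config(epochs = 2, patience = 2)),
               "leakage")
})

test_that("a tiny model overfits a clean four-image set", {
  cfg <- clean_cfg(seed = 11, n = 64)
  tr <- make_samples(cfg, 4, prefix = "T")
  va <- make_samples(cfg, 2, offset = 10, prefix = "V")
  m <- build_model(depth = 3, base_channels = 8, input_size = c(64, 64),
                   seed = 1)
  m <- train(m, tr, va,
             train_config(loss = "dice", epochs = 60, patience = 60,
                          seed = 1, augment = FALSE))
  train_jcd <- vapply(tr, function(s)
    jcd(extract_spheroid(predict_probmap(m, s$image)), s$target), 0)
  expect_lte(mean(train_jcd), 0.1)
})
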