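# Losses, network construction, gradient correctness, training determinism,
# prediction surfaces. Heavy end-to-end training accuracy lives in
# test-acceptance.R; here the models are kept tiny.

test_that("regression losses match hand-computed branch values", {
  mae <- regression_loss_spec("MAE")
  mse <- regression_loss_spec("MSE")
  hub <- regression_loss_spec("Huber", delta = 1)
  expect_equal(regression_loss(mae, c(1, 3), c(2, 2)), 1)
  expect_equal(regression_loss(mse, c(1, 3), c(2, 2)), 1)
  expect_equal(regression_loss(mse, c(1, 3), c(1, 3)), 0)
  # Huber branches at delta = 1: quadratic 0.5 e^2, linear delta(|e| - delta/2)
  expect_equal(regression_loss(hub, 0.5, 0), 0.125)
  expect_equal(regression_loss(hub, 2, 0), 1.5)
  expect_error(regression_loss(mae, 1:3, 1:2), class = "fetalhc_invalid_input")
})

test_that("Huber is continuous at |e| = delta and equals MSE/2 below", {
  for (delta in c(0.5, 1, 2)) {
    hub <- regression_loss_spec("Huber", delta = delta)
    mse <- regression_loss_spec("MSE")
    eps <- 1e-10
    below <- regression_loss(hub, delta - eps, 0)
    above <- regression_loss(hub, delta + eps, 0)
    expect_equal(below, delta^2 / 2, tolerance = 1e-6)
    expect_equal(above, delta^2 / 2, tolerance = 1e-6)
    e <- seq(-delta * 0.99, delta * 0.99, length.out = 11)
    expect_equal(regression_loss(hub, e, numeric(11)),
                 regression_loss(mse, e, numeric(11)) / 2, tolerance = 1e-12)
  }
})

test_that("all three losses vanish iff pred equals gt", {
  set.seed(8)
  g <- runif(10)
  for (kind in c("MAE", "MSE", "Huber")) {
    spec <- regression_loss_spec(kind)
    expect_equal(regression_loss(spec, g, g), 0)
    expect_gt(regression_loss(spec, g + 1e-3, g), 0)
  }
})

test_that("dice loss matches the smoothed formula", {
  g <- matrix(0L, 30, 30); g[5:25, 5:25] <- 1L
  expect_lt(dice_loss(g, g), 1e-3)
  expect_gt(dice_loss(1 - g, g), 0.99)
  # all-0.5 probabilities vs half-ones mask, hand evaluation
  p <- matrix(0.5, 4, 4); g <- matrix(0L, 4, 4); g[1:2, ] <- 1L
  num <- 2 * sum(p * g) + 1; den <- sum(p) + sum(g) + 1
  expect_equal(dice_loss(p, g), 1 - num / den, tolerance = 1e-12)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0L, 3, 3)),
               class = "fetalhc_invalid_input")
})

test_that("HC normalization round-trips and guards the unset constant", {
  cfg <- train_config(hc_norm_constant = 350)
  expect_equal(normalize_hc(350, cfg), 1)
  expect_equal(normalize_hc(175, cfg), 0.5)
  set.seed(4)
  x <- runif(100, 10, 350)
  expect_equal(denormalize_hc(normalize_hc(x, cfg), cfg), x, tolerance = 1e-9)
  cfg0 <- train_config()
  expect_error(normalize_hc(100, cfg0), class = "fetalhc_config_error")
  expect_error(denormalize_hc(0.5, cfg0), class = "fetalhc_config_error")
})

test_that("network builders validate shapes and count parameters stably", {
  cfg <- train_config(input_size = c(64L, 64L), depth = 3L, base_filters = 8L)
  n1 <- build_tiny_segnet(cfg)
  n2 <- build_tiny_segnet(cfg)
  expect_identical(count_parameters(n1), count_parameters(n2))
  expect_identical(n1$params, n2$params) # seeded init
  r1 <- build_tiny_regnet(cfg)
  expect_identical(count_parameters(r1), count_parameters(build_tiny_regnet(cfg)))
  bad <- train_config(input_size = c(60L, 60L), depth = 3L)
  expect_error(build_tiny_segnet(bad), class = "fetalhc_config_error")
  expect_error(build_tiny_regnet(bad), class = "fetalhc_config_error")
})

test_that("forward passes return finite outputs of the right shape", {
  cfg <- train_config(input_size = c(16L, 16L), depth = 2L, base_filters = 4L,
                      seed = 5L)
  seg <- build_tiny_segnet(cfg)
  x <- array(0, c(16, 16, 1, 3))
  p <- fetalhc:::segnet_forward(seg, x)$prob
  expect_identical(dim(p), c(16L, 16L, 1L, 3L))
  expect_true(all(is.finite(p) & p > 0 & p < 1))
  reg <- build_tiny_regnet(cfg)
  y <- fetalhc:::regnet_forward(reg, x)$yhat
  expect_length(y, 3)
  expect_true(all(is.finite(y)))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(9)
  cfg <- train_config(input_size = c(8L, 8L), depth = 2L, base_filters = 2L,
                      seed = 3L, dropout_keep = 1)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  eps <- 1e-6

  # segmentation network under the soft-Dice objective
  net <- build_tiny_segnet(cfg)
  g <- array((runif(8 * 8 * 2) > 0.5) * 1, c(8, 8, 2))
  loss_seg <- function(net) {
    fwd <- fetalhc:::segnet_forward(net, x)
    mean(vapply(1:2, function(j) dice_loss(fwd$prob[, , 1, j], g[, , j]),
                numeric(1)))
  }
  fwd <- fetalhc:::segnet_forward(net, x, keep_cache = TRUE)
  dprob <- array(0, dim(fwd$prob))
  for (j in 1:2) {
    pj <- fwd$prob[, , 1, j]; gj <- g[, , j]
    num <- 2 * sum(pj * gj) + 1; den <- sum(pj) + sum(gj) + 1
    dprob[, , 1, j] <- (num / den^2 - 2 * gj / den) / 2
  }
  grads <- fetalhc:::segnet_backward(net, fwd, dprob)
  for (nm in names(net$params)) {
    for (ii in seq_len(min(3, length(net$params[[nm]])))) {
      n2 <- net; n2$params[[nm]][ii] <- n2$params[[nm]][ii] + eps
      n3 <- net; n3$params[[nm]][ii] <- n3$params[[nm]][ii] - eps
      num_g <- (loss_seg(n2) - loss_seg(n3)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num_g, tolerance = 1e-4)
    }
  }

  # regression network under each loss, in training mode so the batch-norm
  # backward (batch statistics depend on the parameters) is exercised
  net <- build_tiny_regnet(cfg)
  y <- c(0.4, 0.7)
  for (kind in c("MAE", "MSE", "Huber")) {
    spec <- regression_loss_spec(kind, delta = 0.1)
    loss_reg <- function(net)
      regression_loss(spec,
                      fetalhc:::regnet_forward(net, x, train = TRUE)$yhat, y)
    fwd <- fetalhc:::regnet_forward(net, x, train = TRUE, keep_cache = TRUE)
    dy <- fetalhc:::regression_loss_grad(spec, fwd$yhat, y)
    grads <- fetalhc:::regnet_backward(net, fwd, dy)
    for (nm in names(net$params)) {
      for (ii in seq_len(min(3, length(net$params[[nm]])))) {
        n2 <- net; n2$params[[nm]][ii] <- n2$params[[nm]][ii] + eps
        n3 <- net; n3$params[[nm]][ii] <- n3$params[[nm]][ii] - eps
        num_g <- (loss_reg(n2) - loss_reg(n3)) / (2 * eps)
        # conv biases are exactly gradient-free under batch norm; skip the
        # 0-vs-float-noise comparison
        if (abs(num_g) < 1e-6 && abs(grads[[nm]][ii]) < 1e-6) next
        expect_equal(grads[[nm]][ii], num_g, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic given the seed and reduces the loss", {
  cfg <- train_config(input_size = c(32L, 32L), depth = 2L, base_filters = 4L,
                      epochs = 3L, learning_rate = 1e-3, seed = 17L)
  ph <- phantom_config(size = c(32L, 32L), band_px = 2)
  recs <- lapply(1:12, function(s) generate_phantom(s, ph))
  ds <- list(x = lapply(recs, `[[`, "image"),
             y = lapply(recs, `[[`, "gt_mask"))
  f1 <- train_model(build_tiny_segnet(cfg), ds, cfg)
  f2 <- train_model(build_tiny_segnet(cfg), ds, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_lt(tail(f1$trace$train_loss, 1), f1$trace$train_loss[1])

  hc <- vapply(recs, `[[`, numeric(1), "hc_mm")
  cfgr <- train_config(input_size = c(32L, 32L), depth = 2L, base_filters = 4L,
                       epochs = 3L, learning_rate = 1e-3, seed = 19L,
                       dropout_keep = 0.9, hc_norm_constant = max(hc))
  dsr <- list(x = lapply(recs, `[[`, "image"), y = hc)
  r1 <- train_model(build_tiny_regnet(cfgr), dsr, cfgr)
  r2 <- train_model(build_tiny_regnet(cfgr), dsr, cfgr)
  expect_identical(r1$trace, r2$trace)
  expect_error(train_model(build_tiny_segnet(cfg), list(x = list()), cfg),
               class = "fetalhc_invalid_input")
})

test_that("segmentation-route prediction survives oracle and blank models", {
  rec <- generate_phantom(31)
  p <- estimate_hc_segmentation(rec$image, "oracle", rec$spacing, id = "a",
                                oracle_mask = rec$gt_mask)
  expect_false(p$failed)
  expect_lt(abs(p$hc_mm - rec$hc_mm) / rec$hc_mm, 0.01)
  expect_s3_class(p$ellipse, "ellipse_params")
  # blank probability map -> failed prediction, not an error
  blank <- estimate_hc_segmentation(rec$image, "oracle", rec$spacing,
                                    oracle_mask = matrix(0L, 64, 64))
  expect_true(blank$failed)
  expect_true(is.na(blank$hc_mm))
})

test_that("regression-route prediction denormalizes and guards config", {
  cfg <- train_config(input_size = c(16L, 16L), depth = 2L, base_filters = 2L,
                      seed = 23L, hc_norm_constant = 200)
  net <- build_tiny_regnet(cfg)
  # constant-output model: zero conv weights, bias only
  for (nm in names(net$params)) net$params[[nm]] <- net$params[[nm]] * 0
  net$params$fc_b <- 0.5
  rec <- generate_phantom(3)
  p <- estimate_hc_regression(rec$image, net, cfg)
  expect_equal(p$hc_mm, 100)
  cfg_bad <- train_config(input_size = c(16L, 16L), depth = 2L)
  expect_error(estimate_hc_regression(rec$image, net, cfg_bad),
               class = "fetalhc_config_error")
})

test_that("models round-trip through save/load", {
  cfg <- train_config(input_size = c(16L, 16L), depth = 2L, base_filters = 2L)
  net <- build_tiny_segnet(cfg)
  tf <- tempfile(fileext = ".rds")
  save_model(net, tf)
  expect_identical(load_model(tf), net)
})
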