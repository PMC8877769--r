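# Miniature trainable estimators for the two HC routes: an encoder-decoder
# segmentation network trained with the soft-Dice loss, and a convolutional
# regression network trained with MAE, MSE or Huber losses on normalized HC
# targets. Both are deliberately small, CPU-scale stand-ins exposing the same
# pipeline surface a full-size backbone would plug into.

#' Training configuration
#'
#' Bundles the optimization protocol and model hyperparameters. The protocol
#' defaults follow the reference training recipe (Adam, learning rate 1e-4,
#' batch size 16, 100 epochs); desk-scale runs in the examples, tests and
#' experiment runner override `epochs` (20) and `learning_rate` (1e-3), which
#' suit the miniature models' very small number of gradient steps.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param dropout_keep Fraction of regression-head units kept by dropout, in
#'   (0, 1]. The default 0.3 keeps 30% of units.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param input_size `c(H, W)` model input size; images are resized to this.
#' @param hc_norm_constant Maximum training-set HC (mm) used to scale
#'   regression targets into (0, 1]; must be set from the training split only.
#' @param depth Number of encoder / conv blocks.
#' @param base_filters Filters in the first block (doubled per level).
#' @param huber_delta Huber loss threshold, default 1.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         epochs = 100L, dropout_keep = 0.3, seed = 42L,
                         input_size = c(64L, 64L), hc_norm_constant = NULL,
                         depth = 3L, base_filters = 8L, huber_delta = 1) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), dropout_keep = dropout_keep,
              seed = as.integer(seed), input_size = as.integer(input_size),
              hc_norm_constant = hc_norm_constant, depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              huber_delta = huber_delta)
  with(cfg, {
    if (learning_rate <= 0 || batch_size < 1L || epochs < 1L ||
        depth < 1L || base_filters < 1L || huber_delta <= 0)
      stop_config_error("training configuration values must be positive")
    if (dropout_keep <= 0 || dropout_keep > 1)
      stop_config_error("dropout_keep must lie in (0, 1]")
    if (length(input_size) != 2L || any(input_size < 2L))
      stop_config_error("input_size must be two positive integers")
  })
  structure(cfg, class = "train_config")
}

#' Regression loss specification
#'
#' @param kind One of `"MAE"`, `"MSE"`, `"Huber"`.
#' @param delta Huber threshold (ignored by the other losses), default 1.
#' @return A list of class `regression_loss_spec`.
#' @export
regression_loss_spec <- function(kind = c("MAE", "MSE", "Huber"), delta = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(delta) || delta <= 0)
    stop_invalid_parameter("Huber delta must be positive")
  structure(list(kind = kind, delta = delta), class = "regression_loss_spec")
}

#' Regression losses: MAE, MSE, Huber
#'
#' Mean over the batch of the per-element loss. The Huber loss uses the
#' quadratic branch \eqn{e^2/2} for \eqn{|e| < \delta} and the linear branch
#' \eqn{\delta(|e| - \delta/2)} otherwise; the two branches agree
#' (\eqn{\delta^2/2}) at \eqn{|e| = \delta}.
#'
#' @param spec A [regression_loss_spec()].
#' @param pred,gt Equal-length numeric vectors.
#' @return Scalar loss.
#' @export
regression_loss <- function(spec, pred, gt) {
  stopifnot(inherits(spec, "regression_loss_spec"))
  if (!is.numeric(pred) || !is.numeric(gt) || length(pred) != length(gt) ||
      length(gt) < 1L)
    stop_invalid_input("pred and gt must be equal-length numeric vectors")
  e <- pred - gt
  switch(spec$kind,
    MAE = mean(abs(e)),
    MSE = mean(e^2),
    Huber = {
      d <- spec$delta
      mean(ifelse(abs(e) < d, e^2 / 2, d * (abs(e) - d / 2)))
    })
}

regression_loss_grad <- function(spec, pred, gt) {
  e <- pred - gt
  n <- length(e)
  switch(spec$kind,
    MAE = sign(e) / n,
    MSE = 2 * e / n,
    Huber = {
      d <- spec$delta
      ifelse(abs(e) < d, e, d * sign(e)) / n
    })
}

#' Soft-Dice loss
#'
#' `1 - (2 * sum(p*g) + 1) / (sum(p) + sum(g) + 1)` with smoothing constant 1
#' in numerator and denominator, evaluated over continuous probabilities. Zero
#' (up to smoothing) when `p == g` exactly.
#'
#' @param prob_map Numeric matrix/array of probabilities in \[0, 1\].
#' @param gt_mask Binary mask of identical shape.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob_map, gt_mask) {
  if (!all(dim(as.array(prob_map)) == dim(as.array(gt_mask))))
    stop_invalid_input("probability map and mask shapes differ")
  p <- as.numeric(prob_map); g <- as.numeric(gt_mask)
  1 - (2 * sum(p * g) + 1) / (sum(p) + sum(g) + 1)
}

#' Normalize / denormalize HC targets
#'
#' Regression targets are scaled by the maximum HC of the training split so
#' the network predicts values in (0, 1]. The constant must be set on the
#' training split only and carried in the configuration.
#'
#' @param hc_mm Numeric HC values in mm.
#' @param config A [train_config()] with `hc_norm_constant` set.
#' @return Normalized values (or mm values for `denormalize_hc`).
#' @export
normalize_hc <- function(hc_mm, config) {
  if (is.null(config$hc_norm_constant) || !is.finite(config$hc_norm_constant) ||
      config$hc_norm_constant <= 0)
    stop_config_error("hc_norm_constant is unset; set it from the training split")
  hc_mm / config$hc_norm_constant
}

#' @rdname normalize_hc
#' @export
denormalize_hc <- function(hc_norm, config) {
  if (is.null(config$hc_norm_constant) || !is.finite(config$hc_norm_constant) ||
      config$hc_norm_constant <= 0)
    stop_config_error("hc_norm_constant is unset; set it from the training split")
  hc_norm * config$hc_norm_constant
}

# ---- architectures -----------------------------------------------------------

#' Build the miniature segmentation network
#'
#' A small U-shaped encoder-decoder: `depth` encoder blocks (3x3 conv + ReLU +
#' 2x2 max-pool), a bottleneck conv, and `depth` decoder blocks (nearest 2x
#' upsample + skip concatenation + 3x3 conv + ReLU), finished by a 1x1 conv
#' with sigmoid giving a one-channel probability map at input resolution.
#' Filters double per level starting from `base_filters`. Initialization is
#' seeded from `config$seed`.
#'
#' @param config A [train_config()]; `input_size` must be divisible by
#'   `2^depth`.
#' @return A model object of class `tiny_segnet`.
#' @export
build_tiny_segnet <- function(config) {
  stopifnot(inherits(config, "train_config"))
  d <- config$depth; f <- config$base_filters
  if (any(config$input_size %% (2L^d) != 0L))
    stop_config_error("input_size must be divisible by 2^depth")
  set.seed(config$seed)
  filt <- f * 2L^(0:d)                    # f_1 .. f_d, bottleneck f_{d+1}
  params <- list()
  c_in <- 1L
  for (i in seq_len(d)) {
    params[[paste0("enc", i, "_w")]] <- he_conv(3L, c_in, filt[i])
    params[[paste0("enc", i, "_b")]] <- numeric(filt[i])
    c_in <- filt[i]
  }
  params[["bott_w"]] <- he_conv(3L, filt[d], filt[d + 1L])
  params[["bott_b"]] <- numeric(filt[d + 1L])
  for (i in rev(seq_len(d))) {
    below <- if (i == d) filt[d + 1L] else filt[i + 1L]
    params[[paste0("dec", i, "_w")]] <- he_conv(3L, below + filt[i], filt[i])
    params[[paste0("dec", i, "_b")]] <- numeric(filt[i])
  }
  params[["head_w"]] <- he_conv(1L, filt[1L], 1L)
  params[["head_b"]] <- numeric(1L)
  structure(list(params = params, depth = d, filters = filt, config = config),
            class = "tiny_segnet")
}

#' Build the miniature regression network
#'
#' A small conv stack (`depth` blocks of 3x3 conv + batch norm + ReLU + 2x2
#' max-pool), global average pooling, dropout keeping `config$dropout_keep`
#' of the feature units (inverted dropout, train time only), and a single
#' linear output neuron predicting the normalized HC. Batch normalization
#' carries per-channel running statistics on the model (updated during
#' training, used at prediction time), which makes the handful of gradient
#' steps available at desk scale sufficient for convergence.
#'
#' @inheritParams build_tiny_segnet
#' @return A model object of class `tiny_regnet`.
#' @export
build_tiny_regnet <- function(config) {
  stopifnot(inherits(config, "train_config"))
  d <- config$depth; f <- config$base_filters
  if (any(config$input_size %% (2L^d) != 0L))
    stop_config_error("input_size must be divisible by 2^depth")
  set.seed(config$seed)
  filt <- f * 2L^(0:(d - 1L))
  params <- list()
  bn_mean <- bn_var <- list()
  c_in <- 1L
  for (i in seq_len(d)) {
    params[[paste0("conv", i, "_w")]] <- he_conv(3L, c_in, filt[i])
    params[[paste0("conv", i, "_b")]] <- numeric(filt[i])
    params[[paste0("bn", i, "_g")]] <- rep(1, filt[i])
    params[[paste0("bn", i, "_b")]] <- numeric(filt[i])
    bn_mean[[i]] <- numeric(filt[i])
    bn_var[[i]] <- rep(1, filt[i])
    c_in <- filt[i]
  }
  params[["fc_w"]] <- matrix(stats::rnorm(c_in, 0, sqrt(1 / c_in)), c_in, 1L)
  # start the output at the mid-range of the normalized target (0, 1] so early
  # steps refine rather than rescale the prediction
  params[["fc_b"]] <- 0.5
  structure(list(params = params, depth = d, filters = filt, config = config,
                 bn_mean = bn_mean, bn_var = bn_var),
            class = "tiny_regnet")
}

#' Number of trainable parameters of a model
#'
#' Deterministic for a given configuration.
#'
#' @param model A `tiny_segnet` or `tiny_regnet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward / backward ------------------------------------------------------

segnet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; d <- model$depth
  caches <- list(); skips <- list()
  h <- x
  for (i in seq_len(d)) {
    cv <- conv_forward(h, p[[paste0("enc", i, "_w")]], p[[paste0("enc", i, "_b")]])
    a <- relu(cv$y)
    skips[[i]] <- a
    mp <- maxpool2_forward(a)
    h <- mp$y
    if (keep_cache) caches[[paste0("enc", i)]] <- list(conv = cv$cache,
                                                       act = cv$y, mp = mp$cache)
  }
  cv <- conv_forward(h, p$bott_w, p$bott_b)
  h <- relu(cv$y)
  if (keep_cache) caches$bott <- list(conv = cv$cache, act = cv$y)
  for (i in rev(seq_len(d))) {
    up <- upsample2_forward(h)
    cc <- concat_channels(up, skips[[i]])
    cv <- conv_forward(cc, p[[paste0("dec", i, "_w")]], p[[paste0("dec", i, "_b")]])
    h <- relu(cv$y)
    if (keep_cache) caches[[paste0("dec", i)]] <-
      list(conv = cv$cache, act = cv$y, c_up = dim(up)[3])
  }
  cv <- conv_forward(h, p$head_w, p$head_b)
  prob <- sigmoid(cv$y)
  if (keep_cache) caches$head <- list(conv = cv$cache, z = cv$y)
  list(prob = prob, caches = caches)
}

# dprob: gradient of loss wrt the sigmoid output
segnet_backward <- function(model, fwd, dprob) {
  p <- model$params; d <- model$depth
  caches <- fwd$caches
  grads <- list()
  s <- fwd$prob
  dz <- dprob * s * (1 - s)
  cb <- conv_backward(dz, p$head_w, caches$head$conv)
  grads$head_w <- cb$dW; grads$head_b <- cb$db
  dh <- cb$dx
  for (i in seq_len(d)) {
    cc <- caches[[paste0("dec", i)]]
    dact <- dh * (cc$act > 0)
    cb <- conv_backward(dact, p[[paste0("dec", i, "_w")]], cc$conv)
    grads[[paste0("dec", i, "_w")]] <- cb$dW
    grads[[paste0("dec", i, "_b")]] <- cb$db
    sp <- split_channels(cb$dx, cc$c_up)
    dskip <- sp[[2]]
    dh_below <- upsample2_backward(sp[[1]])
    # route skip gradient through the encoder activation at level i later;
    # stash it
    caches[[paste0("enc", i)]]$dskip <- dskip
    dh <- dh_below
  }
  cc <- caches$bott
  dact <- dh * (cc$act > 0)
  cb <- conv_backward(dact, p$bott_w, cc$conv)
  grads$bott_w <- cb$dW; grads$bott_b <- cb$db
  dh <- cb$dx
  for (i in rev(seq_len(d))) {
    cc <- caches[[paste0("enc", i)]]
    da <- maxpool2_backward(dh, cc$mp) + cc$dskip
    dact <- da * (cc$act > 0)
    cb <- conv_backward(dact, p[[paste0("enc", i, "_w")]], cc$conv)
    grads[[paste0("enc", i, "_w")]] <- cb$dW
    grads[[paste0("enc", i, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

regnet_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  p <- model$params; d <- model$depth
  keep <- model$config$dropout_keep
  caches <- list()
  bn_mean <- model$bn_mean; bn_var <- model$bn_var
  h <- x
  for (i in seq_len(d)) {
    cv <- conv_forward(h, p[[paste0("conv", i, "_w")]], p[[paste0("conv", i, "_b")]])
    bn <- bn_forward(cv$y, p[[paste0("bn", i, "_g")]], p[[paste0("bn", i, "_b")]],
                     bn_mean[[i]], bn_var[[i]], train = train)
    bn_mean[[i]] <- bn$run_mean; bn_var[[i]] <- bn$run_var
    a <- relu(bn$y)
    mp <- maxpool2_forward(a)
    h <- mp$y
    if (keep_cache) caches[[paste0("conv", i)]] <-
      list(conv = cv$cache, bn = bn$cache, z = bn$y, mp = mp$cache)
  }
  feat <- global_avg_pool(h)
  dims <- dim(h)
  if (train && keep < 1) {
    mask <- matrix(stats::runif(length(feat)) < keep, nrow(feat)) / keep
    feat_d <- feat * mask
  } else {
    mask <- NULL
    feat_d <- feat
  }
  yhat <- as.vector(crossprod(p$fc_w, feat_d)) + p$fc_b
  if (keep_cache) caches$top <- list(feat_d = feat_d, mask = mask, dims = dims)
  list(yhat = yhat, caches = caches, bn_mean = bn_mean, bn_var = bn_var)
}

regnet_backward <- function(model, fwd, dy) {
  p <- model$params; d <- model$depth
  caches <- fwd$caches
  grads <- list()
  top <- caches$top
  grads$fc_w <- top$feat_d %*% matrix(dy, ncol = 1L)
  grads$fc_b <- sum(dy)
  dfeat <- p$fc_w %*% matrix(dy, nrow = 1L)
  if (!is.null(top$mask)) dfeat <- dfeat * top$mask
  dh <- global_avg_pool_backward(dfeat, top$dims)
  for (i in rev(seq_len(d))) {
    cc <- caches[[paste0("conv", i)]]
    da <- maxpool2_backward(dh, cc$mp)
    dz <- da * (cc$z > 0)
    bb <- bn_backward(dz, p[[paste0("bn", i, "_g")]], cc$bn)
    grads[[paste0("bn", i, "_g")]] <- bb$dgamma
    grads[[paste0("bn", i, "_b")]] <- bb$dbeta
    cb <- conv_backward(bb$dx, p[[paste0("conv", i, "_w")]], cc$conv)
    grads[[paste0("conv", i, "_w")]] <- cb$dW
    grads[[paste0("conv", i, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

# ---- training ----------------------------------------------------------------

# standardize one image to zero mean / unit sd (per-image statistics)
standardize_image <- function(m) {
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) s <- 1
  (m - mean(m)) / s
}

# stack a list of matrices into (H, W, 1, N), resizing to input_size
images_to_batch <- function(images, input_size, standardize = TRUE) {
  H <- input_size[1]; W <- input_size[2]
  N <- length(images)
  x <- array(0, c(H, W, 1L, N))
  for (i in seq_len(N)) {
    m <- images[[i]]
    if (!all(dim(m) == c(H, W))) m <- resize_bilinear(m, H, W)
    if (standardize) m <- standardize_image(m)
    x[, , 1L, i] <- m
  }
  x
}

masks_to_batch <- function(masks, input_size) {
  H <- input_size[1]; W <- input_size[2]
  N <- length(masks)
  y <- array(0, c(H, W, N))
  for (i in seq_len(N)) {
    m <- masks[[i]]
    if (!all(dim(m) == c(H, W)))
      m <- (resize_bilinear(matrix(as.numeric(m), nrow(m)), H, W) >= 0.5) * 1
    y[, , i] <- m
  }
  y
}

#' Train a miniature model
#'
#' Mini-batch Adam training with cosine annealing of the learning rate (from
#' `config$learning_rate` to 0 over the configured epochs), which stabilizes
#' the final-epoch model at these very small step budgets. All randomness
#' (shuffling, dropout) is seeded from `config$seed`, so two runs with the
#' same configuration on the same machine produce identical loss traces. For
#' `tiny_segnet` the loss is the per-image soft-Dice averaged over the batch;
#' for `tiny_regnet` it is the regression loss `loss` on normalized targets.
#'
#' @param model A `tiny_segnet` or `tiny_regnet` from the builders.
#' @param dataset A list: for segmentation, `x` (list of image matrices) and
#'   `y` (list of binary masks); for regression, `x` and `y` (numeric HC, mm,
#'   normalized internally via `config$hc_norm_constant`). Optional `x_val`,
#'   `y_val` give a validation trace.
#' @param config A [train_config()].
#' @param loss A [regression_loss_spec()] (regression only).
#' @return A list with `model` (trained), and `trace`: a data frame with one
#'   row per epoch (`epoch`, `train_loss`, and `val_loss`/`val_metric` when a
#'   validation set is given; for regression the validation metric is PMAE in
#'   %).
#' @export
train_model <- function(model, dataset, config = model$config,
                        loss = regression_loss_spec("MAE", config$huber_delta)) {
  UseMethod("train_model")
}

#' @export
train_model.tiny_segnet <- function(model, dataset, config = model$config,
                                    loss = NULL) {
  if (length(dataset$x) == 0L) stop_invalid_input("dataset is empty")
  set.seed(config$seed + 1L)
  isz <- config$input_size
  x_all <- images_to_batch(dataset$x, isz)
  y_all <- masks_to_batch(dataset$y, isz)
  has_val <- !is.null(dataset$x_val)
  if (has_val) {
    xv <- images_to_batch(dataset$x_val, isz)
    yv <- masks_to_batch(dataset$y_val, isz)
  }
  n <- dim(x_all)[4]
  state <- adam_init(model$params)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate *
      0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[, , idx, drop = FALSE]
      fwd <- segnet_forward(model, xb, keep_cache = TRUE)
      nb_img <- length(idx)
      lsum <- 0
      dprob <- array(0, dim(fwd$prob))
      for (j in seq_len(nb_img)) {
        pj <- fwd$prob[, , 1L, j]; gj <- yb[, , j]
        num <- 2 * sum(pj * gj) + 1
        den <- sum(pj) + sum(gj) + 1
        lsum <- lsum + (1 - num / den)
        dprob[, , 1L, j] <- (num / den^2 - 2 * gj / den) / nb_img
      }
      grads <- segnet_backward(model, fwd, dprob)
      upd <- adam_step(model$params, grads, state, lr_ep)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lsum / nb_img; nb <- nb + 1L
    }
    vl <- NA_real_
    if (has_val) {
      pv <- segnet_forward(model, xv)$prob
      vl <- mean(vapply(seq_len(dim(pv)[4]), function(j)
        dice_loss(pv[, , 1L, j], yv[, , j]), numeric(1)))
    }
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
  }
  list(model = model, trace = trace)
}

#' @export
train_model.tiny_regnet <- function(model, dataset, config = model$config,
                                    loss = regression_loss_spec("MAE",
                                      config$huber_delta)) {
  if (length(dataset$x) == 0L) stop_invalid_input("dataset is empty")
  set.seed(config$seed + 1L)
  isz <- config$input_size
  x_all <- images_to_batch(dataset$x, isz)
  y_all <- normalize_hc(dataset$y, config)
  has_val <- !is.null(dataset$x_val)
  if (has_val) xv <- images_to_batch(dataset$x_val, isz)
  n <- dim(x_all)[4]
  state <- adam_init(model$params)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_metric = numeric(0))
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate *
      0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[idx]
      fwd <- regnet_forward(model, xb, train = TRUE, keep_cache = TRUE)
      model$bn_mean <- fwd$bn_mean
      model$bn_var <- fwd$bn_var
      lval <- regression_loss(loss, fwd$yhat, yb)
      dy <- regression_loss_grad(loss, fwd$yhat, yb)
      grads <- regnet_backward(model, fwd, dy)
      upd <- adam_step(model$params, grads, state, lr_ep)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lval; nb <- nb + 1L
    }
    vm <- NA_real_
    if (has_val) {
      pv <- denormalize_hc(regnet_forward(model, xv)$yhat, config)
      vm <- hc_errors(pv, dataset$y_val)$pmae
    }
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_metric = vm))
  }
  list(model = model, trace = trace)
}

# ---- prediction --------------------------------------------------------------

#' Predict a segmentation probability map for one image
#'
#' @param model A trained `tiny_segnet`.
#' @param image An image matrix in \[0, 1\] (any size; resized internally).
#' @return A probability-map matrix at the model's input resolution.
#' @export
predict_prob_map <- function(model, image) {
  stopifnot(inherits(model, "tiny_segnet"))
  x <- images_to_batch(list(image), model$config$input_size)
  segnet_forward(model, x)$prob[, , 1L, 1L]
}

#' Estimate HC via the segmentation route
#'
#' Runs the full segmentation pipeline on one image: model probability map at
#' the analysis resolution, post-processing to contour points, ellipse fit,
#' exact rescaling of the fitted ellipse back to the original pixel grid, and
#' Ramanujan perimeter in mm using the image's pixel spacing. A post-
#' processing or fit failure is reported as a failed prediction (`hc_mm = NA`,
#' `failed = TRUE` with the failure cause), never as an error.
#'
#' @param image Image matrix in \[0, 1\], original resolution.
#' @param model A trained `tiny_segnet`, or the string `"oracle"` together
#'   with `oracle_mask` to bypass the network (used to isolate the geometric
#'   stages).
#' @param spacing A [pixel_spacing()] for the original grid.
#' @param id Image identifier carried into the prediction.
#' @param threshold Binarization threshold for the probability map.
#' @param oracle_mask Optional ground-truth mask used when `model = "oracle"`.
#' @return A list of class `hc_prediction`: `id`, `hc_mm`, `route`,
#'   `ellipse` (on the original grid), `failed`, `failure_cause`.
#' @export
estimate_hc_segmentation <- function(image, model, spacing, id = NA_character_,
                                     threshold = 0.5, oracle_mask = NULL) {
  H0 <- nrow(image); W0 <- ncol(image)
  if (identical(model, "oracle")) {
    if (is.null(oracle_mask)) stop_invalid_input("oracle mode needs oracle_mask")
    prob <- matrix(as.numeric(oracle_mask), nrow(oracle_mask))
    Hi <- nrow(prob); Wi <- ncol(prob)
  } else {
    stopifnot(inherits(model, "tiny_segnet"))
    prob <- predict_prob_map(model, image)
    Hi <- nrow(prob); Wi <- ncol(prob)
  }
  res <- tryCatch({
    pts <- postprocess_to_points(prob, threshold)
    e_small <- fit_ellipse(pts)
    e_orig <- rescale_ellipse(e_small, W0 / Wi, H0 / Hi)
    list(hc = hc_mm(e_orig, spacing), ellipse = e_orig,
         failed = FALSE, cause = NA_character_)
  }, fetalhc_fit_failure = function(cnd) {
    list(hc = NA_real_, ellipse = NULL, failed = TRUE,
         cause = fit_failure_cause(cnd))
  }, fetalhc_empty_mask = function(cnd) {
    list(hc = NA_real_, ellipse = NULL, failed = TRUE, cause = "empty_mask")
  })
  structure(list(id = id, hc_mm = res$hc, route = "segmentation",
                 ellipse = res$ellipse, failed = res$failed,
                 failure_cause = res$cause),
            class = "hc_prediction")
}

#' Estimate HC via the direct regression route
#'
#' Resizes and standardizes the image, runs the regression network, and
#' denormalizes the scalar output into mm using `config$hc_norm_constant`.
#'
#' @param image Image matrix in \[0, 1\].
#' @param model A trained `tiny_regnet`.
#' @param config A [train_config()] with `hc_norm_constant` set.
#' @param id Image identifier.
#' @return An `hc_prediction` list (`route = "regression"`, no ellipse).
#' @export
estimate_hc_regression <- function(image, model, config = model$config,
                                   id = NA_character_) {
  stopifnot(inherits(model, "tiny_regnet"))
  if (is.null(config$hc_norm_constant))
    stop_config_error("hc_norm_constant is unset; set it from the training split")
  x <- images_to_batch(list(image), config$input_size)
  yhat <- regnet_forward(model, x)$yhat
  structure(list(id = id, hc_mm = denormalize_hc(yhat, config),
                 route = "regression", ellipse = NULL, failed = FALSE,
                 failure_cause = NA_character_),
            class = "hc_prediction")
}

#' Save / load a model
#'
#' Models are plain R lists of arrays and are serialized with `saveRDS`.
#'
#' @param model A model object.
#' @param path File path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
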