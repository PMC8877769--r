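# Minimal convolutional-network engine used by the miniature segmentation and
# regression models. Tensors are R arrays laid out (H, W, C, N). Convolutions
# are cross-correlations implemented by im2col + matrix multiply; every layer
# has a hand-derived backward pass (checked against numerical gradients in the
# test suite). Only what the two tiny architectures need is implemented.

# ---- convolution -------------------------------------------------------------

# w: array(k, k, C_in, C_out), k in {1, 3}; 3x3 uses zero padding 1 ("same").
conv_forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]; Fc <- dim(w)[4]
  if (k == 1L) {
    X <- matrix(aperm(x, c(1, 2, 4, 3)), H * W * N, C)
  } else {
    xp <- array(0, c(H + 2L, W + 2L, C, N))
    xp[2:(H + 1L), 2:(W + 1L), , ] <- x
    X <- matrix(0, H * W * N, 9L * C)
    for (dj in 0:2) for (di in 0:2) {
      s <- xp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
      cols <- (di + 1L) + 3L * dj + 9L * (seq_len(C) - 1L)
      X[, cols] <- matrix(aperm(s, c(1, 2, 4, 3)), H * W * N, C)
    }
  }
  Wm <- matrix(w, k * k * C, Fc)
  Y <- X %*% Wm
  Y <- sweep(Y, 2L, b, "+")
  y <- aperm(array(Y, c(H, W, N, Fc)), c(1, 2, 4, 3))
  list(y = y, cache = list(X = X, dims = c(H, W, C, N), k = k))
}

conv_backward <- function(dy, w, cache) {
  dm <- cache$dims; H <- dm[1]; W <- dm[2]; C <- dm[3]; N <- dm[4]
  k <- cache$k; Fc <- dim(w)[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * N, Fc)
  Wm <- matrix(w, k * k * C, Fc)
  dW <- array(crossprod(cache$X, dym), dim(w))
  db <- colSums(dym)
  dX <- dym %*% t(Wm)
  if (k == 1L) {
    dx <- aperm(array(dX, c(H, W, N, C)), c(1, 2, 4, 3))
  } else {
    dxp <- array(0, c(H + 2L, W + 2L, C, N))
    for (dj in 0:2) for (di in 0:2) {
      cols <- (di + 1L) + 3L * dj + 9L * (seq_len(C) - 1L)
      blk <- aperm(array(dX[, cols], c(H, W, N, C)), c(1, 2, 4, 3))
      dxp[di + seq_len(H), dj + seq_len(W), , ] <-
        dxp[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] + blk
    }
    dx <- dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- pooling / upsampling ----------------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  x11 <- x[i1, j1, , , drop = FALSE]; x21 <- x[i2, j1, , , drop = FALSE]
  x12 <- x[i1, j2, , , drop = FALSE]; x22 <- x[i2, j2, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  m11 <- x11 == y
  m21 <- !m11 & x21 == y
  m12 <- !(m11 | m21) & x12 == y
  m22 <- !(m11 | m21 | m12)
  list(y = y, cache = list(m = list(m11, m21, m12, m22), dims = d))
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  m <- cache$m
  dx[i1, j1, , ] <- dy * m[[1]]
  dx[i2, j1, , ] <- dy * m[[2]]
  dx[i1, j2, , ] <- dy * m[[3]]
  dx[i2, j2, , ] <- dy * m[[4]]
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy); H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(d, c1) {
  list(d[, , seq_len(c1), , drop = FALSE],
       d[, , (c1 + 1L):dim(d)[3], , drop = FALSE])
}

relu <- function(x) x * (x > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

global_avg_pool <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

global_avg_pool_backward <- function(dy, dims) {
  hw <- dims[1] * dims[2]
  array(rep(as.vector(dy) / hw, each = hw), dims)
}

# ---- parameter init and Adam -------------------------------------------------

he_conv <- function(k, c_in, c_out) {
  array(stats::rnorm(k * k * c_in * c_out, 0, sqrt(2 / (k * k * c_in))),
        c(k, k, c_in, c_out))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- batch normalization -------------------------------------------------------

# Per-channel batch norm over (H, W, N). Training mode uses batch statistics
# (biased variance) and updates running averages; eval mode uses the running
# averages, so inference is deterministic and batch-size independent.
bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))              # (H, W, N, C)
  xm <- matrix(xp, ncol = C)                 # rows: HWN, cols: C
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(xm, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d,
                           train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims; C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  if (cache$train) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dxm <- sweep(t1 - t2, 2L, cache$inv_sd, "*")
  } else {
    dxm <- sweep(dxhat, 2L, cache$inv_sd, "*")
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
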