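# Shared fixtures: analytic rasterization of filled ellipses (independent of
# the package's phantom renderer) and small random masks.

rasterize_ellipse <- function(e, H, W) {
  X <- matrix(0:(W - 1), H, W, byrow = TRUE) - e$cx
  Y <- matrix(0:(H - 1), H, W) - e$cy
  th <- e$theta * pi / 180
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  ((u / e$a)^2 + (v / e$b)^2 <= 1) * 1L
}

random_blob_mask <- function(H, W, n_blobs = 2) {
  m <- matrix(0L, H, W)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 5, W - 6); cy <- runif(1, 5, H - 6)
    r <- runif(1, 2, min(H, W) / 4)
    X <- matrix(0:(W - 1), H, W, byrow = TRUE)
    Y <- matrix(0:(H - 1), H, W)
    m[(X - cx)^2 + (Y - cy)^2 <= r^2] <- 1L
  }
  m
}

# angular difference between two orientations in degrees, mod 180
theta_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  min(d, 180 - d)
}
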