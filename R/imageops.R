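# Internal raster primitives (pure, vectorized base R).
# Matrices are indexed [row, col] = [y + 1, x + 1]; x right, y down, 0-based
# pixel centers at integer coordinates.

# Shift a matrix by (dy, dx) with replicate (clamp-to-edge) padding.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur, replicate padding. Kernel radius = ceil(3*sigma).
gauss_blur <- function(m, sigma = 1) {
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, i - r - 1L, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, 0L, i - r - 1L)
  out
}

# Sobel gradients; gx along +x (columns), gy along +y (rows, downwards).
sobel <- function(m) {
  sm <- shift_mat
  gx <- (sm(m, -1L, -1L) + 2 * sm(m, 0L, -1L) + sm(m, 1L, -1L)) -
        (sm(m, -1L,  1L) + 2 * sm(m, 0L,  1L) + sm(m, 1L,  1L))
  gx <- -gx  # kernel [-1 0 1] along increasing x
  gy <- (sm(m, -1L, -1L) + 2 * sm(m, -1L, 0L) + sm(m, -1L, 1L)) -
        (sm(m,  1L, -1L) + 2 * sm(m,  1L, 0L) + sm(m,  1L, 1L))
  gy <- -gy
  list(gx = gx, gy = gy)
}

# Bilinear resize to out_h x out_w, align-corners = FALSE convention:
# src = (dst + 0.5) * (in/out) - 0.5, clamped.
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  sy <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), in_h - 1); fy <- pmin(pmax(sy - y0, 0), 1)
  x0 <- pmin(pmax(floor(sx), 0), in_w - 1); fx <- pmin(pmax(sx - x0, 0), 1)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  Fy <- matrix(fy, out_h, out_w); Fx <- matrix(fx, out_h, out_w, byrow = TRUE)
  m00 * (1 - Fy) * (1 - Fx) + m01 * (1 - Fy) * Fx +
    m10 * Fy * (1 - Fx) + m11 * Fy * Fx
}

# Rotate image content by `angle_deg` about the image center (in the x-right /
# y-down frame; positive angles follow the same sense as ellipse theta).
# interp: "bilinear" for intensity images, "nearest" for masks.
# fill: value for samples falling outside the source frame.
rotate_grid <- function(m, angle_deg, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  # inverse map: output pixel -> source location
  X <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  Y <- matrix(0:(h - 1), h, w) - cy
  sxv <-  cos(th) * X + sin(th) * Y + cx
  syv <- -sin(th) * X + cos(th) * Y + cy
  if (interp == "nearest") {
    xi <- round(sxv); yi <- round(syv)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out <- matrix(fill, h, w)
    out[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1)]
    return(out)
  }
  x0 <- floor(sxv); y0 <- floor(syv)
  fx <- sxv - x0; fy <- syv - y0
  out <- matrix(fill, h, w)
  ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  gv <- function(yy, xx) {
    inb <- yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1 & ok
    v <- matrix(fill, h, w)
    v[inb] <- m[cbind(yy[inb] + 1, xx[inb] + 1)]
    v
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  res <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
  out[ok] <- res[ok]
  out
}

# 8-connected component labeling via igraph. Returns an integer matrix of
# labels (0 = background), labels are arbitrary positive integers.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0)
  if (length(fg) == 0L) return(matrix(0L, h, w))
  rank <- integer(h * w)
  rank[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rows + d[1L]; nc <- cols + d[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    keep <- rank[nidx] > 0L
    if (any(keep))
      edges <- c(edges, rbind(rank[fg[ok]][keep], rank[nidx][keep]))
  }
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else edges,
                          n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, h, w)
  lab[fg] <- as.integer(memb)
  lab
}
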