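# Post-processing of raw segmentation maps: threshold, Canny edge detection,
# largest-connected-component filtering, contour point extraction. This turns
# a possibly noisy or holey head segmentation into a clean point set ready for
# ellipse fitting.

#' Construct a binary segmentation mask
#'
#' @param grid A binary (0/1) matrix, rows = y, columns = x.
#' @param semantics Either `"region"` (filled head) or `"contour"` (skull
#'   band / edge map).
#' @return An integer 0/1 matrix of class `seg_mask` with a `semantics`
#'   attribute.
#' @export
seg_mask <- function(grid, semantics = c("region", "contour")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(grid) || nrow(grid) == 0L || ncol(grid) == 0L)
    stop_invalid_input("mask must be a nonempty matrix")
  if (!all(grid %in% c(0, 1)))
    stop_invalid_input("mask values must be 0 or 1")
  m <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  attr(m, "semantics") <- semantics
  class(m) <- c("seg_mask", class(m))
  m
}

is_seg_mask <- function(x) inherits(x, "seg_mask")

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to the threshold are set to 1
#' (the `>=` convention: a pixel at exactly the threshold is foreground).
#'
#' @param prob_map Numeric matrix with values in \[0, 1\].
#' @param threshold Scalar threshold, default 0.5.
#' @return A [seg_mask()] with `region` semantics.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (!is.matrix(prob_map) || !is.numeric(prob_map))
    stop_invalid_input("probability map must be a numeric matrix")
  if (any(!is.finite(prob_map)) || any(prob_map < 0) || any(prob_map > 1))
    stop_invalid_input("probability map values must lie in [0, 1]")
  seg_mask((prob_map >= threshold) * 1L, semantics = "region")
}

#' Detect mask boundaries with a Canny filter
#'
#' Runs a Canny edge detector (Gaussian blur with `sigma`, Sobel gradients,
#' non-maximum suppression, hysteresis) on the mask scaled to 0--255. The
#' hysteresis thresholds are fixed at (100, 200); on a binary input any
#' mid-range pair gives the same result, and the pair is frozen for
#' reproducibility. An empty mask yields an empty edge map (not an error).
#'
#' @param mask A binary mask (matrix or [seg_mask()]).
#' @param sigma Gaussian blur standard deviation in pixels.
#' @param low,high Hysteresis thresholds on the 0--255 gradient-magnitude
#'   scale.
#' @return A [seg_mask()] with `contour` semantics.
#' @export
detect_edges <- function(mask, sigma = 1, low = 100, high = 200) {
  canny_fields(mask, sigma, low, high)$edges
}

# Full Canny with the gradient fields kept, so callers can do subpixel
# localization of the retained edge pixels.
canny_fields <- function(mask, sigma = 1, low = 100, high = 200) {
  if (!is.matrix(mask)) stop_invalid_input("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop_invalid_input("mask must be binary")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  empty <- function() list(
    edges = seg_mask(matrix(0L, nrow(m), ncol(m)), semantics = "contour"),
    mag = NULL, gx = NULL, gy = NULL)
  if (sum(m) == 0) return(empty())
  sm <- gauss_blur(m * 255, sigma = sigma)
  g <- sobel(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180
  # quantize gradient direction into 4 bins and compare along the gradient
  sector <- integer(length(ang))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L   # gradient ~ x -> neighbors L/R
  sector[ang >= 22.5 & ang < 67.5]      <- 1L   # diagonal
  sector[ang >= 67.5 & ang < 112.5]     <- 2L   # gradient ~ y -> up/down
  sector[ang >= 112.5 & ang < 157.5]    <- 3L
  sector <- matrix(sector, nrow(m), ncol(m))
  n1 <- matrix(0, nrow(m), ncol(m)); n2 <- n1
  pick <- function(dy, dx) shift_mat(mag, dy, dx)
  # neighbors along the gradient direction (dy, dx) and its opposite
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    sel <- sector == s
    n1[sel] <- pick(o[1], o[2])[sel]
    n2[sel] <- pick(-o[1], -o[2])[sel]
  }
  nms <- mag >= n1 & mag > n2 & mag > 0
  strong <- nms & mag >= high
  cand <- nms & mag >= low
  if (!any(strong)) return(empty())
  lab <- label_components8(cand * 1L)
  keep_labels <- unique(lab[strong])
  out <- (lab %in% setdiff(keep_labels, 0L)) * 1L
  list(edges = seg_mask(matrix(as.integer(out), nrow(m), ncol(m)),
                        semantics = "contour"),
       mag = mag, gx = g$gx, gy = g$gy)
}

# bilinear sample of matrix m at continuous 0-based coordinates (x, y)
sample_bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  m[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
    m[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
    m[cbind(y1 + 1, x1 + 1)] * fy * fx
}

#' Keep the largest 8-connected component of a mask
#'
#' Connectivity is 8-neighborhood. Ties in component size are broken by the
#' component containing the smallest pixel in row-major order (scanning rows
#' top to bottom, left to right within a row).
#'
#' @param mask A binary mask (matrix or [seg_mask()]).
#' @return A [seg_mask()] containing only the largest component, with the
#'   input's semantics (default `region` for plain matrices).
#' @section Errors: an all-zero mask signals `fetalhc_empty_mask`.
#' @export
largest_component <- function(mask) {
  if (!is.matrix(mask)) stop_invalid_input("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop_invalid_input("mask must be binary")
  sem <- attr(mask, "semantics")
  if (is.null(sem)) sem <- "region"
  if (sum(mask) == 0) stop_empty_mask("cannot take largest component of an empty mask")
  lab <- label_components8(mask)
  h <- nrow(mask); w <- ncol(mask)
  sizes <- tabulate(lab[lab > 0L])
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # row-major index of each pixel: row * w + col (0-based)
    fg <- which(lab > 0L)
    rm_idx <- (((fg - 1L) %% h)) * w + ((fg - 1L) %/% h)
    first <- vapply(cand, function(l) min(rm_idx[lab[fg] == l]), numeric(1))
    best <- cand[which.min(first)]
  } else best <- cand
  seg_mask((lab == best) * 1L, semantics = sem)
}

#' Reduce a raw segmentation to contour points of the dominant component
#'
#' Composition of the post-processing chain: threshold (if given a probability
#' map), Canny edge detection, largest-connected-component filtering, and
#' extraction of 0-based `(x, y)` pixel coordinates, ordered by polar angle
#' about their centroid. By default each retained edge pixel is localized to
#' subpixel accuracy by parabolic interpolation of the gradient magnitude
#' along the gradient direction, which removes most of the half-pixel
#' quantization error of the raw edge map before ellipse fitting.
#'
#' @param raw Either a numeric probability map in \[0, 1\] or a binary mask.
#' @param threshold Binarization threshold used when `raw` is a probability
#'   map.
#' @param subpixel Refine edge coordinates along the gradient (default TRUE);
#'   set to FALSE for raw integer pixel coordinates.
#' @return An `n x 2` matrix of contour coordinates (columns `x`, `y`),
#'   `n >= 5`.
#' @section Errors: fewer than 5 surviving contour points signals
#'   `fetalhc_fit_failure` with cause `"empty_contour"`, marking the
#'   segmentation as unusable.
#' @export
postprocess_to_points <- function(raw, threshold = 0.5, subpixel = TRUE) {
  if (!is.matrix(raw)) stop_invalid_input("input must be a matrix")
  mask <- if (all(raw %in% c(0, 1))) seg_mask(raw + 0L) else
    binarize(raw, threshold)
  cf <- canny_fields(mask)
  if (sum(cf$edges) == 0)
    stop_fit_failure("no contour pixels survive post-processing",
                     cause = "empty_contour")
  comp <- largest_component(cf$edges)
  idx <- which(comp == 1L)
  h <- nrow(comp)
  xs <- (idx - 1L) %/% h      # 0-based column
  ys <- (idx - 1L) %% h       # 0-based row
  if (length(xs) < 5L)
    stop_fit_failure(sprintf(
      "only %d contour points survive post-processing", length(xs)),
      cause = "empty_contour")
  if (subpixel) {
    gx <- cf$gx[idx]; gy <- cf$gy[idx]
    gn <- sqrt(gx^2 + gy^2)
    ok <- gn > 0
    ux <- ifelse(ok, gx / gn, 0); uy <- ifelse(ok, gy / gn, 0)
    m0 <- cf$mag[idx]
    mp <- sample_bilinear(cf$mag, xs + ux, ys + uy)
    mm <- sample_bilinear(cf$mag, xs - ux, ys - uy)
    den <- mm - 2 * m0 + mp
    t <- ifelse(abs(den) > 1e-12, 0.5 * (mm - mp) / den, 0)
    t <- pmin(pmax(t, -1), 1)
    xs <- xs + t * ux
    ys <- ys + t * uy
  }
  ord <- order(atan2(ys - mean(ys), xs - mean(xs)))
  cbind(x = xs[ord], y = ys[ord])
}

#' Extract boundary points of a filled region mask
#'
#' A foreground pixel is a boundary pixel if any of its 4-neighbors is
#' background or lies outside the grid. Used to obtain contour point sets for
#' the surface-distance metrics.
#'
#' @param mask A binary region mask.
#' @return An `n x 2` matrix of 0-based `(x, y)` coordinates.
#' @export
boundary_points <- function(mask) {
  if (!is.matrix(mask)) stop_invalid_input("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop_invalid_input("mask must be binary")
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop_empty_mask("mask has no foreground")
  pad <- function(dy, dx) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0L, h, w)
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  nb_min <- pmin(pad(1L, 0L), pad(-1L, 0L), pad(0L, 1L), pad(0L, -1L))
  b <- m == 1L & nb_min == 0L
  idx <- which(b)
  h <- nrow(m)
  cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are stored as 8-bit grayscale PNG with foreground 255 and background
#' 0.
#'
#' @param mask A binary mask.
#' @param path File path.
#' @return `read_mask_png` returns a [seg_mask()]; `write_mask_png` returns
#'   `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop_invalid_input("mask must be binary")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  seg_mask((m >= 0.5) * 1L)
}
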