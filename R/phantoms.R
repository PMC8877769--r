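# Synthetic elliptical skull phantoms with analytically known head
# circumference. Each phantom is an 8-bit-quantized grayscale image containing
# a bright elliptical band (the skull) with optional missing angular segments,
# speckle-like multiplicative noise and background clutter, together with the
# exact generating ellipse, a filled ground-truth mask, a band (contour) mask,
# the per-image pixel spacing, and the analytic HC (exact elliptic-integral
# perimeter of the physical ellipse).

#' Phantom generator configuration
#'
#' Ranges and noise settings for the synthetic skull phantoms. Defaults are
#' chosen to emulate fetal-ultrasound biometry images: the head occupies a
#' substantial, variable fraction of the frame, the skull band is a few pixels
#' thick with partially missing segments (fuzzy borders), speckle is
#' multiplicative, and the physical pixel spacing varies per image within
#' `spacing_range`. Spacing is tied to the rendered head size through a
#' monotone log-uniform link with Gaussian jitter (`spacing_jitter`, on the
#' unit interval), emulating the sonographer adjusting the imaging depth to
#' the fetal head with operator variability; without such a link the HC in mm
#' would be unidentifiable from the image alone.
#'
#' @param size `c(H, W)` image size in pixels.
#' @param spacing_range Per-image pixel size range, mm/pixel.
#' @param spacing_jitter Standard deviation of the jitter on the unit-interval
#'   spacing link.
#' @param a_frac Range of the semi-major axis as a fraction of `min(size)`.
#' @param ratio Range of the axis ratio `b/a`.
#' @param center_jitter_frac Max center offset from the frame center, as a
#'   fraction of `min(size)`.
#' @param band_px Full thickness of the skull band along the minor axis,
#'   pixels.
#' @param gap_fraction Total fraction of the band's parametric angle removed
#'   as missing segments.
#' @param n_gaps Number of missing segments.
#' @param speckle Logical; add multiplicative speckle-like noise.
#' @param speckle_sd Speckle amplitude (relative).
#' @param clutter_n Number of dim background clutter blobs.
#' @param bg_level,band_level Background and skull-band intensities in
#'   \[0, 1\].
#' @param margin Minimum distance (pixels) between the outer band and the
#'   frame border.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(size = c(128L, 128L),
                           spacing_range = c(0.05, 0.3),
                           spacing_jitter = 0.04,
                           a_frac = c(0.16, 0.30),
                           ratio = c(0.6, 0.95),
                           center_jitter_frac = 0.06,
                           band_px = 3,
                           gap_fraction = 0.15,
                           n_gaps = 2L,
                           speckle = TRUE,
                           speckle_sd = 0.25,
                           clutter_n = 2L,
                           bg_level = 0.18,
                           band_level = 0.85,
                           margin = 4) {
  cfg <- list(size = as.integer(size), spacing_range = spacing_range,
              spacing_jitter = spacing_jitter, a_frac = a_frac, ratio = ratio,
              center_jitter_frac = center_jitter_frac, band_px = band_px,
              gap_fraction = gap_fraction, n_gaps = as.integer(n_gaps),
              speckle = isTRUE(speckle), speckle_sd = speckle_sd,
              clutter_n = as.integer(clutter_n), bg_level = bg_level,
              band_level = band_level, margin = margin)
  if (length(cfg$size) != 2L || any(cfg$size < 16L))
    stop_invalid_parameter("size must be two integers >= 16")
  if (cfg$spacing_range[1] <= 0 || diff(cfg$spacing_range) < 0)
    stop_invalid_parameter("spacing_range must be positive and ordered")
  if (cfg$a_frac[1] <= 0 || cfg$a_frac[2] > 0.45)
    stop_invalid_parameter("a_frac must lie in (0, 0.45]")
  if (cfg$ratio[1] <= 0 || cfg$ratio[2] > 1)
    stop_invalid_parameter("ratio must lie in (0, 1]")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 1)
    stop_invalid_parameter("gap_fraction must lie in [0, 1)")
  structure(cfg, class = "phantom_config")
}

# run expr with a private, seeded RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# perimeter range implied by the configured geometry ranges (pixel domain)
perimeter_range_px <- function(config) {
  s <- min(config$size)
  a_min <- config$a_frac[1] * s; a_max <- config$a_frac[2] * s
  c(exact_perimeter(a_min, a_min * config$ratio[1]),
    exact_perimeter(a_max, a_max * config$ratio[2]))
}

#' Generate one synthetic skull phantom
#'
#' Samples an ellipse (center jitter, semi-axes, orientation uniform in the
#' configured ranges), renders the bright skull band with optional missing
#' angular segments, adds clutter blobs and multiplicative speckle, quantizes
#' to 8 bits, and returns the record together with exact ground truth. The
#' ground-truth fields (masks, ellipse, spacing, analytic HC) are independent
#' of the image corruption. Deterministic per seed.
#'
#' @param seed Integer seed for this record.
#' @param config A [phantom_config()].
#' @return A list of class `phantom_record`: `id`, `image` (matrix in
#'   \[0, 1\], 8-bit quantized), `gt_mask` (filled head region),
#'   `gt_contour` (full band mask), `ellipse` ([ellipse_params()]), `spacing`
#'   ([pixel_spacing()], isotropic), `hc_mm` (exact perimeter of the physical
#'   ellipse).
#' @export
generate_phantom <- function(seed, config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$size[1]; W <- config$size[2]
  smin <- min(H, W)
  with_seed(seed, {
    a <- stats::runif(1, config$a_frac[1], config$a_frac[2]) * smin
    b <- a * stats::runif(1, config$ratio[1], config$ratio[2])
    theta <- stats::runif(1, 0, 180)
    th <- theta * pi / 180
    half_band <- config$band_px / 2
    # rotated-ellipse half extents along x and y, including the band
    ex <- sqrt(a^2 * cos(th)^2 + b^2 * sin(th)^2) + half_band + config$margin
    ey <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2) + half_band + config$margin
    jit <- config$center_jitter_frac * smin
    cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
    jx <- min(jit, max(0, cx0 - ex)); jy <- min(jit, max(0, cy0 - ey))
    cx <- cx0 + stats::runif(1, -jx, jx)
    cy <- cy0 + stats::runif(1, -jy, jy)
    if (cx - ex < -0.5 || cx + ex > W - 0.5 || cy - ey < -0.5 || cy + ey > H - 0.5)
      stop_invalid_parameter("configured ellipse does not fit inside the frame")
    ell <- ellipse_params(cx, cy, a, b, theta)

    # spacing via log-uniform link to pixel-domain perimeter + jitter
    pr <- perimeter_range_px(config)
    p_px <- exact_perimeter(a, b)
    z <- (p_px - pr[1]) / max(pr[2] - pr[1], .Machine$double.eps)
    z <- min(max(z + stats::rnorm(1, 0, config$spacing_jitter), 0), 1)
    sp <- config$spacing_range[1] *
      (config$spacing_range[2] / config$spacing_range[1])^z
    spacing <- pixel_spacing(sp)
    hc <- exact_perimeter(a * sp, b * sp)

    # elliptical coordinate r over the grid
    X <- matrix(0:(W - 1), H, W, byrow = TRUE) - cx
    Y <- matrix(0:(H - 1), H, W) - cy
    u <- X * cos(th) + Y * sin(th)
    v <- -X * sin(th) + Y * cos(th)
    r <- sqrt((u / a)^2 + (v / b)^2)
    gt_mask <- (r <= 1) * 1L
    wband <- half_band / b
    band <- r >= 1 - wband & r <= 1 + wband

    band_visible <- band
    if (config$gap_fraction > 0 && config$n_gaps > 0L) {
      phi <- atan2(v / b, u / a)
      centers <- stats::runif(config$n_gaps, -pi, pi)
      halfw <- config$gap_fraction * pi / config$n_gaps
      in_gap <- matrix(FALSE, H, W)
      for (g in centers) {
        dphi <- abs(((phi - g + pi) %% (2 * pi)) - pi)
        in_gap <- in_gap | dphi <= halfw
      }
      band_visible <- band & !in_gap
    }

    img <- matrix(config$bg_level, H, W)
    img[band_visible] <- config$band_level
    if (config$clutter_n > 0L) {
      for (k in seq_len(config$clutter_n)) {
        ccx <- stats::runif(1, 0, W - 1); ccy <- stats::runif(1, 0, H - 1)
        sg <- stats::runif(1, 2, 5)
        amp <- stats::runif(1, 0.15, 0.35)
        img <- img + amp * exp(-(((X + cx - ccx)^2 + (Y + cy - ccy)^2) /
                                   (2 * sg^2)))
      }
    }
    if (config$speckle) {
      noise <- gauss_blur(matrix(stats::rnorm(H * W), H, W), sigma = 1)
      noise <- noise / stats::sd(noise)
      img <- img * (1 + config$speckle_sd * noise)
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255     # 8-bit quantization

    structure(list(
      id = sprintf("phantom_%010d", as.integer(seed)),
      image = img,
      gt_mask = seg_mask(gt_mask, semantics = "region"),
      gt_contour = seg_mask(band * 1L, semantics = "contour"),
      ellipse = ell, spacing = spacing, hc_mm = hc
    ), class = "phantom_record")
  })
}

#' Generate a phantom dataset
#'
#' Generates `n` phantoms with distinct per-record seeds derived from `seed`,
#' plus an annotation table (filename, pixel size in mm, HC in mm). When `dir`
#' is given, the dataset is also written to disk in the challenge-style
#' layout: `images/NNN.png`, `masks/NNN_Annotation.png` and
#' `annotations.csv`.
#'
#' @param n Number of phantoms.
#' @param seed Dataset seed.
#' @param config A [phantom_config()].
#' @param dir Optional output directory.
#' @return A list with `records` (list of `phantom_record`) and `annotations`
#'   (data frame: `filename`, `pixel_size_mm`, `hc_mm`).
#' @export
generate_dataset <- function(n, seed, config = phantom_config(), dir = NULL) {
  if (!is.numeric(n) || n < 1L) stop_invalid_parameter("n must be >= 1")
  n <- as.integer(n)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  records <- lapply(seeds, generate_phantom, config = config)
  fnames <- sprintf("%03d.png", seq_len(n))
  for (i in seq_len(n)) records[[i]]$id <- sprintf("%03d", i)
  annotations <- data.frame(
    filename = fnames,
    pixel_size_mm = vapply(records, function(r) r$spacing$sx, numeric(1)),
    hc_mm = vapply(records, function(r) r$hc_mm, numeric(1)),
    stringsAsFactors = FALSE)
  ds <- list(records = records, annotations = annotations)
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Split a dataset into train/validation/test index sets
#'
#' A seeded random permutation of the record indices, partitioned into the
#' three requested counts. The counts must sum to the dataset size; the three
#' index sets are disjoint and exhaustive.
#'
#' @param n_records Number of records (or a list of records).
#' @param n_train,n_val,n_test Split sizes.
#' @param seed Split seed.
#' @return A list with integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_records, n_train, n_val, n_test, seed = 1L) {
  n <- if (is.list(n_records)) length(n_records) else as.integer(n_records)
  if (any(c(n_train, n_val, n_test) < 0))
    stop_invalid_parameter("split counts must be nonnegative")
  if (n_train + n_val + n_test != n)
    stop_invalid_parameter(sprintf(
      "split counts (%d + %d + %d) must sum to the dataset size %d",
      n_train, n_val, n_test, n))
  perm <- with_seed(seed, sample.int(n))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

# flip a phantom record horizontally (x -> W-1-x)
flip_record <- function(rec) {
  W <- ncol(rec$image)
  rev_cols <- function(m) m[, W:1, drop = FALSE]
  e <- rec$ellipse
  rec$image <- rev_cols(rec$image)
  rec$gt_mask <- seg_mask(rev_cols(rec$gt_mask), "region")
  rec$gt_contour <- seg_mask(rev_cols(rec$gt_contour), "contour")
  rec$ellipse <- ellipse_params((W - 1) - e$cx, e$cy, e$a, e$b,
                                (180 - e$theta) %% 180)
  rec$id <- paste0(rec$id, "_flip")
  rec
}

# rotate a phantom record by `angle` degrees about the image center
rotate_record <- function(rec, angle = 10) {
  H <- nrow(rec$image); W <- ncol(rec$image)
  e <- rec$ellipse
  cx0 <- (W - 1) / 2; cy0 <- (H - 1) / 2
  th <- angle * pi / 180
  dx <- e$cx - cx0; dy <- e$cy - cy0
  ncx <- cx0 + cos(th) * dx - sin(th) * dy
  ncy <- cy0 + sin(th) * dx + cos(th) * dy
  new_e <- ellipse_params(ncx, ncy, e$a, e$b, (e$theta + angle) %% 180)
  # padding policy: content leaving the frame is clipped; fill with the
  # background median. Warn if the rotated band no longer fits.
  tr <- new_e$theta * pi / 180
  ex <- sqrt(e$a^2 * cos(tr)^2 + e$b^2 * sin(tr)^2)
  ey <- sqrt(e$a^2 * sin(tr)^2 + e$b^2 * cos(tr)^2)
  if (ncx - ex < -0.5 || ncx + ex > W - 0.5 || ncy - ey < -0.5 ||
      ncy + ey > H - 0.5)
    warning(sprintf("rotated ellipse of record %s is clipped by the frame",
                    rec$id))
  fill <- stats::median(c(rec$image[1, ], rec$image[H, ],
                          rec$image[, 1], rec$image[, W]))
  rec$image <- rotate_grid(rec$image, angle, "bilinear", fill = fill)
  rec$gt_mask <- seg_mask(rotate_grid(matrix(as.numeric(rec$gt_mask), H, W),
                                      angle, "nearest", fill = 0), "region")
  rec$gt_contour <- seg_mask(rotate_grid(matrix(as.numeric(rec$gt_contour),
                                                H, W),
                                         angle, "nearest", fill = 0), "contour")
  rec$ellipse <- new_e
  rec$id <- paste0(rec$id, "_rot", angle)
  rec
}

#' Augment a training set
#'
#' For each record emits three: the original, a horizontally flipped copy, and
#' a copy rotated by +10 degrees about the image center (so 600 inputs become
#' 1800). Masks and ellipse parameters are transformed consistently with the
#' image; the reference HC is exactly unchanged by both operations (flips and
#' rotations are rigid).
#'
#' @param records List of `phantom_record`s.
#' @param angle Rotation angle in degrees (default 10).
#' @return A list of `3 * length(records)` records.
#' @export
augment_training_set <- function(records, angle = 10) {
  if (length(records) == 0L) stop_invalid_input("no records to augment")
  out <- vector("list", 3L * length(records))
  j <- 1L
  for (rec in records) {
    out[[j]] <- rec
    out[[j + 1L]] <- flip_record(rec)
    out[[j + 2L]] <- rotate_record(rec, angle)
    j <- j + 3L
  }
  out
}

#' Reproducible k-fold cross-validation indices
#'
#' Deterministic folds for a seed: a seeded permutation cut into `k`
#' consecutive test folds. When `n` is not divisible by `k` the larger folds
#' come first (n = 999, k = 5 gives test folds of 200, 200, 200, 200, 199).
#' Every index appears in exactly one test fold; the same object should be
#' reused across all methods being compared.
#'
#' @param n Number of cases.
#' @param k Number of folds.
#' @param seed Fold seed.
#' @return A list of `k` lists, each with integer vectors `train` and `test`.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop_invalid_parameter("n must be at least k")
  perm <- with_seed(seed, sample.int(n))
  base <- n %/% k; rem <- n %% k
  sizes <- base + as.integer(seq_len(k) <= rem)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- sort(perm[starts[i]:ends[i]])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
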