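# Synthetic phantom generator: determinism, ground-truth consistency,
# splitting, augmentation, k-fold indices.

test_that("generate_phantom is deterministic and self-consistent", {
  r1 <- generate_phantom(123)
  r2 <- generate_phantom(123)
  expect_identical(r1, r2)
  # analytic HC consistent with the stored ellipse and spacing
  e <- r1$ellipse; sp <- r1$spacing
  expect_equal(r1$hc_mm, exact_perimeter(e$a * sp$sx, e$b * sp$sx),
               tolerance = 1e-9)
  # mask consistent with the ellipse rasterization
  expect_identical(as.integer(r1$gt_mask),
                   as.integer(rasterize_ellipse(e, nrow(r1$image),
                                                ncol(r1$image))))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
})

test_that("corruption does not touch the ground truth", {
  clean_cfg <- phantom_config(speckle = FALSE, gap_fraction = 0,
                              clutter_n = 0L)
  noisy_cfg <- phantom_config(gap_fraction = 0.25)
  c1 <- generate_phantom(77, clean_cfg)
  n1 <- generate_phantom(77, noisy_cfg)
  expect_identical(unclass(c1$ellipse), unclass(n1$ellipse))
  expect_identical(as.integer(c1$gt_mask), as.integer(n1$gt_mask))
  expect_equal(c1$hc_mm, n1$hc_mm)
  expect_false(identical(c1$image, n1$image))
})

test_that("oracle segmentation route recovers phantom HC within 1%", {
  cfg <- phantom_config(speckle = FALSE, gap_fraction = 0, clutter_n = 0L)
  set.seed(2)
  for (s in sample.int(1e6, 15)) {
    r <- generate_phantom(s, cfg)
    p <- estimate_hc_segmentation(r$image, "oracle", r$spacing,
                                  oracle_mask = r$gt_mask)
    expect_false(p$failed)
    expect_lt(abs(p$hc_mm - r$hc_mm) / r$hc_mm, 0.01)
  }
})

test_that("generate_dataset emits consistent annotations and files", {
  dir <- tempfile()
  ds <- generate_dataset(8, seed = 7, dir = dir)
  expect_length(ds$records, 8)
  expect_equal(nrow(ds$annotations), 8)
  expect_length(list.files(file.path(dir, "images")), 8)
  expect_length(list.files(file.path(dir, "masks")), 8)
  # HC column vs recomputed perimeter from stored ellipse parameters
  for (i in 1:8) {
    r <- ds$records[[i]]
    expect_equal(ds$annotations$hc_mm[i],
                 exact_perimeter(r$ellipse$a * r$spacing$sx,
                                 r$ellipse$b * r$spacing$sx),
                 tolerance = 1e-9)
  }
  # same seed -> identical annotations
  ds2 <- generate_dataset(8, seed = 7)
  expect_identical(ds$annotations, ds2$annotations)
  unlink(dir, recursive = TRUE)
})

test_that("split_dataset partitions exhaustively and reproducibly", {
  sp <- split_dataset(999, 600, 199, 200, seed = 4)
  expect_length(sp$train, 600)
  expect_length(sp$val, 199)
  expect_length(sp$test, 200)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, 1:999)
  expect_equal(anyDuplicated(all_idx), 0)
  expect_identical(sp, split_dataset(999, 600, 199, 200, seed = 4))
  # degenerate split
  sp0 <- split_dataset(10, 10, 0, 0)
  expect_setequal(sp0$train, 1:10)
  expect_error(split_dataset(10, 5, 4, 2), class = "fetalhc_invalid_parameter")
})

test_that("augmentation triples the set and preserves HC exactly", {
  cfg <- phantom_config()
  recs <- lapply(c(5, 6, 7), generate_phantom, config = cfg)
  aug <- augment_training_set(recs)
  expect_length(aug, 9)
  hc0 <- rep(vapply(recs, `[[`, numeric(1), "hc_mm"), each = 3)
  expect_identical(vapply(aug, `[[`, numeric(1), "hc_mm"), hc0)
})

test_that("flip and rotation transform the ellipse consistently with masks", {
  rec <- generate_phantom(55)
  aug <- augment_training_set(list(rec))
  flipped <- aug[[2]]; rotated <- aug[[3]]
  W <- ncol(rec$image)
  e <- rec$ellipse
  expect_equal(flipped$ellipse$cx, (W - 1) - e$cx)
  expect_equal(flipped$ellipse$theta, (180 - e$theta) %% 180)
  # double flip is the identity
  f2 <- augment_training_set(list(flipped))[[2]]
  expect_equal(f2$ellipse$cx, e$cx)
  expect_identical(as.integer(f2$gt_mask), as.integer(rec$gt_mask))
  # refitting the transformed masks recovers the transformed ellipses
  for (r in list(flipped, rotated)) {
    f <- fit_ellipse(postprocess_to_points(matrix(as.numeric(r$gt_mask),
                                                  nrow(r$gt_mask))))
    expect_equal(f$cx, r$ellipse$cx, tolerance = 0.15)
    expect_equal(f$cy, r$ellipse$cy, tolerance = 0.15)
    expect_equal(f$a, r$ellipse$a, tolerance = 0.01)
    expect_equal(f$b, r$ellipse$b, tolerance = 0.01)
    expect_lt(theta_diff(f$theta, r$ellipse$theta), 1)
  }
})

test_that("kfold_indices are disjoint, exhaustive, reproducible, larger first", {
  f <- kfold_indices(10, 5, seed = 3)
  expect_length(f, 5)
  tests <- lapply(f, `[[`, "test")
  expect_true(all(lengths(tests) == 2))
  expect_setequal(unlist(tests), 1:10)
  expect_identical(f, kfold_indices(10, 5, seed = 3))
  for (i in 1:5) {
    expect_length(intersect(f[[i]]$train, f[[i]]$test), 0)
    expect_setequal(c(f[[i]]$train, f[[i]]$test), 1:10)
  }
  # 999 cases, 5 folds: sizes 200,200,200,200,199 (larger folds first)
  f <- kfold_indices(999, 5, seed = 1)
  expect_identical(lengths(lapply(f, `[[`, "test")),
                   c(200L, 200L, 200L, 200L, 199L))
  expect_error(kfold_indices(3, 5), class = "fetalhc_invalid_parameter")
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_phantom(1))
  expect_identical(runif(1), before)
})
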