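# Ellipse geometry: perimeter formulas, fitting, rescaling, mm conversion.

test_that("ramanujan circumference matches circle and quadrature references", {
  # circle: 2*pi*r to machine precision
  expect_equal(ramanujan_circumference(1, 1), 2 * pi, tolerance = 1e-15)
  expect_equal(ramanujan_circumference(3, 3), 6 * pi, tolerance = 1e-15)
  # 2:1 ellipse against an independent evaluation of the complete elliptic
  # integral of the second kind (AGM method, pracma), P = 4 a E(e^2)
  skip_if_not_installed("pracma")
  p_oracle <- 4 * 2 * pracma::ellipke(1 - (1 / 2)^2)$e
  expect_equal(ramanujan_circumference(2, 1), p_oracle, tolerance = 1e-5)
  expect_equal(exact_perimeter(2, 1), p_oracle, tolerance = 1e-10)
})

test_that("ramanujan circumference is symmetric and scale-equivariant", {
  expect_identical(ramanujan_circumference(2, 1), ramanujan_circumference(1, 2))
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50); k <- runif(1, 0.01, 100)
    expect_equal(ramanujan_circumference(k * a, k * b),
                 k * ramanujan_circumference(a, b), tolerance = 1e-12)
  }
})

test_that("ramanujan stays within 1e-6 of quadrature for b/a >= 0.2", {
  ratios <- seq(0.2, 1, length.out = 50)
  avals <- seq(1, 100, length.out = 50)
  for (a in avals) {
    b <- a * ratios
    rel <- abs(ramanujan_circumference(a, b) - exact_perimeter(a, b)) /
      exact_perimeter(a, b)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("exact perimeter handles the degenerate-segment limit", {
  expect_equal(exact_perimeter(1, 1e-6), 4, tolerance = 1e-3)
  expect_equal(exact_perimeter(3, 3), 6 * pi, tolerance = 1e-12)
})

test_that("perimeter functions reject nonpositive axes", {
  expect_error(ramanujan_circumference(0, 1), class = "fetalhc_invalid_parameter")
  expect_error(ramanujan_circumference(1, -2), class = "fetalhc_invalid_parameter")
  expect_error(exact_perimeter(-1, 1), class = "fetalhc_invalid_parameter")
})

test_that("ellipse_params normalizes axes order, angle range and circles", {
  e <- ellipse_params(0, 0, a = 2, b = 5, theta = 10)
  expect_equal(e$a, 5)
  expect_equal(e$b, 2)
  expect_equal(e$theta, 100)
  expect_equal(ellipse_params(0, 0, 1, 2, theta = 350)$theta, 80) # 350+90 mod 180
  expect_equal(ellipse_params(0, 0, 3, 3, theta = 77)$theta, 0)   # circle
  expect_error(ellipse_params(0, 0, -1, 1), class = "fetalhc_invalid_parameter")
  expect_error(ellipse_params(Inf, 0, 1, 1), class = "fetalhc_invalid_parameter")
})

test_that("fit_ellipse recovers exact parameters from noiseless samples", {
  e <- ellipse_params(5, -3, 4, 2, 30)
  f <- fit_ellipse(ellipse_points(e, 100))
  expect_equal(f$cx, 5, tolerance = 1e-6)
  expect_equal(f$cy, -3, tolerance = 1e-6)
  expect_equal(f$a, 4, tolerance = 1e-6)
  expect_equal(f$b, 2, tolerance = 1e-6)
  expect_lt(theta_diff(f$theta, 30), 1e-6)
})

test_that("fit_ellipse round-trips 100 random ellipses within 1e-6", {
  set.seed(7)
  for (i in 1:100) {
    e <- ellipse_params(runif(1, -100, 100), runif(1, -100, 100),
                        a = runif(1, 1, 80), b = runif(1, 1, 80),
                        theta = runif(1, 0, 180))
    f <- fit_ellipse(ellipse_points(e, 60))
    expect_lt(max(abs(c(f$cx - e$cx, f$cy - e$cy, f$a - e$a, f$b - e$b))),
              1e-6 * max(1, e$a))
    if ((e$a - e$b) / e$a > 1e-3) expect_lt(theta_diff(f$theta, e$theta), 1e-4)
  }
})

test_that("fit_ellipse failure modes carry distinct causes", {
  err <- tryCatch(fit_ellipse(cbind(1:4, 1:4 + 1)), condition = identity)
  expect_s3_class(err, "fetalhc_fit_failure")
  expect_identical(fit_failure_cause(err), "too_few_points")
  # collinear
  err <- tryCatch(fit_ellipse(cbind(1:20, 2 * (1:20) + 3)),
                  condition = identity)
  expect_s3_class(err, "fetalhc_fit_failure")
  expect_identical(fit_failure_cause(err), "degenerate_points")
  # coincident
  err <- tryCatch(fit_ellipse(matrix(1, 10, 2)), condition = identity)
  expect_identical(fit_failure_cause(err), "degenerate_points")
})

test_that("fit_ellipse on circle points returns equal axes", {
  t <- seq(0, 2 * pi, length.out = 50)
  f <- fit_ellipse(cbind(10 + 7 * cos(t), -2 + 7 * sin(t)))
  expect_equal(f$a, 7, tolerance = 1e-6)
  expect_equal(f$b, 7, tolerance = 1e-6)
  # theta unconstrained for circles; the constructor reports 0
  expect_equal(f$theta, 0)
})

test_that("rescale_ellipse matches axis-aligned expectations and identity", {
  e <- ellipse_params(3, 4, 2, 1, 0)
  r <- rescale_ellipse(e, 2, 1)
  expect_equal(c(r$a, r$b, r$theta, r$cx, r$cy), c(4, 1, 0, 6, 4),
               tolerance = 1e-12)
  e2 <- ellipse_params(-1, 2, 5, 3, 77)
  r2 <- rescale_ellipse(e2, 1, 1)
  expect_equal(unclass(r2), unclass(e2), tolerance = 1e-12)
  expect_error(rescale_ellipse(e, 0, 1), class = "fetalhc_invalid_parameter")
})

test_that("rescale_ellipse equals a point-map + refit oracle for rotated input", {
  e <- ellipse_params(10, 20, 3, 1, 45)
  r <- rescale_ellipse(e, 2, 0.5)
  pts <- ellipse_points(e, 360)
  f <- fit_ellipse(cbind(pts[, 1] * 2, pts[, 2] * 0.5))
  expect_equal(r$a, f$a, tolerance = 1e-9)
  expect_equal(r$b, f$b, tolerance = 1e-9)
  expect_lt(theta_diff(r$theta, f$theta), 1e-7)
  expect_equal(r$cx, f$cx, tolerance = 1e-9)
  expect_equal(r$cy, f$cy, tolerance = 1e-9)
})

test_that("rescale_ellipse inverts within 1e-9", {
  set.seed(11)
  for (i in 1:25) {
    e <- ellipse_params(runif(1, -5, 5), runif(1, -5, 5),
                        a = runif(1, 1, 10), b = runif(1, 1, 10),
                        theta = runif(1, 0, 180))
    fx <- runif(1, 0.2, 5); fy <- runif(1, 0.2, 5)
    r <- rescale_ellipse(rescale_ellipse(e, fx, fy), 1 / fx, 1 / fy)
    expect_equal(r$a, e$a, tolerance = 1e-9)
    expect_equal(r$b, e$b, tolerance = 1e-9)
    expect_equal(r$cx, e$cx, tolerance = 1e-9)
    if ((e$a - e$b) / e$a > 1e-6) expect_lt(theta_diff(r$theta, e$theta), 1e-6)
  }
})

test_that("hc_mm converts pixels to mm, isotropic and anisotropic", {
  # circle, 10 px radius at 0.1 mm/px -> 2*pi mm
  expect_equal(hc_mm(ellipse_params(0, 0, 10, 10), pixel_spacing(0.1)),
               2 * pi, tolerance = 1e-12)
  expect_equal(hc_mm(ellipse_params(0, 0, 20, 10), pixel_spacing(0.1)),
               ramanujan_circumference(2, 1), tolerance = 1e-12)
  # anisotropic spacing maps a pixel circle onto a physical 2:1 ellipse
  expect_equal(hc_mm(ellipse_params(0, 0, 10, 10), pixel_spacing(0.2, 0.1)),
               ramanujan_circumference(2, 1), tolerance = 1e-9)
})

test_that("hc_mm is invariant to the a/b + 90 degree reparameterization", {
  sp <- pixel_spacing(0.13, 0.27)
  e1 <- ellipse_params(1, 2, a = 8, b = 3, theta = 25)
  e2 <- ellipse_params(1, 2, a = 3, b = 8, theta = 115) # same ellipse
  expect_equal(hc_mm(e1, sp), hc_mm(e2, sp), tolerance = 1e-12)
})
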