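# Ellipse geometry: perimeter formulas, direct least-squares fitting,
# rescaling under anisotropic maps, and pixel -> mm conversion.
#
# Conventions used throughout the package:
#   * image coordinates: x to the right (columns), y down (rows),
#     0-based, pixel centers at integer coordinates;
#   * theta: orientation of the major axis against the +x axis, in degrees,
#     normalized to [0, 180); for circles theta is reported as 0.

#' Construct ellipse parameters
#'
#' Creates a validated `ellipse_params` object describing a geometric ellipse
#' in pixel coordinates. Axes are normalized so that `a >= b` (swapping the
#' orientation by 90 degrees if needed) and `theta` is reduced to `[0, 180)`.
#' For (numerically) circular ellipses `theta` is set to 0 by convention.
#'
#' @param cx,cy Center, pixel coordinates (continuous; x right, y down,
#'   0-based pixel centers).
#' @param a,b Semi-axes in pixels; any positive pair (reordered internally so
#'   the stored `a` is the semi-major axis).
#' @param theta Orientation of the axis paired with `a`, degrees from the +x
#'   axis.
#' @return An object of class `ellipse_params` with fields `cx`, `cy`, `a`,
#'   `b`, `theta`.
#' @examples
#' ellipse_params(0, 0, a = 2, b = 5, theta = 10) # stored as a=5, theta=100
#' @export
ellipse_params <- function(cx, cy, a, b, theta = 0) {
  for (v in list(cx = cx, cy = cy, a = a, b = b, theta = theta)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_invalid_parameter("ellipse parameters must be finite numeric scalars")
  }
  if (a <= 0 || b <= 0)
    stop_invalid_parameter("semi-axes must be positive")
  if (a < b) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + 90
  }
  theta <- theta %% 180
  if ((a - b) <= 1e-9 * a) theta <- 0   # circle convention
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse> center=(%.4g, %.4g)  a=%.6g  b=%.6g  theta=%.4g deg\n",
    x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' Construct a pixel spacing
#'
#' @param sx,sy Physical size of one pixel along x and y, mm/pixel. `sy`
#'   defaults to `sx` (isotropic pixels).
#' @return An object of class `pixel_spacing` with fields `sx`, `sy`.
#' @export
pixel_spacing <- function(sx, sy = sx) {
  if (!is.numeric(sx) || !is.numeric(sy) || length(sx) != 1L ||
      length(sy) != 1L || !is.finite(sx) || !is.finite(sy) ||
      sx <= 0 || sy <= 0)
    stop_invalid_parameter("pixel spacing must be positive finite scalars")
  structure(list(sx = sx, sy = sy), class = "pixel_spacing")
}

#' Ellipse perimeter by the Ramanujan approximation
#'
#' Computes the closed-form Ramanujan approximation of the perimeter of an
#' ellipse with semi-axes `a` and `b`:
#' \deqn{h = (a-b)^2/(a+b)^2, \quad
#'       P \approx \pi (a+b) \left(1 + \frac{3h}{10 + \sqrt{4 - 3h}}\right).}
#' The relative error against the exact elliptic-integral perimeter is below
#' 1e-6 for axis ratios `b/a >= 0.2`. Symmetric in `a` and `b`; reduces to the
#' circle perimeter when `a == b`.
#'
#' @param a,b Semi-axis lengths, any positive values (same units); vectorized.
#' @return Perimeter in the same units as the axes.
#' @examples
#' ramanujan_circumference(1, 1)  # 2*pi
#' @seealso [exact_perimeter()] for the quadrature reference.
#' @export
ramanujan_circumference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) ||
      any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop_invalid_parameter("semi-axes must be positive finite numbers")
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Exact ellipse perimeter by numerical quadrature
#'
#' Evaluates the arc-length integral
#' \eqn{P = 4 \int_0^{\pi/2} \sqrt{a^2 \sin^2 t + b^2 \cos^2 t}\, dt}
#' with adaptive quadrature to a relative tolerance well below 1e-9. This is
#' the reference value the Ramanujan formula approximates, and is used as the
#' analytic ground truth for synthetic phantoms.
#'
#' @inheritParams ramanujan_circumference
#' @return Perimeter in the same units as the axes (vectorized over `a`, `b`).
#' @export
exact_perimeter <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) ||
      any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop_invalid_parameter("semi-axes must be positive finite numbers")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    A <- max(a[i], b[i]); B <- min(a[i], b[i])
    # scale out A for conditioning; integrand in [B/A, 1]
    r <- B / A
    f <- function(t) sqrt(sin(t)^2 + r^2 * cos(t)^2)
    4 * A * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12,
                             abs.tol = 0, subdivisions = 400L)$value
  }, numeric(1))
}

# ---- conic <-> geometric conversions (internal) -----------------------------

# Conic: A x^2 + B xy + C y^2 + D x + E y + F = 0, coefficients as length-6
# vector. Returns ellipse_params or signals fit failure if not an ellipse.
conic_to_ellipse <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0)
    stop_fit_failure("fitted conic is not an ellipse", cause = "not_an_ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(M, symmetric = TRUE)    # values decreasing
  ax2 <- -F0 / eg$values              # squared semi-axes
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop_fit_failure("fitted conic is degenerate", cause = "not_an_ellipse")
  # smaller eigenvalue -> larger axis (major)
  vmaj <- eg$vectors[, 2]
  theta <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  ellipse_params(cx, cy, a = sqrt(ax2[2]), b = sqrt(ax2[1]), theta = theta)
}

# Positive-definite quadratic form Q of an ellipse: (p-c)' Q (p-c) = 1.
ellipse_to_form <- function(e) {
  th <- e$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R %*% diag(c(1 / e$a^2, 1 / e$b^2)) %*% t(R)
}

form_to_ellipse <- function(Q, cx, cy) {
  eg <- eigen(Q, symmetric = TRUE)    # values decreasing: 1/b^2 >= 1/a^2
  vmaj <- eg$vectors[, 2]             # eigenvector of the smaller eigenvalue
  theta <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  ellipse_params(cx, cy, a = 1 / sqrt(eg$values[2]), b = 1 / sqrt(eg$values[1]),
                 theta = theta)
}

#' Fit an ellipse to 2-D points by direct least squares
#'
#' Fits the conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0} to the points by
#' the numerically stabilized direct least-squares method of Halir and Flusser
#' (Fitzgibbon's ellipse-specific constraint \eqn{4AC - B^2 = 1}), then
#' converts the conic to geometric parameters. The fit is deterministic:
#' identical input always yields identical output. Points are centered and
#' isotropically scaled internally for conditioning.
#'
#' @param points A numeric matrix (or data frame) with two columns, `x` and
#'   `y`, in pixel coordinates; at least 5 non-collinear points.
#' @return An [ellipse_params()] object.
#' @section Errors: signals a condition of class `fetalhc_fit_failure` with a
#'   `cause` field: `"too_few_points"` (< 5 points), `"degenerate_points"`
#'   (collinear or coincident input), or `"not_an_ellipse"` (best conic is a
#'   different conic section).
#' @examples
#' t <- seq(0, 2 * pi, length.out = 100)
#' pts <- cbind(5 + 4 * cos(t), -3 + 2 * sin(t))
#' fit_ellipse(pts)
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop_invalid_input("points must be an n x 2 numeric matrix")
  points <- points[stats::complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 5L)
    stop_fit_failure(sprintf("need >= 5 points to fit an ellipse, got %d", n),
                     cause = "too_few_points")
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  xc <- points[, 1] - mx; yc <- points[, 2] - my
  s <- mean(sqrt(xc^2 + yc^2))
  if (!is.finite(s) || s <= 0)
    stop_fit_failure("points are coincident", cause = "degenerate_points")
  # collinearity check on centered coordinates
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * sv[1])
    stop_fit_failure("points are collinear", cause = "degenerate_points")
  x <- xc / s; y <- yc / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop_fit_failure(
                   "degenerate point configuration",
                   cause = "degenerate_points"))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  vec <- Re(eg$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0 & abs(Im(eg$values)) < 1e-8 * (abs(Re(eg$values)) + 1))
  if (length(ok) == 0L)
    stop_fit_failure("no ellipse satisfies the fit constraint",
                     cause = "not_an_ellipse")
  a1 <- vec[, ok[1]]
  cf_s <- c(a1, as.vector(T2 %*% a1))   # conic in scaled coordinates
  e_s <- conic_to_ellipse(cf_s)
  # undo isotropic scaling/translation: axes and center scale by s, theta kept
  ellipse_params(e_s$cx * s + mx, e_s$cy * s + my,
                 a = e_s$a * s, b = e_s$b * s, theta = e_s$theta)
}

#' Rescale an ellipse under an anisotropic axis scaling
#'
#' Maps the ellipse through the exact diagonal linear map
#' \eqn{(x, y) \mapsto (f_x x, f_y y)} and re-extracts geometric parameters.
#' The result is the exact image of the input ellipse (an anisotropically
#' scaled ellipse is again an ellipse, generally with a different
#' orientation). Used to map an ellipse fitted on a resized analysis grid
#' back to the original pixel grid.
#'
#' @param e An [ellipse_params()] object.
#' @param fx,fy Positive scale factors along x and y.
#' @return An [ellipse_params()] object on the rescaled grid.
#' @export
rescale_ellipse <- function(e, fx, fy) {
  stopifnot(inherits(e, "ellipse_params"))
  if (!is.numeric(fx) || !is.numeric(fy) || length(fx) != 1L ||
      length(fy) != 1L || !is.finite(fx) || !is.finite(fy) ||
      fx <= 0 || fy <= 0)
    stop_invalid_parameter("scale factors must be positive finite scalars")
  Q <- ellipse_to_form(e)
  Sinv <- diag(c(1 / fx, 1 / fy))
  Q2 <- Sinv %*% Q %*% Sinv
  Q2 <- (Q2 + t(Q2)) / 2
  form_to_ellipse(Q2, e$cx * fx, e$cy * fy)
}

#' Head circumference of an ellipse in millimetres
#'
#' Converts a pixel-domain ellipse to physical units using the pixel spacing
#' and returns the Ramanujan perimeter in mm. With isotropic spacing the axes
#' are simply multiplied by the spacing; with anisotropic spacing the ellipse
#' is first mapped through the exact diagonal scaling [rescale_ellipse()], so
#' the physical ellipse (not an approximation by a mean scale) is measured.
#'
#' @param e An [ellipse_params()] object in pixel coordinates.
#' @param spacing A [pixel_spacing()] object (mm/pixel).
#' @return Head circumference in mm.
#' @export
hc_mm <- function(e, spacing) {
  stopifnot(inherits(e, "ellipse_params"))
  if (!inherits(spacing, "pixel_spacing"))
    spacing <- do.call(pixel_spacing, as.list(spacing))
  if (spacing$sx == spacing$sy)
    return(ramanujan_circumference(e$a * spacing$sx, e$b * spacing$sx))
  ep <- rescale_ellipse(e, spacing$sx, spacing$sy)
  ramanujan_circumference(ep$a, ep$b)
}

#' Sample points on an ellipse boundary
#'
#' Utility used by tests and the phantom generator: returns `n` points evenly
#' spaced in the parametric angle on the boundary of an ellipse.
#'
#' @param e An [ellipse_params()] object.
#' @param n Number of points.
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @export
ellipse_points <- function(e, n = 360L) {
  stopifnot(inherits(e, "ellipse_params"), n >= 1L)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  th <- e$theta * pi / 180
  u <- e$a * cos(t); v <- e$b * sin(t)
  cbind(x = e$cx + u * cos(th) - v * sin(th),
        y = e$cy + u * sin(th) + v * cos(th))
}
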