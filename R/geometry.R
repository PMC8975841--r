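#' Segment a sessile droplet and return its outer contour
#'
#' Thresholds the image (Otsu by default), labels connected components,
#' keeps the largest, and returns its outer contour as ordered (x, y) pixel
#' coordinates, optionally smoothed along the contour with a circular
#' Gaussian (sub-pixel). If more than one component clears the minimum area
#' the largest is kept and a warning is issued.
#'
#' @param image grayscale matrix (rows x cols); the droplet is brighter than
#'   the background unless `invert = TRUE`.
#' @param threshold_method `"otsu"` or `"fixed"` (midpoint of the intensity
#'   range).
#' @param invert segment a dark droplet on a bright background.
#' @param min_area smallest accepted component (px).
#' @param smooth_sigma Gaussian smoothing along the contour (in contour
#'   points); 0 disables.
#' @return Matrix with columns `x` (col) and `y` (row), ordered along the
#'   contour, sub-pixel positions.
#' @export
segment_droplet <- function(image, threshold_method = c("otsu", "fixed"),
                            invert = FALSE, min_area = 25, smooth_sigma = 2) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(image))
  img <- image
  if (invert) img <- max(img) - img
  rng <- range(img)
  if (diff(rng) <= .Machine$double.eps) {
    stop_mucogel("no droplet found: image has no contrast")
  }
  scaled <- (img - rng[1L]) / diff(rng)
  thr <- if (threshold_method == "otsu") {
    # EBImage works in x (col), y (row); transpose so dims are (x, y)
    EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
  } else 0.5
  mask <- scaled > thr
  labels <- EBImage::bwlabel(EBImage::Image(t(mask)))
  areas <- table(labels[labels > 0])
  areas <- areas[areas >= min_area]
  if (length(areas) == 0L) {
    stop_mucogel("no droplet found: no component above %d px", min_area)
  }
  if (length(areas) > 1L) {
    warning(sprintf("%d components found; keeping the largest", length(areas)),
            call. = FALSE)
  }
  keep <- as.integer(names(areas)[which.max(areas)])
  contour <- EBImage::ocontour(labels == keep)[[1L]]  # (x, y) with x = col
  contour <- contour + 1L  # EBImage contours are 0-based
  if (smooth_sigma > 0 && nrow(contour) > 8L) {
    k <- gaussian_kernel_1d(smooth_sigma)
    contour <- cbind(convolve_circular(contour[, 1L], k),
                     convolve_circular(contour[, 2L], k))
  }
  colnames(contour) <- c("x", "y")
  contour
}

# circular (periodic) convolution for closed contours
convolve_circular <- function(x, k) {
  half <- (length(k) - 1L) / 2L
  if (half == 0) return(x * k)
  n <- length(x)
  padded <- c(x[(n - half + 1L):n], x, x[1:half])
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Detect the substrate baseline of a sessile-droplet contour
#'
#' Auto mode finds the horizontal line through the contour's lowest extended
#' flat run: the set of contour points within one pixel of the maximum row
#' must span a horizontal extent of at least `min_run` px (the flat contact
#' line where the droplet meets the substrate). Tilted substrates are not
#' supported in auto mode; supply `fixed_row` instead.
#'
#' @param contour contour matrix from [segment_droplet()].
#' @param mode `"auto"` or `"fixed_row"`.
#' @param fixed_row substrate row when `mode = "fixed_row"`.
#' @param min_run minimum horizontal extent (px) of the flat run in auto
#'   mode.
#' @return List with `row` (baseline row, px) and `mode`.
#' @export
detect_baseline <- function(contour, mode = c("auto", "fixed_row"),
                            fixed_row = NULL, min_run = 10) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  if (mode == "fixed_row") {
    check_scalar(fixed_row, "fixed_row", lower = 1)
    if (all(contour[, 2L] < fixed_row - 1)) {
      stop_mucogel("contour lies entirely above the supplied fixed_row (%g)",
                   fixed_row)
    }
    return(list(row = fixed_row, mode = mode))
  }
  y <- contour[, 2L]
  y_max <- max(y)
  bottom <- contour[y > y_max - 1.5, , drop = FALSE]
  run <- diff(range(bottom[, 1L]))
  if (nrow(bottom) < 3L || run < min_run) {
    stop_mucogel(paste0(
      "no flat run found at the contour bottom (extent %.1f px < %d px); ",
      "a tilted substrate is not supported in auto mode - use mode = 'fixed_row'"),
      run, min_run)
  }
  list(row = median(bottom[, 2L]), mode = mode)
}

#' Measure left and right contact angles of a sessile droplet
#'
#' Computes the interior angle between the substrate and the droplet surface
#' at each contact line, through the droplet phase (the sessile-drop
#' convention). `circle_fit` fits a circle to the contour points above the
#' baseline (small two-phase droplets are near-spherical caps) and takes the
#' tangent at the circle-baseline intersections. `polynomial_tangent` fits a
#' local quadratic to the contour near each contact point and uses its slope;
#' it is kept for irregular droplets, and is the automatic fallback when the
#' circle fit is degenerate.
#'
#' @param contour contour from [segment_droplet()].
#' @param baseline baseline from [detect_baseline()] (or a list with `row`).
#' @param method `"circle_fit"` (default) or `"polynomial_tangent"`.
#' @param window_px window around each contact point for the polynomial
#'   method (px).
#' @return An object of class `contact_angle`: list with `theta_left`,
#'   `theta_right`, `theta_mean` (degrees), `baseline_row`,
#'   `contact_points` (2 x 2 matrix), and `method`.
#' @export
measure_contact_angles <- function(contour, baseline,
                                   method = c("circle_fit", "polynomial_tangent"),
                                   window_px = 15) {
  method <- match.arg(method)
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  row0 <- baseline$row %||% baseline
  above <- contour[contour[, 2L] < row0 - 0.5, , drop = FALSE]
  if (nrow(above) < 5L) stop_mucogel("contour has fewer than 5 points above the baseline")

  if (method == "circle_fit") {
    fit <- fit_circle_kasa(above)
    dy <- row0 - fit$cy   # center height above the baseline (+ if above)
    if (!is.finite(fit$r) || fit$r <= 0 || abs(dy) >= fit$r) {
      warning("degenerate circle fit; falling back to polynomial_tangent",
              call. = FALSE)
      return(measure_contact_angles(contour, baseline,
                                    method = "polynomial_tangent",
                                    window_px = window_px))
    }
    half_chord <- sqrt(fit$r^2 - dy^2)
    xl <- fit$cx - half_chord
    xr <- fit$cx + half_chord
    # interior angle through the droplet: a spherical cap has its center at
    # height -R*cos(theta) relative to the baseline, so theta = acos(-dy/R);
    # dy = 0 gives a hemisphere (90 deg), center above baseline an obtuse cap
    theta <- acos(-dy / fit$r) * 180 / pi
    theta_left <- theta_right <- theta
    contact <- rbind(c(xl, row0), c(xr, row0))
  } else {
    cross <- baseline_crossings(contour, row0)
    if (nrow(cross) < 2L) stop_mucogel("contour intersects the baseline at fewer than 2 points")
    xl <- min(cross[, 1L]); xr <- max(cross[, 1L])
    theta_left <- tangent_angle_poly(above, xl, row0, side = "left", window_px)
    theta_right <- tangent_angle_poly(above, xr, row0, side = "right", window_px)
    contact <- rbind(c(xl, row0), c(xr, row0))
  }
  structure(
    list(theta_left = theta_left, theta_right = theta_right,
         theta_mean = (theta_left + theta_right) / 2,
         baseline_row = row0, contact_points = contact, method = method),
    class = "contact_angle"
  )
}

#' @export
print.contact_angle <- function(x, ...) {
  cat(sprintf("<contact_angle> left %.1f deg, right %.1f deg, mean %.1f deg (%s)\n",
              x$theta_left, x$theta_right, x$theta_mean, x$method))
  invisible(x)
}

# algebraic (Kasa) circle fit: linear least squares on x^2 + y^2
fit_circle_kasa <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) rep(NA_real_, 3))
  cx <- sol[1L]; cy <- sol[2L]
  r2 <- sol[3L] + cx^2 + cy^2
  list(cx = cx, cy = cy, r = if (is.finite(r2) && r2 > 0) sqrt(r2) else NA_real_)
}

# where consecutive contour points straddle the baseline row
baseline_crossings <- function(contour, row0) {
  y <- contour[, 2L]
  n <- nrow(contour)
  nxt <- c(2:n, 1L)
  hit <- which((y - row0) * (y[nxt] - row0) <= 0 & y != y[nxt])
  if (length(hit) == 0L) {
    # contour may sit exactly on the row; take extreme x of near-baseline points
    near <- contour[abs(y - row0) <= 1, , drop = FALSE]
    if (nrow(near) == 0L) return(matrix(numeric(0), ncol = 2))
    return(rbind(c(min(near[, 1L]), row0), c(max(near[, 1L]), row0)))
  }
  t <- (row0 - y[hit]) / (y[nxt][hit] - y[hit])
  xs <- contour[hit, 1L] + t * (contour[nxt, 1L][hit] - contour[hit, 1L])
  cbind(xs, rep(row0, length(xs)))
}

tangent_angle_poly <- function(above, x_contact, row0, side, window_px) {
  sel <- abs(above[, 1L] - x_contact) <= window_px &
    (row0 - above[, 2L]) <= 2 * window_px
  pts <- above[sel, , drop = FALSE]
  if (nrow(pts) < 3L) stop_mucogel("too few contour points near the %s contact point", side)
  # fit height above baseline as a quadratic in x
  h <- row0 - pts[, 2L]
  x <- pts[, 1L] - x_contact
  fit <- stats::lm.fit(cbind(1, x, x^2), h)
  slope <- unname(fit$coefficients[2L])
  # slope of droplet height at the contact point; interior angle through the
  # droplet: left side rises to the right (+slope), right side to the left
  ang <- atan(if (side == "left") slope else -slope) * 180 / pi
  if (ang < 0) ang <- ang + 180
  ang
}

#' Circularity of a top-view droplet mask
#'
#' Computes `4 * pi * area / perimeter^2`, 1 for a perfect disc. The
#' perimeter is the arc length of the Gaussian-smoothed outer contour
#' (raw pixel-edge perimeters overestimate by up to ~11%, which would bias
#' circularity low), and the area is the polygon area of the same contour.
#'
#' @param mask binary matrix (or numeric, thresholded at 0.5) with a single
#'   connected component.
#' @param smooth_sigma contour smoothing (contour points).
#' @return An object of class `circularity_result`: list with `circularity`,
#'   `area` (px^2), `perimeter` (px).
#' @export
circularity <- function(mask, smooth_sigma = 2) {
  stopifnot(is.matrix(mask))
  m <- mask > 0.5
  if (!any(m)) stop_mucogel("empty mask")
  labels <- EBImage::bwlabel(EBImage::Image(t(m)))
  areas <- table(labels[labels > 0])
  keep <- as.integer(names(areas)[which.max(areas)])
  contour <- EBImage::ocontour(labels == keep)[[1L]] + 1L
  if (smooth_sigma > 0 && nrow(contour) > 8L) {
    k <- gaussian_kernel_1d(smooth_sigma)
    contour <- cbind(convolve_circular(contour[, 1L], k),
                     convolve_circular(contour[, 2L], k))
  }
  per <- polygon_perimeter(contour)
  area <- polygon_area(contour)
  structure(list(circularity = 4 * pi * area / per^2, area = area,
                 perimeter = per),
            class = "circularity_result")
}

polygon_perimeter <- function(pts) {
  nxt <- c(2:nrow(pts), 1L)
  sum(sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2)))
}

polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  nxt <- c(2:length(x), 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}
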