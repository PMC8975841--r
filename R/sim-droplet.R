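#' Render a synthetic sessile droplet image with known contact angle
#'
#' Draws the side-view cross-section of a spherical-cap droplet (a circular
#' segment) of the requested contact angle resting on a horizontal baseline:
#' bright droplet on dark background, optionally with additive Gaussian
#' noise. The generating geometry uses the spherical-cap identities
#' `h = a * tan(theta / 2)` (cap height from base radius) and circle radius
#' `R = a / sin(theta)`, valid for any `0 < theta < 180` degrees.
#'
#' @param theta_deg ground-truth contact angle (degrees), in (0, 180).
#' @param base_radius_px droplet base (contact line) half-width (px).
#' @param baseline_row image row of the substrate surface (px, from top).
#' @param image_shape `c(rows, cols)` of the output image.
#' @param noise_sigma additive Gaussian noise standard deviation, in units of
#'   the droplet intensity (droplet = 1, background = 0).
#' @param seed integer seed for the noise.
#' @return List with `image` (matrix, rows x cols), `theta_deg` (ground
#'   truth), `baseline_row`, `base_radius_px` and the generating circle
#'   (`center_x`, `center_y`, `radius`, px; y measured down from the top).
#' @export
simulate_droplet_image <- function(theta_deg, base_radius_px = 100,
                                   baseline_row = NULL,
                                   image_shape = c(400, 400),
                                   noise_sigma = 0, seed = 1L) {
  check_scalar(theta_deg, "theta_deg", lower = 0, strict_lower = TRUE)
  if (theta_deg >= 180) stop_mucogel("'theta_deg' must be < 180")
  check_scalar(base_radius_px, "base_radius_px", lower = 1)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  stopifnot(length(image_shape) == 2L)
  nr <- image_shape[1L]; nc <- image_shape[2L]
  if (is.null(baseline_row)) baseline_row <- round(nr * 0.75)
  check_scalar(baseline_row, "baseline_row", lower = 1, upper = nr)

  theta <- theta_deg * pi / 180
  a <- base_radius_px
  h <- a * tan(theta / 2)            # cap height above the baseline
  R <- a / sin(theta)                # circle radius
  cx <- nc / 2
  # image rows grow downward; circle center is h - R above the baseline
  cy <- baseline_row - (h - R)
  half_width <- if (theta_deg > 90) R else a
  if (h >= baseline_row - 1 || cx - half_width < 1 || cx + half_width > nc) {
    stop_mucogel("droplet cap (height %.0f px, half-width %.0f px) does not fit the frame",
                 h, half_width)
  }

  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- ((col_idx - cx)^2 + (row_idx - cy)^2 <= R^2) &
    (row_idx <= baseline_row)
  img <- matrix(0, nr, nc)
  img[inside] <- 1
  if (noise_sigma > 0) {
    with_seed(seed, img <- img + matrix(rnorm(nr * nc, sd = noise_sigma), nr, nc))
  }
  list(image = img, theta_deg = theta_deg, baseline_row = baseline_row,
       base_radius_px = base_radius_px,
       center_x = cx, center_y = cy, radius = R)
}
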