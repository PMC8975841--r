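#' Detect the reservoir-hydrogel interface in a diffusion-assay frame
#'
#' The interface is located as the position of maximum magnitude of the
#' smoothed axial intensity gradient in the first frame: the reservoir is
#' bright, the gel initially dark, so the step between them dominates the
#' gradient. The profile is averaged across the channel width and smoothed
#' with a Gaussian kernel (sigma = 2 px) before differencing, which is robust
#' to shot noise without shifting a step edge. A manual override always wins.
#'
#' @param first_frame matrix (rows x cols) of the first frame; the channel
#'   axis runs along columns, reservoir on the left.
#' @param smooth_sigma Gaussian smoothing sigma (px) applied before the
#'   gradient.
#' @param override optional known interface column; returned unchanged.
#' @param min_contrast minimum ratio of the peak |gradient| to the median
#'   |gradient| (the noise floor); below it no interface is declared.
#' @return Interface column index (px): the first gel pixel is
#'   `interface_px`, i.e. the edge sits between `interface_px - 1` and
#'   `interface_px`.
#' @export
detect_interface <- function(first_frame, smooth_sigma = 2, override = NULL,
                             min_contrast = 8) {
  if (!is.null(override)) {
    check_scalar(override, "override", lower = 1, integer = TRUE)
    return(as.integer(override))
  }
  stopifnot(is.matrix(first_frame))
  profile <- colMeans(first_frame)
  rng <- diff(range(profile))
  if (rng <= .Machine$double.eps * max(abs(profile), 1)) {
    stop_mucogel("no interface found: frame is uniform along the channel axis")
  }
  k <- gaussian_kernel_1d(smooth_sigma)
  smoothed <- convolve_reflect(profile, k)
  grad <- diff(smoothed)
  peak <- which.max(abs(grad))
  floor_grad <- median(abs(grad)) + .Machine$double.eps
  if (abs(grad[peak]) < min_contrast * floor_grad) {
    stop_mucogel("no interface found: axial gradient below the noise floor")
  }
  # diff element i spans columns i -> i+1; first gel pixel is i+1
  as.integer(peak + 1L)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- ceiling(3 * sigma)
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution with edge reflection (same length out).
convolve_reflect <- function(x, k) {
  half <- (length(k) - 1L) / 2L
  if (half == 0) return(x * k)
  padded <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1L):(half + length(x))])
}

#' Extract axial intensity profiles from a diffusion image stack
#'
#' For every frame, averages intensity across a band of rows (default the
#' central 60% of the channel width, avoiding wall artifacts) and returns the
#' axial profile from the interface out to `interface + profile_length`.
#' Positions are assigned at pixel centers: the i-th profile sample (1-based)
#' sits at `(i - 0.5) * pixel_size` cm from the interface.
#'
#' @param stack an `image_stack` (see [render_image_stack()],
#'   [read_image_stack()]).
#' @param interface_px interface column (first gel pixel); defaults to the
#'   stack's stored value, else [detect_interface()] on the first frame.
#' @param profile_length length of the analyzed window (cm); default 0.2 cm
#'   (2 mm).
#' @param pixel_size cm/px; defaults to the stack's value.
#' @param width_band integer vector of rows to average over; default central
#'   60%.
#' @return List with `raw` (space x time intensity matrix), `x_grid` (cm),
#'   `t_grid` (s), `interface_px`.
#' @export
extract_profiles <- function(stack, interface_px = NULL, profile_length = 0.2,
                             pixel_size = NULL, width_band = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  pixel_size <- pixel_size %||% stack$pixel_size
  check_scalar(profile_length, "profile_length", lower = 0, strict_lower = TRUE)
  if (is.null(interface_px)) {
    interface_px <- if (!is.na(stack$interface_px)) stack$interface_px
    else detect_interface(stack$frames[, , 1L])
  }
  d <- dim(stack$frames)
  n_px <- round(profile_length / pixel_size)
  max_len <- (d[2L] - interface_px + 1L) * pixel_size
  if (interface_px + n_px - 1L > d[2L]) {
    stop_mucogel("profile window (%g cm) exceeds the frame; maximum feasible length is %g cm",
                 profile_length, max_len)
  }
  if (is.null(width_band)) {
    margin <- floor(d[1L] * 0.2)
    width_band <- (margin + 1L):(d[1L] - margin)
  }
  cols <- interface_px:(interface_px + n_px - 1L)
  raw <- sapply(seq_len(d[3L]), function(j) {
    colMeans(stack$frames[width_band, cols, j, drop = FALSE])
  })
  raw <- matrix(raw, nrow = n_px)
  x_grid <- (seq_len(n_px) - 0.5) * pixel_size
  list(raw = raw, x_grid = x_grid, t_grid = stack$t_grid,
       interface_px = as.integer(interface_px))
}

#' Normalize raw profiles to a reference intensity
#'
#' Divides each frame's profile by that frame's reference intensity -- the
#' fluorescence of a channel containing only tracer solution -- so the
#' normalized fluorescence `F` is 1 at full tracer concentration. The
#' reference is a per-frame scalar vector, a single scalar, or a reference
#' image stack (reduced to its per-frame mean). Frames with a missing
#' (`NA`) reference fall back to the first finite reference value, with a
#' flag recorded.
#'
#' @param profiles output of [extract_profiles()].
#' @param reference per-frame reference intensities (length `n_frames` or 1),
#'   or an `image_stack` whose per-frame mean is used.
#' @return An object of class `profile_matrix`: list with `f` (normalized
#'   space x time matrix), `x_grid` (cm), `t_grid` (s), `interface_px`,
#'   `reference_intensity`, and `fallback_frames` (indices that used the
#'   fallback reference).
#' @export
normalize_profiles <- function(profiles, reference) {
  raw <- profiles$raw
  n_frames <- ncol(raw)
  if (inherits(reference, "image_stack")) {
    reference <- apply(reference$frames, 3, mean)
  }
  if (length(reference) == 1L) reference <- rep(reference, n_frames)
  if (length(reference) != n_frames) {
    stop_mucogel("reference has %d values for %d frames",
                 length(reference), n_frames)
  }
  fallback <- which(is.na(reference))
  if (length(fallback) > 0L) {
    first_ok <- reference[which(is.finite(reference))[1L]]
    if (is.na(first_ok)) stop_mucogel("no finite reference value available")
    reference[fallback] <- first_ok
  }
  if (any(reference <= 0)) {
    stop_mucogel("reference intensities must be strictly positive (frame %d is not)",
                 which(reference <= 0)[1L])
  }
  f <- sweep(raw, 2L, reference, "/")
  new_profile_matrix(f, profiles$x_grid, profiles$t_grid,
                     interface_px = profiles$interface_px,
                     reference_intensity = reference,
                     fallback_frames = fallback)
}

new_profile_matrix <- function(f, x_grid, t_grid, interface_px = NA_integer_,
                               reference_intensity = rep(1, ncol(f)),
                               fallback_frames = integer()) {
  stopifnot(is.matrix(f), length(x_grid) == nrow(f), length(t_grid) == ncol(f))
  if (any(!is.finite(f))) stop_mucogel("profile matrix contains non-finite values")
  if (is.unsorted(x_grid, strictly = TRUE) || any(x_grid < 0)) {
    stop_mucogel("x_grid must be strictly increasing and non-negative")
  }
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop_mucogel("t_grid must be strictly increasing")
  }
  structure(
    list(f = f, x_grid = x_grid, t_grid = t_grid,
         interface_px = interface_px,
         reference_intensity = reference_intensity,
         fallback_frames = fallback_frames),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d positions x %d frames, x in [%g, %g] cm, t in [%g, %g] s\n",
              nrow(x$f), ncol(x$f), min(x$x_grid), max(x$x_grid),
              min(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Number of analysis frames in an acquisition window
#'
#' With frame `j` acquired at `j * frame_interval`, a window of `duration`
#' seconds contains `floor(duration / frame_interval)` frames -- e.g. 2 h at
#' 4-minute intervals gives 30 frames.
#'
#' @param duration_s window duration (s).
#' @param frame_interval_s acquisition interval (s).
#' @return Integer frame count.
#' @export
frames_in_window <- function(duration_s, frame_interval_s) {
  check_scalar(duration_s, "duration_s", lower = 0)
  check_scalar(frame_interval_s, "frame_interval_s", lower = 0, strict_lower = TRUE)
  as.integer(floor(duration_s / frame_interval_s + 1e-9))
}

#' Select the analyzed frame window
#'
#' Truncates a profile matrix to the frames used for fitting -- by default
#' the first 30 frames, the 2 h window of a 4-minute-interval acquisition.
#' Skipped initial frames are dropped but elapsed times are kept on the
#' acquisition clock (t is never re-zeroed, so the diffusion model's time
#' origin stays at tracer loading).
#'
#' @param matrix a `profile_matrix`.
#' @param n_frames number of frames to keep after skipping.
#' @param skip_initial number of leading frames to drop.
#' @return A truncated `profile_matrix`.
#' @export
select_frames <- function(matrix, n_frames = 30, skip_initial = 0) {
  stopifnot(inherits(matrix, "profile_matrix"))
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(skip_initial, "skip_initial", lower = 0, integer = TRUE)
  avail <- ncol(matrix$f)
  idx <- (skip_initial + 1L):(skip_initial + n_frames)
  if (max(idx) > avail) {
    stop_mucogel("requested frames %d-%d but only %d available",
                 min(idx), max(idx), avail)
  }
  new_profile_matrix(matrix$f[, idx, drop = FALSE], matrix$x_grid,
                     matrix$t_grid[idx],
                     interface_px = matrix$interface_px,
                     reference_intensity = matrix$reference_intensity[idx],
                     fallback_frames = intersect(matrix$fallback_frames, idx))
}
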