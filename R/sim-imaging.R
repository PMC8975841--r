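#' Noise model for rendered fluorescence images
#'
#' Parametric model of epifluorescence acquisition noise applied when a
#' simulated concentration field is rendered to pixels: Poisson shot noise at
#' a stated photon gain, additive Gaussian read noise, and first-order
#' photobleaching of the whole frame. Defaults are representative of a
#' benchtop epifluorescence setup: 2% Gaussian noise, 100 photons per
#' concentration unit, no bleaching.
#'
#' @param gaussian_sigma standard deviation of additive Gaussian noise
#'   (fluorescence units). 0 disables.
#' @param poisson_gain photons per fluorescence unit; shot noise is drawn as
#'   Poisson(gain * signal) / gain. 0 disables shot noise.
#' @param bleach_rate first-order bleaching rate (1/s); frame at time t is
#'   scaled by `exp(-bleach_rate * t)`.
#' @param seed integer seed making the rendered stack reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0.02, poisson_gain = 100,
                        bleach_rate = 0, seed = 1L) {
  check_scalar(gaussian_sigma, "gaussian_sigma", lower = 0)
  check_scalar(poisson_gain, "poisson_gain", lower = 0)
  check_scalar(bleach_rate, "bleach_rate", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(gaussian_sigma = gaussian_sigma, poisson_gain = poisson_gain,
                 bleach_rate = bleach_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Render a concentration field as a time-lapse image stack
#'
#' Resamples the axial concentration profile to pixel centers (pixel `i`,
#' 0-based, is centered at `(i + 0.5) * pixel_size` from the interface),
#' replicates it across the channel width, optionally prepends a band of
#' reservoir-intensity pixels left of the interface, applies bleaching, then
#' Poisson and Gaussian noise. Frames correspond to the field's stored times
#' excluding `t = 0` (imaging starts one frame interval after tracer loading,
#' matching the analysis convention that the first analyzed frame has
#' `t = frame_interval`).
#'
#' @param field a `concentration_field` from [simulate_diffusion_pde()].
#' @param noise a [noise_model()].
#' @param pixel_size pixel size along the channel axis (cm/px). Default 10 um.
#' @param channel_width_px number of rows across the channel.
#' @param reservoir_px number of columns of reservoir liquid rendered left of
#'   the interface (at the reservoir concentration for that frame); 0 renders
#'   gel only, with the interface at column 1.
#' @return An object of class `image_stack`: list with `frames` (3-D array,
#'   rows x cols x frames, fluorescence units), `pixel_size`, `interface_px`
#'   (column index of the first gel pixel), `t_grid` (s), and the ground
#'   truth (`d_true`, seed) carried from the field.
#' @export
render_image_stack <- function(field, noise = noise_model(),
                               pixel_size = 10e-4, channel_width_px = 50,
                               reservoir_px = 0) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(noise, "noise_model"))
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_scalar(channel_width_px, "channel_width_px", lower = 1, integer = TRUE)
  check_scalar(reservoir_px, "reservoir_px", lower = 0, integer = TRUE)
  L <- max(field$x_grid)
  if (pixel_size > L) stop_mucogel("pixel_size (%g cm) exceeds the domain (%g cm)",
                                   pixel_size, L)
  n_px <- floor(L / pixel_size)
  x_centers <- (seq_len(n_px) - 0.5) * pixel_size
  t_frames <- field$t_grid[-1L]
  n_frames <- length(t_frames)
  n_cols <- reservoir_px + n_px

  frames <- array(0, dim = c(channel_width_px, n_cols, n_frames))
  with_seed(noise$seed, {
    for (j in seq_len(n_frames)) {
      prof <- approx(field$x_grid, field$values[, j + 1L], xout = x_centers,
                     rule = 2)$y
      row_vals <- c(rep(field$reservoir[j + 1L], reservoir_px), prof)
      frame <- matrix(row_vals, nrow = channel_width_px, ncol = n_cols,
                      byrow = TRUE)
      frame <- frame * exp(-noise$bleach_rate * t_frames[j])
      if (noise$poisson_gain > 0) {
        frame[] <- rpois(length(frame), lambda = frame * noise$poisson_gain) /
          noise$poisson_gain
      }
      if (noise$gaussian_sigma > 0) {
        frame <- frame + rnorm(length(frame), sd = noise$gaussian_sigma)
      }
      frames[, , j] <- frame
    }
  })
  structure(
    list(frames = frames, pixel_size = pixel_size,
         interface_px = reservoir_px + 1L, t_grid = t_frames,
         d_true = field$config$d_true %||% NA_real_,
         seed = noise$seed),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frames, %g cm/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Write an image stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Quantizes fluorescence values to 16-bit unsigned counts at a stated scale
#' and writes one TIFF page per frame, plus a `.json` sidecar recording the
#' ground truth, grid, scale and seed so stacks round-trip losslessly up to
#' quantization.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param counts_per_unit intensity counts per fluorescence unit. The default
#'   maps 1.2 fluorescence units to near full scale.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, counts_per_unit = 5e4) {
  stopifnot(inherits(stack, "image_stack"))
  check_scalar(counts_per_unit, "counts_per_unit", lower = 0, strict_lower = TRUE)
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(j) {
    counts <- round(pmax(pmin(stack$frames[, , j] * counts_per_unit, 65535), 0))
    counts / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    d_true = stack$d_true, pixel_size = stack$pixel_size,
    interface_px = stack$interface_px, t_grid = stack$t_grid,
    counts_per_unit = counts_per_unit, seed = stack$seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF (or directory of single-frame images) as a stack
#'
#' Inverse of [write_image_stack()]. If a sidecar JSON is present its scale
#' converts counts back to fluorescence units; otherwise raw 16-bit counts
#' are returned. A directory input is read as one frame per file, sorted
#' lexicographically.
#'
#' @param path TIFF file or directory of TIFF files.
#' @param pixel_size,frame_interval used when no sidecar exists.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, pixel_size = 10e-4, frame_interval = 240) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop_mucogel("no TIFF files in directory '%s'", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    sidecar_path <- file.path(path, "stack.json")
  } else {
    if (!file.exists(path)) stop_mucogel("input '%s' not found", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar_path <- paste0(path, ".json")
  }
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL
  scale <- sidecar$counts_per_unit %||% 1
  frames <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (j in seq_along(pages)) frames[, , j] <- pages[[j]] / scale
  t_grid <- sidecar$t_grid %||% (seq_along(pages) * frame_interval)
  structure(
    list(frames = frames,
         pixel_size = sidecar$pixel_size %||% pixel_size,
         interface_px = sidecar$interface_px %||% NA_integer_,
         t_grid = t_grid,
         d_true = sidecar$d_true %||% NA_real_,
         seed = sidecar$seed %||% NA_integer_),
    class = "image_stack"
  )
}
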