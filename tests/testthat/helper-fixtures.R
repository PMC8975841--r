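# Shared fixtures: analytic profile matrices and default grids.

default_x_grid <- function(n_px = 200, pixel_size = 1e-3) {
  (seq_len(n_px) - 0.5) * pixel_size
}

default_t_grid <- function(n_frames = 30, frame_interval = 240) {
  seq_len(n_frames) * frame_interval
}

# Noiseless (or Gaussian-noised) profile matrix straight from the erfc model.
analytic_profile_matrix <- function(d, amplitude = 1, offset = 0,
                                    x = default_x_grid(),
                                    t = default_t_grid(),
                                    noise_sd = 0, seed = NULL) {
  f <- sapply(t, function(tt) {
    amplitude * analytic_erfc_solution(x, tt, d) + offset
  })
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + matrix(rnorm(length(f), sd = noise_sd), nrow(f))
  }
  mucogel:::new_profile_matrix(f, x, t)
}

# Rasterized shapes for circularity tests.
raster_disc <- function(radius, pad = 20) {
  n <- 2 * (radius + pad) + 1
  c0 <- radius + pad + 1
  outer(seq_len(n), seq_len(n),
        function(r, c) as.numeric((r - c0)^2 + (c - c0)^2 <= radius^2))
}

raster_ellipse <- function(a, b, pad = 20) {
  nr <- 2 * (b + pad) + 1; nc <- 2 * (a + pad) + 1
  rc <- b + pad + 1; cc <- a + pad + 1
  outer(seq_len(nr), seq_len(nc),
        function(r, c) as.numeric((r - rc)^2 / b^2 + (c - cc)^2 / a^2 <= 1))
}

# Synthetic step-edge frame: bright reservoir (rows x cols) left of `edge_col`.
step_edge_frame <- function(edge_col, nrow = 40, ncol = 300, hi = 1, lo = 0,
                            noise_sd = 0) {
  frame <- matrix(lo, nrow, ncol)
  frame[, seq_len(edge_col - 1L)] <- hi
  if (noise_sd > 0) frame <- frame + matrix(rnorm(length(frame), sd = noise_sd),
                                            nrow, ncol)
  frame
}
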