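# Generators: diffusion PDE, image rendering, droplets, counts, sweeps.

test_that("analytic erfc solution has the right boundary, far-field and interior values", {
  expect_equal(analytic_erfc_solution(0, t = 100, d = 1e-6, c0 = 3), 3)
  # far field: x >= 10 * 2 sqrt(dt)
  far <- 10 * 2 * sqrt(1e-6 * 100)
  expect_lt(analytic_erfc_solution(far, 100, 1e-6), 1e-10)
  # x = 2 sqrt(dt) gives erfc(1); independent oracle: quadrature of the
  # defining integral erfc(1) = 2/sqrt(pi) * int_1^Inf exp(-s^2) ds
  erfc1 <- 2 / sqrt(pi) *
    integrate(function(s) exp(-s^2), 1, Inf, rel.tol = 1e-12)$value
  x1 <- 2 * sqrt(5e-7 * 600)
  expect_equal(analytic_erfc_solution(x1, 600, 5e-7, c0 = 2), 2 * erfc1,
               tolerance = 1e-10)
  expect_equal(erfc1, 0.15729920705, tolerance = 1e-9)
  expect_error(analytic_erfc_solution(0.1, t = 0, d = 1e-6), "t")
  expect_error(analytic_erfc_solution(0.1, t = 10, d = -1), "d")
})

test_that("PDE solver handles the no-transport and initial-condition cases exactly", {
  cfg <- diffusion_sim_config(d_true = 0, n_frames = 5)
  f <- simulate_diffusion_pde(cfg)
  expect_equal(f$values[1L, ], rep(1, 6))
  expect_true(all(f$values[-1L, ] == 0))
  cfg2 <- diffusion_sim_config(d_true = 1e-6, n_frames = 3)
  f2 <- simulate_diffusion_pde(cfg2)
  expect_equal(f2$values[-1L, 1L], rep(0, length(f2$x_grid) - 1L))
  expect_equal(f2$values[1L, 1L], 1)
})

test_that("PDE solution matches the analytic erfc oracle under a constant boundary", {
  cfg <- diffusion_sim_config(d_true = 1e-6, domain_length = 1, dx = 1e-3,
                              frame_interval = 240, n_frames = 15, c0 = 2)
  f <- simulate_diffusion_pde(cfg)
  ana <- analytic_erfc_solution(f$x_grid, 3600, 1e-6, c0 = 2)
  expect_lt(max(abs(f$values[, 16L] - ana)), 1e-3 * 2)
})

test_that("PDE solution is monotone non-increasing in x at every frame", {
  for (d in c(1e-7, 1e-6, 1e-5)) {
    cfg <- diffusion_sim_config(d_true = d, dx = 2e-3, n_frames = 10)
    f <- simulate_diffusion_pde(cfg)
    expect_true(all(apply(f$values, 2, function(v) all(diff(v) <= 1e-10))))
    expect_true(all(f$values >= -1e-12))
    expect_true(all(f$values <= 1 + 1e-9))
  }
})

test_that("grid refinement changes the solution by < 0.5% once dx <= L/500", {
  probe_x <- c(0.02, 0.05, 0.1)
  probe_t <- 3600
  vals <- lapply(c(1 / 500, 1 / 1000), function(h) {
    cfg <- diffusion_sim_config(d_true = 1e-6, domain_length = 1, dx = h,
                                frame_interval = 240, n_frames = 15)
    f <- simulate_diffusion_pde(cfg)
    approx(f$x_grid, f$values[, which(f$t_grid == probe_t)], xout = probe_x)$y
  })
  expect_lt(max(abs(vals[[2]] - vals[[1]]) / vals[[1]]), 0.005)
})

test_that("depleting reservoir conserves tracer mass", {
  cfg <- diffusion_sim_config(d_true = 5e-6, domain_length = 1, dx = 2e-3,
                              n_frames = 20, reservoir_mode = "depleting",
                              reservoir_volume_ratio = 2)
  f <- simulate_diffusion_pde(cfg)
  L <- cfg$domain_length
  # mass gained by the channel (trapezoid) vs lost by the reservoir
  channel_mass <- function(v) sum((v[-1] + v[-length(v)]) / 2) * cfg$dx
  gained <- channel_mass(f$values[, 21L]) - channel_mass(f$values[, 1L])
  lost <- (1 - f$reservoir[21L]) * cfg$reservoir_volume_ratio * L
  expect_equal(gained, lost, tolerance = 1e-6)
  # and the reservoir actually depletes
  expect_lt(f$reservoir[21L], 1)
})

test_that("solver rejects invalid configurations", {
  expect_error(diffusion_sim_config(d_true = -1), "d_true")
  expect_error(diffusion_sim_config(dx = 0), "dx")
  expect_error(diffusion_sim_config(domain_length = 0.005, dx = 1e-3),
               "domain_length")
  expect_error(diffusion_sim_config(n_frames = 1), "n_frames")
})

test_that("noiseless rendering reproduces concentrations at pixel centers", {
  cfg <- diffusion_sim_config(d_true = 5e-7, dx = 1e-4, n_frames = 5)
  f <- simulate_diffusion_pde(cfg)
  stack <- render_image_stack(f, noise_model(0, 0, 0), pixel_size = 10e-4,
                              channel_width_px = 10)
  x_centers <- (seq_len(dim(stack$frames)[2]) - 0.5) * 10e-4
  for (j in 1:5) {
    expected <- approx(f$x_grid, f$values[, j + 1L], xout = x_centers)$y
    expect_equal(stack$frames[3, , j], expected, tolerance = 1e-12)
  }
})

test_that("bleaching decays frame-mean intensity as exp(-k t)", {
  cfg <- diffusion_sim_config(d_true = 0, n_frames = 6)
  f <- simulate_diffusion_pde(cfg)
  f$values[] <- 0.5  # uniform field isolates the bleaching factor
  k <- 1e-4
  stack <- render_image_stack(f, noise_model(0, 0, bleach_rate = k),
                              channel_width_px = 5)
  means <- apply(stack$frames, 3, mean)
  expect_equal(means, 0.5 * exp(-k * stack$t_grid), tolerance = 1e-12)
})

test_that("rendering is deterministic for a fixed seed and pure in the RNG", {
  cfg <- diffusion_sim_config(d_true = 5e-7, dx = 5e-3, n_frames = 4)
  f <- simulate_diffusion_pde(cfg)
  nm <- noise_model(0.02, 100, 0, seed = 42L)
  s1 <- render_image_stack(f, nm, channel_width_px = 8)
  set.seed(999); before <- rnorm(1)
  s2 <- render_image_stack(f, nm, channel_width_px = 8)
  expect_identical(s1$frames, s2$frames)
  # generator must not disturb the caller's RNG stream
  set.seed(999)
  expect_identical(rnorm(1), before)
})

test_that("rendered stacks round-trip through 16-bit TIFF within quantization", {
  cfg <- diffusion_sim_config(d_true = 5e-7, dx = 1e-3, n_frames = 4)
  f <- simulate_diffusion_pde(cfg)
  stack <- render_image_stack(f, noise_model(0, 0, 0), channel_width_px = 6,
                              reservoir_px = 10)
  path <- tempfile(fileext = ".tiff")
  write_image_stack(stack, path, counts_per_unit = 5e4)
  back <- read_image_stack(path)
  expect_lt(max(abs(back$frames - stack$frames)), 1 / 5e4)
  expect_equal(back$interface_px, stack$interface_px)
  expect_equal(back$t_grid, stack$t_grid)
  unlink(c(path, paste0(path, ".json")))
})

test_that("droplet generator geometry follows the spherical-cap identities", {
  # theta = 90: cap height equals base radius
  d <- simulate_droplet_image(90, base_radius_px = 80, image_shape = c(300, 300))
  filled_rows <- which(apply(d$image > 0.5, 1, any))
  height <- d$baseline_row - min(filled_rows) + 1
  expect_equal(height, 80, tolerance = 0.02)
  # h = 0.5 a corresponds to theta = 2 atan(0.5) = 53.13 deg
  theta <- 2 * atan(0.5) * 180 / pi
  expect_equal(theta, 53.1301, tolerance = 1e-4)
  d2 <- simulate_droplet_image(theta, base_radius_px = 100,
                               image_shape = c(400, 400))
  filled <- which(apply(d2$image > 0.5, 1, any))
  expect_equal(d2$baseline_row - min(filled) + 1, 50, tolerance = 0.05)
  expect_error(simulate_droplet_image(0), "theta")
  expect_error(simulate_droplet_image(90, base_radius_px = 500,
                                      image_shape = c(100, 100)), "fit")
})

test_that("noiseless droplet segmentation recovers the generating contour within 1 px", {
  d <- simulate_droplet_image(60, base_radius_px = 90, image_shape = c(350, 400))
  contour <- segment_droplet(d$image)
  # every contour point above the baseline should sit on the generating circle
  above <- contour[contour[, 2] < d$baseline_row - 1, , drop = FALSE]
  r_emp <- sqrt((above[, 1] - d$center_x)^2 + (above[, 2] - d$center_y)^2)
  expect_lt(max(abs(r_emp - d$radius)), 1)
})

test_that("spot count simulation is Poisson with the right mean and deterministic", {
  t0 <- simulate_spot_counts(0, seed = 3L)
  expect_true(all(t0$count == 0))
  t1 <- simulate_spot_counts(2e8, seed = 11L)
  t2 <- simulate_spot_counts(2e8, seed = 11L)
  expect_identical(t1$count, t2$count)
  # mean over many seeds vs analytic mean at one dilution (3 SE band)
  mu <- 2e8 * 0.02 * 1e-5  # exponent 5
  counts <- vapply(1:1000, function(s) {
    simulate_spot_counts(2e8, dilution_exponents = 5, seed = s)$count
  }, numeric(1))
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("Maxwell frequency sweep matches closed forms", {
  # crossover: omega * tau = 1 gives G' = G'' = G/2
  sw <- simulate_frequency_sweep(100, relaxation_time = 1,
                                 omega_grid = c(0.01, 1, 100))
  expect_equal(sw$g_prime_pa[2], 50)
  expect_equal(sw$g_double_prime_pa[2], 50)
  expect_equal(attr(sw, "tan_delta_true")[2], 1)
  # sol-like low-frequency limit: tan delta = 1/(omega tau) >> 1
  expect_equal(attr(sw, "tan_delta_true")[1], 1 / 0.01, tolerance = 1e-3)
  # Hookean limit: purely elastic solid
  el <- simulate_frequency_sweep(100, relaxation_time = Inf)
  expect_true(all(el$g_double_prime_pa == 0))
  expect_true(all(el$g_prime_pa == 100))
})
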