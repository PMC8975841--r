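#' Simulate serial-dilution spot-plating colony counts
#'
#' Draws per-dilution colony counts for a single-plate serial-dilution
#' spotting (SP-SDS) experiment: the count at dilution `10^-e` is Poisson
#' with mean `true_cfu_per_ml * spot_volume_ml * 10^-e`, independently per
#' spot. Default dilutions span `10^-2` to `10^-9`, the plated volume 20 ul.
#'
#' @param true_cfu_per_ml ground-truth abundance (CFU/ml), `>= 0`.
#' @param spot_volume_ml plated spot volume (ml).
#' @param dilution_exponents integer exponents `e` meaning dilution `10^-e`.
#' @param seed integer seed.
#' @return A `data.frame` of class `spot_count_table` with columns
#'   `dilution_exponent`, `spot_volume_ml`, `count`, and the ground truth in
#'   attribute `true_cfu_per_ml`.
#' @export
simulate_spot_counts <- function(true_cfu_per_ml, spot_volume_ml = 0.02,
                                 dilution_exponents = 2:9, seed = 1L) {
  check_scalar(true_cfu_per_ml, "true_cfu_per_ml", lower = 0)
  check_scalar(spot_volume_ml, "spot_volume_ml", lower = 0, strict_lower = TRUE)
  if (any(dilution_exponents < 0) || any(dilution_exponents != round(dilution_exponents))) {
    stop_mucogel("'dilution_exponents' must be non-negative integers")
  }
  means <- true_cfu_per_ml * spot_volume_ml * 10^(-dilution_exponents)
  counts <- with_seed(seed, rpois(length(means), lambda = means))
  out <- data.frame(dilution_exponent = as.integer(dilution_exponents),
                    spot_volume_ml = spot_volume_ml,
                    count = counts)
  attr(out, "true_cfu_per_ml") <- true_cfu_per_ml
  class(out) <- c("spot_count_table", "data.frame")
  out
}

#' Simulate an oscillatory-rheology frequency sweep
#'
#' Generates storage and loss moduli over a frequency grid from a single-mode
#' Maxwell model, `G' = G w^2 tau^2 / (1 + w^2 tau^2)` and
#' `G'' = G w tau / (1 + w^2 tau^2)`, optionally with an additional elastic
#' plateau `G_plateau` added to `G'` (a crosslinked-network term, making the
#' response gel-like at low frequency as a calcium-crosslinked alginate gel
#' is). Multiplicative log-normal noise emulates instrument scatter.
#'
#' @param modulus_plateau Maxwell-mode strength `G` (Pa).
#' @param relaxation_time mode relaxation time `tau` (s). `Inf` gives a
#'   purely elastic (Hookean) solid: `G' = G`, `G'' = 0`.
#' @param omega_grid angular frequencies (rad/s), positive and increasing.
#'   Default: 30 log-spaced points over 0.1-100 rad/s.
#' @param g_plateau additional elastic plateau (Pa), default 0.
#' @param noise_cv coefficient of variation of multiplicative noise; 0 (the
#'   default) gives the exact model.
#' @param seed integer seed.
#' @return A `data.frame` of class `frequency_sweep` with columns
#'   `omega_rad_s`, `g_prime_pa`, `g_double_prime_pa`; ground-truth loss
#'   tangent in attribute `tan_delta_true`.
#' @export
simulate_frequency_sweep <- function(modulus_plateau, relaxation_time,
                                     omega_grid = 10^seq(-1, 2, length.out = 30),
                                     g_plateau = 0, noise_cv = 0, seed = 1L) {
  check_scalar(modulus_plateau, "modulus_plateau", lower = 0)
  if (!(is.numeric(relaxation_time) && length(relaxation_time) == 1L &&
        (is.infinite(relaxation_time) || relaxation_time > 0))) {
    stop_mucogel("'relaxation_time' must be a positive number or Inf")
  }
  check_scalar(g_plateau, "g_plateau", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  if (any(omega_grid <= 0) || is.unsorted(omega_grid, strictly = TRUE)) {
    stop_mucogel("'omega_grid' must be positive and strictly increasing")
  }
  if (is.infinite(relaxation_time)) {
    gp <- rep(modulus_plateau, length(omega_grid)) + g_plateau
    gpp <- rep(0, length(omega_grid))
  } else {
    wt <- omega_grid * relaxation_time
    gp <- modulus_plateau * wt^2 / (1 + wt^2) + g_plateau
    gpp <- modulus_plateau * wt / (1 + wt^2)
  }
  tan_true <- ifelse(gp > 0, gpp / gp, NA_real_)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, {
      gp <- gp * exp(rnorm(length(gp), -sdlog^2 / 2, sdlog))
      gpp <- gpp * exp(rnorm(length(gpp), -sdlog^2 / 2, sdlog))
    })
  }
  out <- data.frame(omega_rad_s = omega_grid, g_prime_pa = gp,
                    g_double_prime_pa = gpp)
  attr(out, "tan_delta_true") <- tan_true
  class(out) <- c("frequency_sweep", "data.frame")
  out
}
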