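#' Initial diffusivity guess from half-maximum crossings
#'
#' For each frame, finds the depth `x_half` at which the normalized
#' fluorescence first falls below half its interface (first-sample) value.
#' Under the semi-infinite erfc model that depth satisfies
#' `x_half = 2 * z_half * sqrt(d * t)` with `z_half = erfcinv(0.5) = 0.47694`,
#' so each frame yields `d_j = (x_half / (2 * z_half))^2 / t_j`; the median
#' over frames is returned. When no frame crosses the half level (flat or
#' saturated profiles) a fallback of 1e-7 cm^2/s is returned with a flag.
#'
#' @param matrix a `profile_matrix`.
#' @return List with `d0` (cm^2/s) and `fallback` (logical).
#' @export
initial_guess <- function(matrix) {
  stopifnot(inherits(matrix, "profile_matrix"))
  z_half <- erfcinv(0.5)
  ests <- vapply(seq_len(ncol(matrix$f)), function(j) {
    prof <- matrix$f[, j]
    half <- prof[1L] / 2
    below <- which(prof < half)
    if (length(below) == 0L || below[1L] == 1L) return(NA_real_)
    x_half <- matrix$x_grid[below[1L]]
    (x_half / (2 * z_half))^2 / matrix$t_grid[j]
  }, numeric(1))
  ests <- ests[is.finite(ests)]
  if (length(ests) == 0L) {
    return(list(d0 = 1e-7, fallback = TRUE))
  }
  list(d0 = median(ests), fallback = FALSE)
}

# Drop frames whose reservoir reference drifted > 20% from the first frame
# (bleaching / evaporation guard). Returns the matrix and indices dropped.
guard_reference_drift <- function(matrix, tolerance = 0.2) {
  ref <- matrix$reference_intensity
  drift <- abs(ref / ref[1L] - 1)
  bad <- which(drift > tolerance)
  if (length(bad) > 0L) {
    warning(sprintf("excluding %d frame(s) with reference drift > %.0f%%: %s",
                    length(bad), 100 * tolerance,
                    paste(bad, collapse = ", ")), call. = FALSE)
    keep <- setdiff(seq_len(ncol(matrix$f)), bad)
    matrix <- new_profile_matrix(matrix$f[, keep, drop = FALSE], matrix$x_grid,
                                 matrix$t_grid[keep],
                                 interface_px = matrix$interface_px,
                                 reference_intensity = ref[keep])
  }
  list(matrix = matrix, excluded = bad)
}

new_diffusion_fit <- function(d_eff, amplitude, offset, fitted, matrix, model,
                              converged, ci = c(NA_real_, NA_real_),
                              boot = NULL, seed = NA_integer_,
                              excluded_frames = integer()) {
  resid <- matrix$f - fitted
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((matrix$f - mean(matrix$f))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(resid^2) / ss_tot)) else NA_real_
  structure(
    list(d_eff = d_eff, amplitude = amplitude, offset = offset,
         residual_rmse = rmse, r_squared = r2,
         ci_low = ci[1L], ci_high = ci[2L], converged = converged,
         model = model, fitted = fitted, boot = boot, seed = seed,
         excluded_frames = excluded_frames,
         x_grid = matrix$x_grid, t_grid = matrix$t_grid),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> model = %s\n", x$model))
  cat(sprintf("  D_eff     : %.4g cm^2/s", x$d_eff))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  [%.4g, %.4g] (bootstrap 95%%)", x$ci_low, x$ci_high))
  }
  cat("\n")
  cat(sprintf("  amplitude : %.4g   offset: %.4g\n", x$amplitude, x$offset))
  cat(sprintf("  RMSE      : %.4g   R^2: %.4f   converged: %s\n",
              x$residual_rmse, x$r_squared, x$converged))
  invisible(x)
}

erfc_model_matrix <- function(x_grid, t_grid, d, amplitude, offset) {
  z <- outer(x_grid, 2 * sqrt(d * t_grid), "/")
  amplitude * erfc(z) + offset
}

# core erfc least-squares on one matrix; no bootstrap, no guards
fit_erfc_core <- function(matrix, d0, fit_amplitude, fit_offset) {
  f <- matrix$f
  x <- matrix$x_grid
  t <- matrix$t_grid
  par0 <- c(log_d = log10(d0))
  lower <- c(log_d = -12)
  upper <- c(log_d = -1)
  if (fit_amplitude) {
    par0 <- c(par0, amplitude = min(max(f[1L, 1L], 0.05), 2))
    lower <- c(lower, amplitude = 1e-6)
    upper <- c(upper, amplitude = 2)
  }
  if (fit_offset) {
    par0 <- c(par0, offset = 0)
    lower <- c(lower, offset = -0.5)
    upper <- c(upper, offset = 0.5)
  }
  residual <- function(p) {
    pred <- erfc_model_matrix(x, t, 10^p[["log_d"]],
                              if (fit_amplitude) p[["amplitude"]] else 1,
                              if (fit_offset) p[["offset"]] else 0)
    as.numeric(pred - f)
  }
  best <- NULL
  par_try <- par0
  for (attempt in 1:5) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par_try, lower = lower, upper = upper,
                         fn = residual,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(fit = fit, sse = sse)
      }
      if (fit$info %in% 1:4) break
    }
    # restart from a jittered guess
    par_try <- par0
    par_try[["log_d"]] <- par0[["log_d"]] + runif(1, -1, 1)
  }
  if (is.null(best)) return(NULL)
  p <- best$fit$par
  d_hat <- 10^p[["log_d"]]
  # a matrix with no spatial structure cannot constrain d (e.g. F constant)
  identifiable <- max(apply(f, 2, function(v) diff(range(v)))) >
    1e-9 * (mean(abs(f)) + 1)
  list(d = d_hat,
       amplitude = if (fit_amplitude) p[["amplitude"]] else 1,
       offset = if (fit_offset) p[["offset"]] else 0,
       converged = (best$fit$info %in% 1:4) && identifiable,
       info = best$fit$info)
}

#' Fit the one-dimensional diffusion (erfc) model to normalized profiles
#'
#' Estimates the effective diffusion coefficient by nonlinear least squares
#' of `F(x, t) = A * erfc(x / (2 * sqrt(D * t))) + B` jointly over every
#' space-time cell of the profile matrix. The semi-infinite constant-boundary
#' model makes `F` proportional to `erfc`; the free amplitude `A` (default)
#' absorbs normalization error, and the opt-in offset `B` absorbs camera
#' background. Uncertainty is a percentile bootstrap over frames (frames are
#' resampled with replacement; axial pixels within a frame are strongly
#' correlated, so pixel-level resampling would be anticonservative).
#'
#' Frames whose reference intensity drifted more than 20% from the first
#' frame are excluded with a warning before fitting.
#'
#' @param matrix a `profile_matrix` (all `t > 0`).
#' @param fit_amplitude fit `A` in (0, 2] (default) or fix `A = 1`.
#' @param fit_offset fit `B` in \[-0.5, 0.5\] (default fixed at 0).
#' @param n_boot bootstrap replicates for the 95% CI; 0 skips the bootstrap.
#' @param boot_seed seed for the bootstrap resampling.
#' @return A `diffusion_fit` with `d_eff` (cm^2/s), `amplitude`, `offset`,
#'   `residual_rmse`, `r_squared`, `ci_low`/`ci_high`, `converged`, and the
#'   fitted matrix for diagnostics.
#' @export
fit_erfc <- function(matrix, fit_amplitude = TRUE, fit_offset = FALSE,
                     n_boot = 200, boot_seed = 1L) {
  stopifnot(inherits(matrix, "profile_matrix"))
  if (any(matrix$t_grid <= 0)) stop_mucogel("all frame times must be > 0")
  guarded <- guard_reference_drift(matrix)
  matrix <- guarded$matrix
  g <- initial_guess(matrix)
  core <- with_seed(boot_seed, fit_erfc_core(matrix, g$d0, fit_amplitude, fit_offset))
  if (is.null(core)) {
    fitted <- erfc_model_matrix(matrix$x_grid, matrix$t_grid, g$d0, 1, 0)
    return(new_diffusion_fit(g$d0, 1, 0, fitted, matrix, "erfc", FALSE,
                             excluded_frames = guarded$excluded))
  }
  ci <- c(NA_real_, NA_real_)
  boot <- NULL
  if (n_boot > 0 && core$converged) {
    n_frames <- ncol(matrix$f)
    boot <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sort(sample.int(n_frames, replace = TRUE))
        sub <- new_profile_matrix(matrix$f[, idx, drop = FALSE], matrix$x_grid,
                                  # resampled frames keep their own clocks;
                                  # enforce strict ordering by tiny jitter of
                                  # duplicated times (model depends on t only)
                                  matrix$t_grid[idx] * (1 + 1e-12 * seq_along(idx)),
                                  reference_intensity = matrix$reference_intensity[idx])
        r <- fit_erfc_core(sub, core$d, fit_amplitude, fit_offset)
        if (is.null(r)) NA_real_ else r$d
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  fitted <- erfc_model_matrix(matrix$x_grid, matrix$t_grid, core$d,
                              core$amplitude, core$offset)
  new_diffusion_fit(core$d, core$amplitude, core$offset, fitted, matrix,
                    "erfc", core$converged, ci = ci, boot = boot,
                    seed = boot_seed, excluded_frames = guarded$excluded)
}

# Forward PDE model sampled on a profile grid, normalized to c0 = 1.
pde_model_matrix <- function(x_grid, t_grid, d, reservoir_mode,
                             reservoir_volume_ratio, domain_length,
                             n_nodes = 201L) {
  dt <- min(diff(c(0, t_grid)))
  n_frames <- round(max(t_grid) / dt)
  cfg <- diffusion_sim_config(
    d_true = d, domain_length = domain_length,
    dx = domain_length / (n_nodes - 1L),
    frame_interval = dt, n_frames = n_frames,
    reservoir_mode = reservoir_mode,
    reservoir_volume_ratio = reservoir_volume_ratio, c0 = 1
  )
  field <- simulate_diffusion_pde(cfg)
  cols <- vapply(t_grid, function(t) which.min(abs(field$t_grid - t)), integer(1))
  out <- matrix(0, nrow = length(x_grid), ncol = length(t_grid))
  for (j in seq_along(cols)) {
    out[, j] <- approx(field$x_grid, field$values[, cols[j]],
                       xout = x_grid, rule = 2)$y
  }
  out
}

#' Fit a finite-difference diffusion forward model to normalized profiles
#'
#' Like [fit_erfc()], but the model curve is the Crank-Nicolson solution of
#' the diffusion equation on a finite domain, so the semi-infinite assumption
#' is dropped and a depleting reservoir can be modeled. Under a constant
#' boundary and a domain much longer than the profile window the two
#' estimators agree; with appreciable reservoir depletion the erfc fit is
#' biased low while this fit recovers the true diffusivity.
#'
#' @inheritParams fit_erfc
#' @param reservoir_mode boundary behavior of the forward model.
#' @param reservoir_volume_ratio reservoir / channel volume ratio (depleting
#'   mode).
#' @param domain_length forward-model domain (cm); default 5x the profile
#'   window, long enough to be effectively semi-infinite for the constant
#'   mode.
#' @param n_nodes forward-model grid nodes.
#' @return A `diffusion_fit` with `model` `"pde_constant"` or
#'   `"pde_depleting"`.
#' @export
fit_pde <- function(matrix, reservoir_mode = c("constant", "depleting"),
                    reservoir_volume_ratio = 10, domain_length = NULL,
                    n_nodes = 201L, fit_amplitude = TRUE) {
  stopifnot(inherits(matrix, "profile_matrix"))
  reservoir_mode <- match.arg(reservoir_mode)
  if (any(matrix$t_grid <= 0)) stop_mucogel("all frame times must be > 0")
  guarded <- guard_reference_drift(matrix)
  matrix <- guarded$matrix
  domain_length <- domain_length %||% max(5 * max(matrix$x_grid), 1.0)
  g <- initial_guess(matrix)
  f <- matrix$f

  objective <- function(log_d) {
    pred <- pde_model_matrix(matrix$x_grid, matrix$t_grid, 10^log_d,
                             reservoir_mode, reservoir_volume_ratio,
                             domain_length, n_nodes)
    if (fit_amplitude) {
      # amplitude solved in closed form (linear in A)
      a_hat <- sum(pred * f) / sum(pred^2)
      a_hat <- min(max(a_hat, 1e-6), 2)
    } else a_hat <- 1
    sum((a_hat * pred - f)^2)
  }
  opt <- optim(log10(g$d0), objective, method = "Brent",
               lower = -12, upper = -1,
               control = list(reltol = 1e-12))
  d_hat <- 10^opt$par
  pred <- pde_model_matrix(matrix$x_grid, matrix$t_grid, d_hat,
                           reservoir_mode, reservoir_volume_ratio,
                           domain_length, n_nodes)
  a_hat <- if (fit_amplitude) min(max(sum(pred * f) / sum(pred^2), 1e-6), 2) else 1
  fitted <- a_hat * pred
  model <- paste0("pde_", reservoir_mode)
  converged <- opt$convergence == 0 && is.finite(d_hat)
  new_diffusion_fit(d_hat, a_hat, 0, fitted, matrix, model, converged,
                    excluded_frames = guarded$excluded)
}

#' Residual diagnostics for a diffusion fit
#'
#' Recomputes the residual field of a fit against the matrix it came from
#' and summarizes it: root-mean-square error, coefficient of determination,
#' and the full residual matrix for plotting.
#'
#' @param matrix the `profile_matrix` the fit was computed on.
#' @param result a `diffusion_fit`.
#' @return List with `r_squared`, `rmse`, `residuals` (space x time matrix).
#' @export
goodness_of_fit <- function(matrix, result) {
  stopifnot(inherits(matrix, "profile_matrix"), inherits(result, "diffusion_fit"))
  if (!identical(dim(matrix$f), dim(result$fitted)) ||
      max(abs(matrix$x_grid - result$x_grid)) > 1e-12) {
    stop_mucogel("fit and matrix grids do not match")
  }
  resid <- matrix$f - result$fitted
  ss_tot <- sum((matrix$f - mean(matrix$f))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  list(r_squared = r2, rmse = sqrt(mean(resid^2)), residuals = resid)
}
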