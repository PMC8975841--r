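#' Configuration for a one-dimensional tracer diffusion simulation
#'
#' Describes the ground-truth physics and geometry of a simulated channel
#' diffusion assay: a fluorescent tracer enters a hydrogel-filled channel from
#' a liquid reservoir at `x = 0` and diffuses along the channel axis. The
#' default geometry mirrors the characterization assay the package targets: a
#' 1 cm channel imaged every 4 minutes, with a 2 mm profile window analyzed
#' over 30 frames.
#'
#' @param d_true ground-truth effective diffusion coefficient (cm^2/s).
#' @param domain_length channel length (cm).
#' @param dx spatial grid spacing (cm). Must satisfy
#'   `domain_length >= 10 * dx`.
#' @param frame_interval time between stored frames (s).
#' @param n_frames number of stored frames (>= 2). Frame `j` corresponds to
#'   elapsed time `j * frame_interval`; the initial condition is stored
#'   separately so the model is never evaluated at `t = 0`.
#' @param reservoir_mode `"constant"` holds the boundary at `c0` for all time
#'   (the semi-infinite assumption behind the erfc model); `"depleting"`
#'   treats the reservoir as a finite well-mixed compartment whose
#'   concentration drops as tracer enters the gel.
#' @param reservoir_volume_ratio reservoir volume expressed as a multiple of
#'   the channel volume; used only in depleting mode.
#' @param c0 initial reservoir concentration (arbitrary fluorescence units).
#' @param seed integer seed recorded with the configuration (the PDE solve is
#'   deterministic; the seed seeds downstream noise).
#'
#' @return An object of class `diffusion_sim_config`.
#' @seealso [simulate_diffusion_pde()], [render_image_stack()]
#' @export
diffusion_sim_config <- function(d_true = 5e-7,
                                 domain_length = 1.0,
                                 dx = 1e-3,
                                 frame_interval = 240,
                                 n_frames = 30,
                                 reservoir_mode = c("constant", "depleting"),
                                 reservoir_volume_ratio = 10,
                                 c0 = 1,
                                 seed = 1L) {
  reservoir_mode <- match.arg(reservoir_mode)
  check_scalar(d_true, "d_true", lower = 0)
  check_scalar(dx, "dx", lower = 0, strict_lower = TRUE)
  check_scalar(domain_length, "domain_length", lower = 10 * dx)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", lower = 2, integer = TRUE)
  check_scalar(reservoir_volume_ratio, "reservoir_volume_ratio",
               lower = 0, strict_lower = TRUE)
  check_scalar(c0, "c0", lower = 0, strict_lower = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(d_true = d_true, domain_length = domain_length, dx = dx,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         reservoir_mode = reservoir_mode,
         reservoir_volume_ratio = reservoir_volume_ratio,
         c0 = c0, seed = as.integer(seed)),
    class = "diffusion_sim_config"
  )
}

#' Analytic concentration profile for diffusion into a semi-infinite medium
#'
#' Closed-form solution of the one-dimensional diffusion equation with a
#' constant-concentration boundary at `x = 0` and zero initial concentration:
#' `C(x, t) = c0 * erfc(x / (2 * sqrt(d * t)))`. This is the model fitted to
#' normalized fluorescence profiles to estimate the effective diffusion
#' coefficient, and the independent oracle for the finite-difference solver.
#'
#' @param x distance from the reservoir-hydrogel interface (cm), `>= 0`.
#' @param t elapsed time (s), `> 0`.
#' @param d diffusion coefficient (cm^2/s), `> 0`.
#' @param c0 boundary concentration (fluorescence units).
#' @return Concentration at `(x, t)`, recycled over the longer of `x`, `t`.
#' @export
analytic_erfc_solution <- function(x, t, d, c0 = 1) {
  if (any(!is.finite(x)) || any(x < 0)) stop_mucogel("'x' must be >= 0")
  if (any(!is.finite(t)) || any(t <= 0)) stop_mucogel("'t' must be > 0")
  check_scalar(d, "d", lower = 0, strict_lower = TRUE)
  c0 * erfc(x / (2 * sqrt(d * t)))
}

# Thomas algorithm for a constant tridiagonal system solved repeatedly.
# Returns a function b -> x with forward-elimination coefficients precomputed.
tridiag_solver <- function(lower, diag, upper) {
  n <- length(diag)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  dp[1L] <- diag[1L]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      cp[i] <- upper[i] / dp[i]
      dp[i + 1L] <- diag[i + 1L] - lower[i] * cp[i]
    }
  }
  if (any(abs(dp) < .Machine$double.eps)) {
    stop_mucogel("singular tridiagonal system: unstable discretization parameters")
  }
  function(b) {
    y <- numeric(n)
    y[1L] <- b[1L] / dp[1L]
    if (n > 1L) {
      for (i in 2:n) y[i] <- (b[i] - lower[i - 1L] * y[i - 1L]) / dp[i]
      for (i in (n - 1L):1L) y[i] <- y[i] - cp[i] * y[i + 1L]
    }
    y
  }
}

#' Simulate Fickian diffusion into a hydrogel channel
#'
#' Solves `dC/dt = D d2C/dx2` on `[0, domain_length]` by the Crank-Nicolson
#' scheme (second order in space and time, unconditionally stable, so no
#' silent blow-up at user-chosen grids). The boundary at `x = 0` is held at
#' the reservoir concentration -- constant `c0`, or depleting by the mass flux
#' into the channel scaled by the reservoir-to-channel volume ratio -- and the
#' far end is zero-flux. Initial condition: `C = 0` for `x > 0`.
#'
#' In depleting mode the reservoir is a well-mixed compartment: each step its
#' concentration drops by exactly (channel mass gain) / (reservoir volume), so
#' tracer mass is conserved to round-off by construction.
#'
#' @param config a [diffusion_sim_config()].
#' @param dt_max optional cap on the internal time step (s). By default the
#'   step is chosen so the diffusion number `D * dt / dx^2` is at most 2 and
#'   frames land exactly on stored times; Crank-Nicolson is stable at any
#'   step, the cap controls temporal accuracy.
#' @return An object of class `concentration_field`: list with `values`
#'   (space x time matrix including the `t = 0` column), `x_grid` (cm, node
#'   positions, `x = 0` at the interface), `t_grid` (s), the reservoir
#'   concentration trace, and the generating config.
#' @export
simulate_diffusion_pde <- function(config, dt_max = NULL) {
  stopifnot(inherits(config, "diffusion_sim_config"))
  L <- config$domain_length
  dx <- config$dx
  n_nodes <- round(L / dx) + 1L
  x_grid <- seq(0, L, length.out = n_nodes)
  t_grid <- c(0, seq_len(config$n_frames) * config$frame_interval)
  values <- matrix(0, nrow = n_nodes, ncol = length(t_grid))

  c_res <- config$c0
  values[1L, 1L] <- c_res

  if (config$d_true == 0) {
    # no transport: interior stays at 0, boundary tracks the reservoir
    values[1L, ] <- config$c0
    return(new_concentration_field(values, x_grid, t_grid,
                                   reservoir = rep(config$c0, length(t_grid)),
                                   config = config))
  }

  # substep so the diffusion number stays modest (accuracy, not stability)
  dt_acc <- 2 * dx^2 / config$d_true
  dt_target <- min(config$frame_interval, dt_acc, dt_max %||% Inf)
  n_sub <- max(1L, ceiling(config$frame_interval / dt_target))
  dt <- config$frame_interval / n_sub
  r <- config$d_true * dt / dx^2

  # Crank-Nicolson on interior + Neumann end node; Dirichlet node 1 handled
  # through the right-hand side. Unknowns are nodes 2..n_nodes.
  m <- n_nodes - 1L
  lower <- rep(-r / 2, m - 1L)
  upper <- rep(-r / 2, m - 1L)
  diagv <- rep(1 + r, m)
  # zero-flux at x = L via ghost node: C[n+1] = C[n-1]
  lower[m - 1L] <- -r
  solve_step <- tridiag_solver(lower, diagv, upper)

  c_now <- values[, 1L]
  res_trace <- numeric(length(t_grid))
  res_trace[1L] <- c_res
  channel_mass <- function(v) sum((v[-1L] + v[-length(v)]) / 2) * dx

  for (frame in seq_len(config$n_frames)) {
    for (s in seq_len(n_sub)) {
      mass_before <- channel_mass(c_now)
      # explicit half of CN applied to current state (interior nodes 2..n-1)
      idx <- 2:(n_nodes - 1L)
      rhs_interior <- c_now[idx] +
        (r / 2) * (c_now[idx - 1L] - 2 * c_now[idx] + c_now[idx + 1L])
      rhs_end <- c_now[n_nodes] +
        (r / 2) * (2 * c_now[n_nodes - 1L] - 2 * c_now[n_nodes])
      rhs <- c(rhs_interior, rhs_end)
      # implicit-side Dirichlet term (explicit side already in rhs_interior
      # through c_now[1]); boundary frozen at c_res over the substep
      rhs[1L] <- rhs[1L] + (r / 2) * c_res
      c_new <- c(c_res, solve_step(rhs))
      if (any(!is.finite(c_new))) {
        stop_mucogel("diffusion solve produced non-finite values; refine dx/dt")
      }
      if (config$reservoir_mode == "depleting") {
        # the boundary node (trapezoid weight dx/2) is part of the channel
        # mass, so its reset to the new reservoir level enters the balance;
        # solving the linear pair (gain, new level) keeps mass conserved to
        # round-off
        v_res <- config$reservoir_volume_ratio * L
        mass_rest <- channel_mass(c_new) - c_new[1L] * dx / 2
        c_res_new <- (c_res - (mass_rest - mass_before) / v_res) /
          (1 + dx / (2 * v_res))
        c_res <- max(c_res_new, 0)
        c_new[1L] <- c_res
      }
      c_now <- c_new
    }
    values[, frame + 1L] <- c_now
    res_trace[frame + 1L] <- c_res
  }
  new_concentration_field(values, x_grid, t_grid, reservoir = res_trace,
                          config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_concentration_field <- function(values, x_grid, t_grid, reservoir,
                                    config = NULL) {
  structure(
    list(values = values, x_grid = x_grid, t_grid = t_grid,
         reservoir = reservoir, config = config),
    class = "concentration_field"
  )
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "<concentration_field> %d nodes x %d times, x in [0, %g] cm, t in [0, %g] s\n",
    nrow(x$values), ncol(x$values), max(x$x_grid), max(x$t_grid)))
  invisible(x)
}
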