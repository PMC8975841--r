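#' Build a spot-count table from vectors
#'
#' @param dilution_exponent integer exponents `e` meaning dilution `10^-e`.
#' @param spot_volume_ml plated volume per spot (ml), recycled.
#' @param count colony counts (non-negative integers).
#' @return A `data.frame` of class `spot_count_table`.
#' @export
spot_count_table <- function(dilution_exponent, spot_volume_ml, count) {
  out <- data.frame(dilution_exponent = dilution_exponent,
                    spot_volume_ml = spot_volume_ml, count = count)
  validate_spot_table(out)
  class(out) <- c("spot_count_table", "data.frame")
  out
}

validate_spot_table <- function(table) {
  need <- c("dilution_exponent", "spot_volume_ml", "count")
  if (!all(need %in% names(table))) {
    stop_mucogel("spot count table needs columns: %s", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    if (!is.finite(r$count) || r$count < 0 || r$count != round(r$count)) {
      stop_mucogel("row %d: count must be a non-negative integer (got %s)",
                   i, format(r$count))
    }
    if (!is.finite(r$spot_volume_ml) || r$spot_volume_ml <= 0) {
      stop_mucogel("row %d: spot_volume_ml must be > 0", i)
    }
    if (!is.finite(r$dilution_exponent) || r$dilution_exponent < 0 ||
        r$dilution_exponent != round(r$dilution_exponent)) {
      stop_mucogel("row %d: dilution_exponent must be a non-negative integer", i)
    }
  }
  invisible(table)
}

#' CFU/ml from a serial-dilution spot-plating table
#'
#' Applies the SP-SDS countable range -- only spots with between
#' `countable_min` and `countable_max` colonies (default 6-60) are reliable
#' -- and converts each usable row to an abundance estimate
#' `count / (spot_volume_ml * 10^-exponent)`. Usable rows are averaged by
#' default; `mode = "most_dilute"` instead takes the single most dilute
#' usable row. When no row is countable the result is censored: abundance 0
#' with the detection limit `countable_min / (spot_volume_ml * 10^-e_max)`
#' at the most dilute plated exponent attached.
#'
#' @param table a `spot_count_table` (or data.frame with the same columns).
#' @param countable_min,countable_max countable range (colonies).
#' @param mode `"mean"` (average usable rows) or `"most_dilute"`.
#' @return An object of class `cfu_result`: list with `cfu_per_ml`,
#'   `usable_rows` (indices), `censored`, `detection_limit`.
#' @export
cfu_per_ml <- function(table, countable_min = 6, countable_max = 60,
                       mode = c("mean", "most_dilute")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) stop_mucogel("spot count table is empty")
  validate_spot_table(table)
  per_row <- table$count / (table$spot_volume_ml * 10^(-table$dilution_exponent))
  usable <- which(table$count >= countable_min & table$count <= countable_max)
  if (length(usable) == 0L) {
    e_max <- max(table$dilution_exponent)
    v <- table$spot_volume_ml[which.max(table$dilution_exponent)]
    return(structure(list(cfu_per_ml = 0, usable_rows = integer(),
                          censored = TRUE,
                          detection_limit = countable_min / (v * 10^(-e_max))),
                     class = "cfu_result"))
  }
  est <- if (mode == "mean") mean(per_row[usable])
  else per_row[usable[which.max(table$dilution_exponent[usable])]]
  structure(list(cfu_per_ml = est, usable_rows = usable, censored = FALSE,
                 detection_limit = NA_real_),
            class = "cfu_result")
}

#' @export
print.cfu_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<cfu_result> censored: no countable spot (detection limit %.3g CFU/ml)\n",
                x$detection_limit))
  } else {
    cat(sprintf("<cfu_result> %.4g CFU/ml from %d usable row(s)\n",
                x$cfu_per_ml, length(x$usable_rows)))
  }
  invisible(x)
}

#' Live/Dead cell viability
#'
#' `viability = 100 * (total - dead) / total` percent, from a total
#' (nucleus) count and a dead-cell count.
#'
#' @param total_cells total cell count (> 0).
#' @param dead_cells dead cell count, `0 <= dead <= total`.
#' @return Viability in percent.
#' @export
viability <- function(total_cells, dead_cells) {
  check_scalar(total_cells, "total_cells", lower = 0, strict_lower = TRUE)
  check_scalar(dead_cells, "dead_cells", lower = 0)
  if (dead_cells > total_cells) {
    stop_mucogel("dead_cells (%g) exceeds total_cells (%g)",
                 dead_cells, total_cells)
  }
  100 * (total_cells - dead_cells) / total_cells
}

#' Count nuclei and dead cells in a stained image pair
#'
#' Minimal spot counter for Live/Dead + nuclear-stain image pairs: each
#' channel is band-pass filtered (difference of Gaussians at the spot
#' scale), local maxima above a threshold are detected with a minimum
#' separation, and dead-cell spots are matched to the nearest nucleus within
#' `match_radius_px` (unmatched dead spots are ignored as debris). The
#' returned counts feed [viability()].
#'
#' @param nuclei_image,dead_image co-registered grayscale matrices of equal
#'   shape.
#' @param match_radius_px maximum nucleus-to-dead-spot distance for a match.
#' @param spot_sigma approximate spot radius scale (px) for the band-pass.
#' @param threshold detection threshold as a fraction of the filtered
#'   image's maximum.
#' @return List with `total`, `dead`, and the detected coordinates.
#' @export
count_cells <- function(nuclei_image, dead_image, match_radius_px = 5,
                        spot_sigma = 2, threshold = 0.3) {
  stopifnot(is.matrix(nuclei_image), is.matrix(dead_image))
  if (!identical(dim(nuclei_image), dim(dead_image))) {
    stop_mucogel("image shapes differ: %s vs %s",
                 paste(dim(nuclei_image), collapse = "x"),
                 paste(dim(dead_image), collapse = "x"))
  }
  nuclei <- detect_spots(nuclei_image, spot_sigma, threshold)
  dead <- detect_spots(dead_image, spot_sigma, threshold)
  matched <- 0L
  if (nrow(dead) > 0L && nrow(nuclei) > 0L) {
    for (i in seq_len(nrow(dead))) {
      dists <- sqrt((nuclei[, 1L] - dead[i, 1L])^2 +
                    (nuclei[, 2L] - dead[i, 2L])^2)
      if (min(dists) <= match_radius_px) matched <- matched + 1L
    }
  }
  list(total = nrow(nuclei), dead = matched,
       nuclei_xy = nuclei, dead_xy = dead)
}

# difference-of-Gaussians band-pass + local maxima with minimum separation
detect_spots <- function(image, spot_sigma, threshold) {
  img <- EBImage::Image(t(image))
  lo <- EBImage::gblur(img, sigma = spot_sigma)
  hi <- EBImage::gblur(img, sigma = 3 * spot_sigma)
  band <- lo - hi
  m <- t(EBImage::imageData(band))
  peak <- max(m)
  if (peak <= 0) return(matrix(numeric(0), ncol = 2))
  thr <- threshold * peak
  sep <- max(3L, ceiling(2 * spot_sigma))
  # local maximum within a (2*sep+1)^2 neighborhood via grayscale dilation
  dil <- t(EBImage::imageData(EBImage::dilate(
    band, EBImage::makeBrush(2 * sep + 1, shape = "box"))))
  is_peak <- (m >= dil - 1e-12) & (m > thr)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 2))
  # suppress duplicate plateau peaks closer than sep
  ord <- order(m[is_peak], decreasing = TRUE)
  pts <- idx[ord, , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nrow(kept) == 0L ||
        min((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2) > sep^2) {
      kept <- rbind(kept, p)
    }
  }
  colnames(kept) <- c("row", "col")
  kept
}

#' Loss tangent from a frequency sweep
#'
#' Computes `tan(delta) = G'' / G'` at every frequency of the sweep, and
#' answers query frequencies either by the nearest grid point within 5%
#' (mirroring how instrument grids are read at nominal frequencies such as 1
#' and 10 rad/s) or by linear interpolation in log frequency (opt-in).
#'
#' @param sweep a `frequency_sweep` (or data.frame with columns
#'   `omega_rad_s`, `g_prime_pa`, `g_double_prime_pa`).
#' @param query optional frequencies (rad/s) to report.
#' @param match `"nearest"` (within `nearest_tol`) or `"interpolate"`.
#' @param nearest_tol relative tolerance for nearest-point matching.
#' @return List with `omega`, `tan_delta` (per grid point), and if queried a
#'   data.frame `at_query` with `omega_query`, `tan_delta`, `method`.
#' @export
loss_tangent <- function(sweep, query = NULL,
                         match = c("nearest", "interpolate"),
                         nearest_tol = 0.05) {
  match <- match.arg(match)
  need <- c("omega_rad_s", "g_prime_pa", "g_double_prime_pa")
  if (!all(need %in% names(sweep))) {
    stop_mucogel("sweep needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(sweep$g_prime_pa <= 0)) {
    stop_mucogel("tan(delta) undefined: G' <= 0 at omega = %g rad/s",
                 sweep$omega_rad_s[which(sweep$g_prime_pa <= 0)[1L]])
  }
  td <- sweep$g_double_prime_pa / sweep$g_prime_pa
  out <- list(omega = sweep$omega_rad_s, tan_delta = td)
  if (!is.null(query)) {
    vals <- vapply(query, function(w) {
      if (match == "nearest") {
        i <- which.min(abs(sweep$omega_rad_s - w))
        if (abs(sweep$omega_rad_s[i] - w) > nearest_tol * w) {
          stop_mucogel("no grid point within %.0f%% of omega = %g rad/s; use match = 'interpolate'",
                       100 * nearest_tol, w)
        }
        td[i]
      } else {
        if (w < min(sweep$omega_rad_s) || w > max(sweep$omega_rad_s)) {
          stop_mucogel("query omega = %g rad/s outside the sweep range", w)
        }
        approx(log(sweep$omega_rad_s), td, xout = log(w))$y
      }
    }, numeric(1))
    out$at_query <- data.frame(omega_query = query, tan_delta = vals,
                               method = match)
  }
  out
}

#' Linear viscoelastic (LVE) region of a strain sweep
#'
#' Identifies the strain range over which the storage modulus is
#' strain-independent: the plateau is the median G' over the lowest decade
#' of strain, and the LVE region is the maximal initial run of points with
#' `|G' - plateau| <= tolerance * plateau` (default 5%).
#'
#' @param strain_sweep data.frame with columns `strain_pct` (increasing) and
#'   `g_prime_pa`.
#' @param tolerance allowed relative deviation from the plateau.
#' @return List with `strain_min`, `strain_max` (the LVE bounds), `plateau`
#'   (Pa), and `n_points` in the region.
#' @export
lve_region <- function(strain_sweep, tolerance = 0.05) {
  need <- c("strain_pct", "g_prime_pa")
  if (!all(need %in% names(strain_sweep))) {
    stop_mucogel("strain sweep needs columns: %s", paste(need, collapse = ", "))
  }
  s <- strain_sweep$strain_pct
  g <- strain_sweep$g_prime_pa
  if (length(s) < 5L) stop_mucogel("need at least 5 strain points")
  if (is.unsorted(s, strictly = TRUE)) stop_mucogel("strains must be strictly increasing")
  low_decade <- s <= min(s) * 10
  plateau <- median(g[low_decade])
  ok <- abs(g - plateau) <= tolerance * plateau
  if (!ok[1L]) {
    stop_mucogel("no LVE plateau: G' deviates from the low-strain median at the first point")
  }
  last <- which(!ok)[1L]
  last <- if (is.na(last)) length(s) else last - 1L
  list(strain_min = s[1L], strain_max = s[last], plateau = plateau,
       n_points = last)
}

#' Hydrogel recipe volumes for an alginate / alginate-mucin gel
#'
#' Computes component volumes for a crosslinked hydrogel mixed from an
#' alginate stock, a mucin stock, PBS, and a CaCl2 crosslinker solution that
#' makes up a fixed fraction (default half) of the total volume. Stock
#' dilution is linear: `component volume = total * target% / stock%`; PBS
#' fills the remainder of the non-crosslinker half. Volumes are reported in
#' integer microliters with any rounding remainder assigned to PBS so the
#' components always sum exactly to the total. The final crosslinker
#' concentration is `stock_mM * fraction_of_total`.
#'
#' @param total_volume total hydrogel volume (ul).
#' @param alginate_target_pct,alginate_stock_pct target and stock alginate
#'   concentrations (% w/v). Defaults: 1% target from a 3% stock.
#' @param mucin_target_pct,mucin_stock_pct target and stock mucin
#'   concentrations (% w/v). Defaults: 10% stock.
#' @param cacl2_stock_mM crosslinker stock concentration (mM), default 11.
#' @param cacl2_fraction_of_total fraction of the total volume contributed
#'   by the crosslinker solution, default 0.5.
#' @return An object of class `recipe_result`: list with `volumes_ul`
#'   (named: alginate_stock, pbs, mucin_stock, cacl2), `total_ul`, and
#'   `final_cacl2_mM`.
#' @export
recipe <- function(total_volume = 900,
                   alginate_target_pct = 1, alginate_stock_pct = 3,
                   mucin_target_pct = 0, mucin_stock_pct = 10,
                   cacl2_stock_mM = 11, cacl2_fraction_of_total = 0.5) {
  check_scalar(total_volume, "total_volume", lower = 0, strict_lower = TRUE)
  check_scalar(alginate_target_pct, "alginate_target_pct", lower = 0)
  check_scalar(alginate_stock_pct, "alginate_stock_pct", lower = 0, strict_lower = TRUE)
  check_scalar(mucin_target_pct, "mucin_target_pct", lower = 0)
  check_scalar(mucin_stock_pct, "mucin_stock_pct", lower = 0, strict_lower = TRUE)
  check_scalar(cacl2_stock_mM, "cacl2_stock_mM", lower = 0)
  check_scalar(cacl2_fraction_of_total, "cacl2_fraction_of_total",
               lower = 0, upper = 1)
  if (alginate_target_pct > alginate_stock_pct) {
    stop_mucogel("alginate target (%g%%) exceeds its stock (%g%%)",
                 alginate_target_pct, alginate_stock_pct)
  }
  if (mucin_target_pct > mucin_stock_pct) {
    stop_mucogel("mucin target (%g%%) exceeds its stock (%g%%)",
                 mucin_target_pct, mucin_stock_pct)
  }
  v_cacl2 <- round(total_volume * cacl2_fraction_of_total)
  v_alg <- round(total_volume * alginate_target_pct / alginate_stock_pct)
  v_muc <- round(total_volume * mucin_target_pct / mucin_stock_pct)
  v_pbs <- total_volume - v_cacl2 - v_alg - v_muc
  if (v_pbs < 0) {
    # the non-crosslinker half caps the mucin stock volume
    muc_max <- (total_volume - v_cacl2 - v_alg) * mucin_stock_pct / total_volume
    stop_mucogel("infeasible recipe: PBS volume would be %g ul; maximum feasible mucin target is %.2f%%",
                 v_pbs, max(muc_max, 0))
  }
  structure(
    list(volumes_ul = c(alginate_stock = v_alg, pbs = v_pbs,
                        mucin_stock = v_muc, cacl2 = v_cacl2),
         total_ul = v_alg + v_pbs + v_muc + v_cacl2,
         final_cacl2_mM = cacl2_stock_mM * cacl2_fraction_of_total),
    class = "recipe_result"
  )
}

#' @export
print.recipe_result <- function(x, ...) {
  v <- x$volumes_ul
  cat(sprintf("<recipe_result> total %g ul\n", x$total_ul))
  cat(sprintf("  alginate stock: %g ul\n  PBS           : %g ul\n  mucin stock   : %g ul\n  CaCl2 solution: %g ul\n",
              v[["alginate_stock"]], v[["pbs"]], v[["mucin_stock"]], v[["cacl2"]]))
  cat(sprintf("  final CaCl2   : %g mM\n", x$final_cacl2_mM))
  invisible(x)
}

#' Convert a mass concentration to molarity
#'
#' `ug/ml` divided by molar mass in `g/mol` gives `mmol/l` (mM); used for
#' stain bookkeeping (e.g. a nuclear stain at 5 ug/ml with molar mass
#' ~616 g/mol is ~8.1e-3 mM).
#'
#' @param ug_per_ml mass concentration (ug/ml).
#' @param molar_mass_g_mol molar mass (g/mol).
#' @return Concentration in mM.
#' @export
ug_ml_to_mM <- function(ug_per_ml, molar_mass_g_mol) {
  check_scalar(ug_per_ml, "ug_per_ml", lower = 0)
  check_scalar(molar_mass_g_mol, "molar_mass_g_mol", lower = 0, strict_lower = TRUE)
  ug_per_ml / molar_mass_g_mol
}

#' @rdname ug_ml_to_mM
#' @param mM concentration in mM.
#' @export
mM_to_ug_ml <- function(mM, molar_mass_g_mol) {
  check_scalar(mM, "mM", lower = 0)
  check_scalar(molar_mass_g_mol, "molar_mass_g_mol", lower = 0, strict_lower = TRUE)
  mM * molar_mass_g_mol
}
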