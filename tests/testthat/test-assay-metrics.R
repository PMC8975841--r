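# CFU arithmetic, viability, cell counting, loss tangent, LVE region, recipe.

test_that("CFU calculator applies the countable range and per-row arithmetic", {
  # hand oracle: 30 colonies at dilution 1e-5 in 0.02 ml -> 30/(0.02*1e-5)
  t1 <- spot_count_table(5, 0.02, 30)
  r1 <- cfu_per_ml(t1)
  expect_equal(r1$cfu_per_ml, 30 / (0.02 * 1e-5))
  expect_equal(r1$cfu_per_ml, 1.5e8)
  # only the 45-count row falls in 6-60: 45/(0.02*1e-4) = 2.25e7
  t2 <- spot_count_table(c(3, 4, 5), 0.02, c(400, 45, 4))
  r2 <- cfu_per_ml(t2)
  expect_identical(r2$usable_rows, 2L)
  expect_equal(r2$cfu_per_ml, 2.25e7)
  # several usable rows: mean by default, most dilute on request
  t3 <- spot_count_table(c(4, 5), 0.02, c(50, 6))
  expect_equal(cfu_per_ml(t3)$cfu_per_ml,
               mean(c(50 / (0.02 * 1e-4), 6 / (0.02 * 1e-5))))
  expect_equal(cfu_per_ml(t3, mode = "most_dilute")$cfu_per_ml,
               6 / (0.02 * 1e-5))
})

test_that("sterile samples are censored with an explicit detection limit", {
  t0 <- spot_count_table(2:9, 0.02, rep(0, 8))
  r <- cfu_per_ml(t0)
  expect_true(r$censored)
  expect_equal(r$cfu_per_ml, 0)
  expect_equal(r$detection_limit, 6 / (0.02 * 1e-9))
  expect_error(cfu_per_ml(spot_count_table(2, 0.02, 0)[0, ]), "empty")
  expect_error(spot_count_table(2, 0.02, -3), "count")
  expect_error(spot_count_table(2, 0.02, 4.5), "count")
})

test_that("CFU estimate is scale-consistent in counts and range", {
  tab <- spot_count_table(c(3, 4), 0.02, c(30, 3))
  base <- cfu_per_ml(tab, 6, 60)
  tab_k <- spot_count_table(c(3, 4), 0.02, c(300, 30))
  scaled <- cfu_per_ml(tab_k, 60, 600)
  expect_equal(scaled$cfu_per_ml, 10 * base$cfu_per_ml)
})

test_that("simulated counts feed the calculator back to the generating abundance", {
  # Poisson mean at the usable dilution vs analytic expectation, 1000 seeds
  truth <- 1.5e8
  ests <- vapply(1:1000, function(s) {
    tab <- simulate_spot_counts(truth, seed = s)
    r <- cfu_per_ml(tab)
    if (r$censored) NA_real_ else r$cfu_per_ml
  }, numeric(1))
  ests <- ests[is.finite(ests)]
  expect_gt(length(ests), 900)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * se + 0.05 * truth)
})

test_that("viability follows the (total - dead)/total formula and guards inputs", {
  expect_equal(viability(100, 0), 100)
  expect_equal(viability(100, 100), 0)
  expect_equal(viability(250, 50), 80)
  expect_error(viability(0, 0), "total")
  expect_error(viability(100, 150), "exceeds")
})

test_that("viability stays in [0, 100] for random valid inputs", {
  set.seed(42)
  for (i in 1:50) {
    total <- sample(1:10000, 1)
    dead <- sample(0:total, 1)
    v <- viability(total, dead)
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("spot counting finds rendered nuclei and composes with viability", {
  render_spots <- function(centers, shape = c(220, 220), sigma = 2) {
    img <- matrix(0, shape[1], shape[2])
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      img <- img + exp(-((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2) /
                         (2 * sigma^2))
    }
    img
  }
  set.seed(7)
  grid <- as.matrix(expand.grid(row = seq(25, 200, by = 25),
                                col = seq(25, 200, by = 25)))
  centers <- grid[sample(nrow(grid), 50), ] +
    matrix(runif(100, -4, 4), ncol = 2)
  nuclei <- render_spots(centers)
  res0 <- count_cells(nuclei, matrix(0, 220, 220))
  expect_equal(res0$total, 50)
  expect_equal(res0$dead, 0)
  # 25 of the 50 cells also carry a dead stain at the same location
  dead_img <- render_spots(centers[1:25, , drop = FALSE])
  res <- count_cells(nuclei, dead_img)
  expect_equal(res$total, 50)
  expect_equal(res$dead, 25)
  expect_equal(viability(res$total, res$dead), 50)
  # blank images give zero counts and viability is undefined downstream
  blank <- count_cells(matrix(0, 50, 50), matrix(0, 50, 50))
  expect_equal(blank$total, 0)
  expect_error(viability(blank$total, blank$dead), "total")
  expect_error(count_cells(matrix(0, 10, 10), matrix(0, 20, 20)), "shapes")
})

test_that("loss tangent follows G''/G' with nearest-grid and interpolated queries", {
  sw <- simulate_frequency_sweep(200, relaxation_time = 0.5,
                                 omega_grid = 10^seq(-1, 2, length.out = 40))
  lt <- loss_tangent(sw)
  expect_equal(lt$tan_delta, 1 / (sw$omega_rad_s * 0.5), tolerance = 1e-10)
  # ideal elastic: G'' = 0 everywhere
  el <- simulate_frequency_sweep(100, relaxation_time = Inf)
  expect_true(all(loss_tangent(el)$tan_delta == 0))
  # crossover gives exactly 1
  cr <- simulate_frequency_sweep(100, relaxation_time = 1, omega_grid = c(0.5, 1, 2))
  expect_equal(loss_tangent(cr)$tan_delta[2], 1)
  # nearest-grid query within 5%, interpolation opt-in
  q <- loss_tangent(sw, query = sw$omega_rad_s[10] * 1.01)$at_query
  expect_equal(q$tan_delta, 1 / (sw$omega_rad_s[10] * 0.5), tolerance = 1e-10)
  expect_error(loss_tangent(cr, query = 10), "interpolate")
  qi <- loss_tangent(sw, query = 10, match = "interpolate")$at_query
  expect_equal(qi$tan_delta, 1 / (10 * 0.5), tolerance = 0.01)
  # G' = 0 anywhere queried is undefined
  bad <- data.frame(omega_rad_s = 1:3, g_prime_pa = c(1, 0, 1),
                    g_double_prime_pa = c(1, 1, 1))
  expect_error(loss_tangent(bad), "undefined")
})

test_that("loss tangent is invariant to joint modulus rescaling", {
  sw <- simulate_frequency_sweep(200, relaxation_time = 0.5)
  sw2 <- sw
  sw2$g_prime_pa <- sw2$g_prime_pa * 7
  sw2$g_double_prime_pa <- sw2$g_double_prime_pa * 7
  expect_equal(loss_tangent(sw2)$tan_delta, loss_tangent(sw)$tan_delta)
})

test_that("LVE region detection finds the plateau and its 5% departure point", {
  s <- 10^seq(-2, 2, length.out = 41)
  flat <- data.frame(strain_pct = s, g_prime_pa = rep(120, 41))
  r <- lve_region(flat)
  expect_equal(r$strain_max, max(s))
  expect_equal(r$plateau, 120)
  # plateau then power-law decay beyond 10% strain
  g <- ifelse(s <= 10, 100, 100 * (s / 10)^-0.8)
  sweep2 <- data.frame(strain_pct = s, g_prime_pa = g)
  r2 <- lve_region(sweep2, tolerance = 0.05)
  crossing <- max(s[abs(g - r2$plateau) <= 0.05 * r2$plateau])
  idx_cross <- which(s == crossing)
  expect_lte(abs(which(s == r2$strain_max) - idx_cross), 1)
  # monotone decay from the first point has no plateau
  dec <- data.frame(strain_pct = s, g_prime_pa = 100 * s^-0.5)
  expect_error(lve_region(dec), "plateau")
})

test_that("recipe arithmetic reproduces the published formulation volumes", {
  r1 <- recipe(900, mucin_target_pct = 1)
  expect_equal(r1$volumes_ul,
               c(alginate_stock = 300, pbs = 60, mucin_stock = 90, cacl2 = 450))
  expect_equal(r1$total_ul, 900)
  expect_equal(r1$final_cacl2_mM, 5.5)
  r0 <- recipe(900, mucin_target_pct = 0)
  expect_equal(r0$volumes_ul[["pbs"]], 150)
  expect_equal(r0$volumes_ul[["mucin_stock"]], 0)
  rhalf <- recipe(900, mucin_target_pct = 0.5)
  expect_equal(rhalf$volumes_ul[["pbs"]], 105)
  expect_equal(rhalf$volumes_ul[["mucin_stock"]], 45)
  expect_error(recipe(900, mucin_target_pct = 6), "feasible")
  expect_error(recipe(900, alginate_target_pct = 4), "stock")
})

test_that("recipe volumes always sum exactly to the total", {
  set.seed(11)
  for (i in 1:30) {
    tot <- sample(100:2000, 1)
    muc <- runif(1, 0, 1.5)  # feasible range with half the volume crosslinker
    r <- recipe(tot, mucin_target_pct = muc)
    expect_equal(sum(r$volumes_ul), tot)
  }
})

test_that("mass-molarity conversion round-trips", {
  expect_equal(ug_ml_to_mM(5, 616), 5 / 616)
  expect_equal(mM_to_ug_ml(ug_ml_to_mM(5, 616), 616), 5)
})
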