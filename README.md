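# mucogel

Quantitative characterization of engineered alginate–mucin hydrogels used
as mucus mimics in microbial–epithelial co-culture platforms.

Mucus-mimic hydrogels must be characterized along several axes before they
can stand in for native mucus: how fast molecules diffuse through them, how
stable an aqueous two-phase system (ATPS) droplet is on their surface, how
viscoelastic they are, and how many viable bacteria they host. `mucogel`
implements that pipeline as a tested R package:

- **Effective diffusivity.** A fluorescent tracer enters a gel-filled
  channel from a reservoir; the normalized fluorescence profiles follow the
  one-dimensional semi-infinite diffusion solution

  F(x, t) ∝ erfc( x / (2·√(D_eff·t)) ),

  and `fit_erfc()` recovers D_eff (cm²/s) by nonlinear least squares over
  the full space–time profile matrix, with a frame-bootstrap confidence
  interval. `fit_pde()` swaps the closed form for a Crank–Nicolson
  finite-difference forward model, which also handles a depleting (finite)
  reservoir.
- **Droplet geometry.** `segment_droplet()`, `detect_baseline()` and
  `measure_contact_angles()` measure left/right/mean sessile-drop contact
  angles from side-view images by circle fitting (with a local-tangent
  fallback); `circularity()` scores top-view masks by 4πA/P².
- **Assay calculators.** `cfu_per_ml()` applies the single-plate
  serial-dilution spotting countable range (6–60 colonies);
  `viability()`/`count_cells()` compute Live/Dead viability;
  `loss_tangent()` and `lve_region()` summarize oscillatory rheology;
  `recipe()` computes hydrogel component volumes.
- **Synthetic data.** `simulate_diffusion_pde()`, `render_image_stack()`,
  `simulate_droplet_image()`, `simulate_spot_counts()` and
  `simulate_frequency_sweep()` generate every pipeline input with known
  ground truth, so the entire chain is validated by round-trip.

## Worked example

Simulate a diffusion assay at a known D_eff = 5e-7 cm²/s (1 cm channel,
2 mm analysis window at 10 µm/px, 30 frames at 4-minute intervals, 2%
Gaussian noise plus Poisson shot noise), then recover it:

```r
library(mucogel)

cfg   <- diffusion_sim_config(d_true = 5e-7, n_frames = 30, seed = 11)
field <- simulate_diffusion_pde(cfg)
stack <- render_image_stack(field, noise_model(seed = 11), reservoir_px = 40)

prof <- extract_profiles(stack)                      # 2 mm from the interface
ref  <- apply(stack$frames[, 1:39, ], 3, mean)       # reservoir-band reference
m    <- select_frames(normalize_profiles(prof, ref)) # first 30 frames (2 h)
fit_erfc(m, boot_seed = 11)
#> <diffusion_fit> model = erfc
#>   D_eff     : 4.993e-07 cm^2/s  [4.978e-07, 5.008e-07] (bootstrap 95%)
#>   amplitude : 1   offset: 0
#>   RMSE      : 0.009513   R^2: 0.9989   converged: TRUE
```

The estimate (4.99e-7 cm²/s) recovers the generating diffusivity within
0.2%, the 95% bootstrap interval brackets it, and the residual RMSE
(≈0.0095) matches the injected noise floor.

The calculators are one-liners:

```r
recipe(900, mucin_target_pct = 1)
#> <recipe_result> total 900 ul
#>   alginate stock: 300 ul
#>   PBS           : 60 ul
#>   mucin stock   : 90 ul
#>   CaCl2 solution: 450 ul
#>   final CaCl2   : 5.5 mM

cfu_per_ml(spot_count_table(c(3, 4, 5), 0.02, c(400, 45, 4)))
#> <cfu_result> 2.25e+07 CFU/ml from 1 usable row(s)

sw <- simulate_frequency_sweep(100, relaxation_time = 1,
                               omega_grid = c(0.5, 1, 2, 5, 10))
loss_tangent(sw, query = c(1, 10))$at_query
#>   omega_query tan_delta  method
#> 1           1       1.0 nearest
#> 2          10       0.1 nearest
```

Only the 45-colony spot falls in the 6–60 countable range, giving
45 / (0.02 ml × 10⁻⁴) = 2.25e7 CFU/ml; the Maxwell sweep's loss tangent is
1/(ωτ), i.e. 1 at the crossover and 0.1 a decade above.

A command-line wrapper over the same functions ships at
`inst/cli/mucogel.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mucogel.R", package = "mucogel"))')" \
  recipe --total 900 --alg 1 --muc 1 --out run1
```

Subcommands: `simulate`, `diffusion`, `angle`, `cfu`, `rheology`,
`recipe`, `viability`; every run writes CSV results plus a `manifest.json`
with the configuration, seed, package version and input checksums.

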