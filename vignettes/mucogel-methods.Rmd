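---
title: "Methods: diffusivity, droplet geometry and assay calculators for mucus-mimic hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusivity, droplet geometry and assay calculators for mucus-mimic hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucogel)
```

## What this package computes

`mucogel` characterizes engineered alginate–mucin hydrogels used as mucus
mimics in microbial/epithelial co-culture platforms. Four measurements are
covered:

1. **Effective diffusivity** $D_\mathrm{eff}$ (cm²/s) of a fluorescent
   tracer entering a hydrogel-filled channel from a liquid reservoir,
   estimated from time-lapse fluorescence profiles.
2. **Sessile-droplet geometry** — contact angles of dextran-rich droplets of
   a PEG–dextran aqueous two-phase system (ATPS) on the gel surface, and
   top-view circularity — as proxies for interfacial tension and droplet
   stability.
3. **Oscillatory rheology summaries** — the loss tangent
   $\tan\delta = G''/G'$ across a frequency sweep, and the linear
   viscoelastic (LVE) strain region.
4. **Tabular assay calculators** — CFU/ml from single-plate serial-dilution
   spotting (SP-SDS), Live/Dead viability, and hydrogel recipe volumes.

Because no raw imagery is distributed with the package, a synthetic-data
module generates every input with known ground truth; all validation is
round-trip against that ground truth.

## The diffusion model

The channel is a 0.5 mm × 0.5 mm × 10 mm conduit filled with gel, with a
tracer reservoir at one end. Transport is one-dimensional Fickian
diffusion,
$$\frac{\partial C}{\partial t} = D\,\frac{\partial^2 C}{\partial x^2},
\qquad C(x, 0) = 0 \;(x > 0),$$
with $x$ measured in cm from the reservoir–gel interface. If the reservoir
holds the boundary at a constant concentration $c_0$ and the gel is
effectively semi-infinite over the observation window, the solution is
$$C(x, t) = c_0\,\mathrm{erfc}\!\left(\frac{x}{2\sqrt{D t}}\right),$$
so normalized fluorescence profiles $F(x,t)$ are proportional to the
complementary error function. `fit_erfc()` estimates $D_\mathrm{eff}$ by
nonlinear least squares of
$$\hat F(x,t) = A\,\mathrm{erfc}\!\left(\frac{x}{2\sqrt{D t}}\right) + B$$
jointly over every space–time cell. The proportionality is promoted to a
free amplitude $A \in (0, 2]$ by default because imperfect normalization is
the dominant physical nuisance; the background offset $B$ is opt-in (fixed
at 0) because a well-subtracted camera background is the common case. The
loss is unweighted over cells — no principled weighting is available
without a noise calibration, and an optional per-frame weight vector covers
the cases where one is.

### Time origin

Frame $j$ is assigned $t = j \cdot \Delta t$ with $\Delta t$ the frame
interval (default 240 s): imaging starts one interval after tracer loading,
and the erfc argument diverges at $t = 0$, so the model is never evaluated
there. `select_frames()` keeps elapsed times on the acquisition clock when
initial frames are skipped, for the same reason.

### The finite-difference alternative

`fit_pde()` replaces the closed form with a Crank–Nicolson solution of the
diffusion equation on a finite domain (default 5× the profile window), so
the semi-infinite assumption can be checked rather than assumed, and a
**depleting reservoir** can be modeled: a well-mixed compartment of volume
$\rho \times$ (channel volume) whose concentration drops by
(channel mass gain)/$\rho L$ each step. The update is solved implicitly so
reservoir loss equals channel gain to round-off at every step. The
volume ratio $\rho$ is a parameter (default 10) because the effective
reservoir volume of the physical device is not known precisely; the
depleting mode exists to quantify the bias that depletion would induce,
not to match a known value.

Two facts from the package's own simulations are worth knowing:

- Under a constant boundary, `fit_erfc()` and `fit_pde()` agree to ~0.1%
  on the default grid, across $D$ from 1e-8 to 1e-5 cm²/s.
- On depleting-reservoir data ($\rho = 2$) the strict proportionality fit
  ($A = 1$, i.e. trusting the normalization) is biased **low** — depleted
  profiles read as slower diffusion — while `fit_pde(reservoir_mode =
  "depleting")` recovers the truth within a few percent. With the default
  free amplitude, most of the depletion is absorbed into $A$ and the
  residual bias is small and slightly positive. If you suspect depletion,
  fit the PDE model; do not rely on $A$ to launder a boundary-condition
  error.

### Numerical choices

- **Scheme**: Crank–Nicolson (second order in space and time,
  unconditionally stable), Dirichlet at the reservoir, zero-flux at the far
  end, tridiagonal systems solved by the Thomas algorithm with precomputed
  elimination coefficients. The internal step is capped at a diffusion
  number $D\,\Delta t/\Delta x^2 \le 2$ — an accuracy choice, not a
  stability requirement. Against the analytic solution the solver is
  accurate to ~5e-5 · $c_0$ in $L_\infty$ at $\Delta x = L/1000$.
- **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm`) on
  $\log_{10} D$, with up to 5 restarts from jittered initial guesses; all
  MINPACK success codes (1–4) count as convergence. A matrix with no
  spatial structure (constant $F$) is flagged `converged = FALSE` because
  $D$ is unidentifiable.
- **Initial guess**: per-frame half-maximum crossing depths inverted
  through $\mathrm{erfc}(z) = 1/2$ at $z \approx 0.4769$, median over
  frames; fallback 1e-7 cm²/s (typical macromolecule-in-hydrogel scale)
  when no crossing exists.
- **Uncertainty**: percentile bootstrap over **frames** (200 replicates,
  seeded). Axial pixels within a frame are strongly correlated, so
  pixel-level resampling would be anticonservative. At 1–2% noise the
  nominal 95% interval covers the generating value in ≳90% of simulated
  datasets.
- **Reference guard**: frames whose reservoir reference drifts more than
  20% from the first frame are excluded with a warning (bleaching or
  evaporation), before fitting.

## What the synthetic generator emulates — and what it does not

`simulate_diffusion_pde()` + `render_image_stack()` emulate the study
conditions: a 1 cm channel, 2 mm analysis window at 10 µm/px, frames every
240 s, 30 analysis frames (2 h), tracer entering from a reservoir at the
left. The noise model applies Poisson shot noise at 100 photons per
concentration unit, additive Gaussian noise at 2% of $c_0$, and optional
first-order photobleaching (off by default) — representative benchtop
epifluorescence statistics.

Deliberately **not** modeled: optical blur (PSF), vignetting and other
fixed-pattern nonuniformity, gel autofluorescence, tracer–mucin binding,
2-D/3-D transport and convection, and focus drift. Passing the round-trip
tests therefore shows the estimator chain is correct and noise-robust under
the stated statistics; it does not certify performance against optical
artifacts a real microscope can add. The same applies to the droplet
renderer (ideal circular-segment caps on a horizontal substrate) and the
Maxwell-model frequency sweeps (single relaxation mode plus optional
elastic plateau — real mucus shows a relaxation spectrum).

One consequence of the clean rendering worth noting: at 2% Gaussian image
noise, Otsu thresholding separates droplet from background essentially
noise-free, so contact-angle errors are dominated by rasterization bias
(~0.2° mean absolute error) and barely vary between noise realizations.

## Droplet geometry

Contact angles are measured through the droplet phase (sessile-drop
convention). The default method fits a circle (algebraic Kasa fit) to the
contour above the detected baseline: small ATPS droplets are near-spherical
caps, and the interior angle follows from the center height $z_c$ via
$z_c = -R\cos\theta$. The `polynomial_tangent` method — a local quadratic
at each contact point — is retained for irregular droplets and as the
automatic fallback for degenerate circle fits; it is reliable only for
shallow caps (slopes representable as a function of $x$). Auto baseline
detection requires a flat bottom run; tilted substrates are a documented
error (`fixed_row` is the escape hatch), never a silent misfit.

Circularity is $4\pi A / P^2$ with the perimeter taken from the
Gaussian-smoothed contour ($\sigma = 2$ contour points): raw pixel-edge
perimeters overestimate by up to ~11%, which would bias circularity low. A
rasterized disc scores ~1.00, a square ~$\pi/4$, a 2:1 ellipse ~0.84.

## Assay calculators

- **CFU (SP-SDS)**: only spots with 6–60 colonies are countable; each
  usable row converts as $\mathrm{count}/(V_\mathrm{spot} \cdot 10^{-e})$.
  When several dilutions are usable their estimates are **averaged** (the
  cited protocol leaves this open; a `most_dilute` mode is available).
  Sterile tables are reported as censored with an explicit detection limit
  at the most dilute plated spot rather than a silent zero.
- **Viability**: $100\,(N_\mathrm{total} - N_\mathrm{dead})/N_\mathrm{total}$,
  with a minimal difference-of-Gaussians spot counter (`count_cells()`) to
  produce the two counts from stained image pairs.
- **Loss tangent**: $G''/G'$ per frequency; query frequencies (e.g. the 1
  and 10 rad/s comparisons) are answered by the nearest grid point within
  5% — mirroring how instrument grids are read at nominal frequencies —
  with log-frequency interpolation opt-in.
- **LVE region**: plateau = median $G'$ over the lowest decade of strain;
  region = maximal initial run within 5% of the plateau.
- **Recipe**: volumes in integer µl with the rounding remainder assigned to
  PBS so components sum exactly to the total; the crosslinker solution is
  half the total volume, so an 11 mM CaCl₂ stock yields 5.5 mM final.

## Validation problem sizes

The shipped tests and the acceptance script use: 30 × 200 profile matrices
(30 frames, 2 mm at 10 µm/px); 100 noise seeds for the noisy-recovery study
and 30 for bootstrap coverage; $\Delta x = L/1000$ for the solver-vs-analytic
comparison; 20 seeds per angle at θ ∈ {30, 60, 90, 120}°; 1000 seeds for
the Poisson spot-count check. These sizes give stable statistics for every
tolerance asserted while keeping a full validation run in minutes on one
core.

## Known limitations

- One-dimensional transport only; lateral averaging across the channel
  width assumes a flat transverse profile (the central 60% band default
  avoids wall artifacts but cannot correct genuine 2-D effects).
- The erfc model assumes a semi-infinite gel; for long times or short
  channels use `fit_pde()`, which is ~200× slower per fit.
- Auto interface/baseline detection assumes the geometry it is documented
  for (bright reservoir left, flat substrate); both accept manual
  overrides, and the override always wins.
- The spot counter is a minimal stand-in for dedicated cell-counting
  software: it assumes roughly isotropic, non-clumped spots at a known
  scale.
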