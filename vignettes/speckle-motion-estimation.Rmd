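---
title: "Smoothness-regularized block matching for speckle tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothness-regularized block matching for speckle tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklemotion)
```

## The problem

B-mode ultrasound renders tissue echo amplitude as a granular interference
texture — speckle.  Speckle moves with the tissue, which makes it a usable
tracking target, but it also decorrelates from frame to frame and gives the
images a low signal-to-noise character that defeats methods relying on
strict intensity constancy.  `specklemotion` estimates a dense displacement
field over a region of interest (ROI) by block matching: for each pixel,
find the displacement `u = (ux, uy)` that makes the block around the pixel
in the current frame most similar to the displaced block in the previous
frame.

Two estimators share one objective:

* **IFSA** (iterative full search): at every pixel, every sweep, evaluate
  all `(2W+1)^2` integer displacements and keep the best.  Deterministic,
  expensive, and the quality reference.
* **IFA** (iterative firefly algorithm): at every pixel maintain a small
  swarm of `m` candidate displacements ("fireflies") whose brightness is
  the matching fitness; per sweep each firefly takes one update step.
  Stochastic, and roughly 2.5x cheaper per run in fitness evaluations at
  the default operating point while matching IFSA's recovery on phantoms.

## The matching model

The similarity term is the block mean square error between the current
frame `f_k` and the reference frame `f_(k-1)`:

$$\mathrm{MSE}(u) = \frac{1}{n^2} \sum_{(dx,dy)}
  \left[f_k(x+dx,\,y+dy) - f_{k-1}(x+u_x+dx,\,y+u_y+dy)\right]^2$$

with `n x n` blocks and displacements constrained to `[-W, W]` per
component.  Pure MSE matching is brittle on speckle, so a smoothness
constraint couples each pixel to its 8-connected neighbors' vectors from
the *previous* iteration `t - 1`:

$$\mathrm{SC}(u^t) = \frac{1}{|N|} \sum_{i \in N}
  \left[(u^t_x - u^{t-1}_{i,x})^2 + (u^t_y - u^{t-1}_{i,y})^2\right]$$

Both components of the vector difference enter the penalty; the divisor is
the number of *available* neighbors (fewer than 8 at ROI borders), which
keeps the penalty scale comparable across the ROI.  An empty neighbor set
yields 0.  The combined fitness, maximized by both estimators, is

$$\mathrm{fitness}(u^t) = \frac{1}{1 + \mathrm{MSE}(u^t) +
  \lambda\,\mathrm{SC}(u^t)} \in (0, 1]$$

which equals 1 exactly for a perfect match in a locally uniform field and
is strictly decreasing in both terms.

Because SC references the previous iteration, field estimation is
iterative: each global iteration performs one synchronous (Jacobi) sweep in
which every ROI pixel is updated against the `t - 1` field, so the update
order of pixels cannot influence the result.  The field is initialized
with uniform random integer vectors on `[-W, W]^2`.

## The firefly update

Each pixel's swarm holds `m` continuous positions in `[-W, W]^2`.
Brightness is the fitness at the *rounded* (half-away-from-zero), clamped
position — the matching model indexes pixels, and no interpolation scheme
is imposed on the data.  Per sweep:

1. every firefly's brightness is refreshed against the current neighbor
   field (`m` evaluations);
2. each non-brightest firefly `i` picks a uniformly random partner `j`;
   if `j` is brighter, `i` moves by the convex combination
   `(1 - beta) x_i + beta x_j` plus a per-component uniform walk in
   `(-0.5, 0.5)`, where `beta = min(1, beta0 * exp(-gamma * r))` with
   `r = ||x_i - x_j||` and `beta0` the *sum* of the two brightness values;
3. the brightest firefly performs the same walk greedily, keeping the new
   position only on strict improvement;
4. the best evaluated (rounded) position ever seen at this pixel —
   `u_BestCu` — is recorded with its fitness; this elite record is
   monotone non-decreasing and is what the output field reports.

The clamp on `beta` is needed because the sum of two brightness values can
exceed 1, which would otherwise turn the convex combination into an
extrapolation beyond the two fireflies.

### Swarm re-initialization (a deliberate design choice)

Whether the `m` positions persist across global sweeps or are redrawn each
sweep is genuinely open: the update loop reads either way.  We implemented
both (`persist_swarms` in `search_config()`) and measured them on
noiseless translation phantoms with known ground truth.  Persistent swarms
collapse onto whatever the early sweeps found: with brightness values of
order `1/MSE` (about `1e-3` on speckle away from the optimum), the
attraction factor `beta0 * exp(-gamma * r)` is numerically negligible, so
the only exploration left is the `±0.5` walks — a diffusion of roughly 3
pixels over 200 sweeps, far too slow to scan a 15 x 15 window.  Redrawing
positions each sweep gives the search a stochastic-restart character while
the elite record and the smoothness recursion still carry information
across sweeps; on the same phantom it recovers essentially every pixel
(the test suite verifies both the superiority of re-initialization and
the ≥ 95% recovery).  Re-initialization is therefore the default;
persistence remains available for study.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `block_size` (n) | block side, pixels (odd) | 7 | enough texture to disambiguate speckle without smearing motion boundaries |
| `search_width` (W) | max displacement per component, pixels | 7 | a 15 x 15 window, 225 integer candidates |
| `lambda` | smoothness weight, dimensionless | 1.0 | final quality is insensitive over a broad range; 1.0 balances intensity² MSE against pixel² SC on 8-bit data |
| `gamma` | attractiveness decay, 1/pixels | 1.0 | attraction fades over a few pixels of displacement space |
| `swarm_size` (m) | fireflies per pixel | 5 | « 225 candidates — the point of the swarm search |
| `iterations` (l) | global Jacobi sweeps | 200 | the swarm needs ~200 sweeps to saturate recovery; IFSA converges in ~20 |
| `seed` | RNG seed | 1 | every stochastic run is reproducible bit-exactly |

Random draws come from R's stream in a fixed documented order (field
initialization pixel-major, then swarm draws pixel-major/firefly-major per
sweep), so a seed fully determines a run.  IFSA consumes only the field
initialization; on phantoms where it converges its output is independent
of the seed.

## Evaluation metrics

Quality is measured by motion compensation: predict the current ROI from
the reference frame via the estimated field, and report
`PSNR = 10 log10(255² / MSE)` in dB.  An exact compensation (MSE 0) is
reported as `+Inf`; when comparing near-exact reconstructions we cap PSNR
at the 8-bit quantization noise floor `psnr(1/12) ≈ 58.9 dB`, below which
differences are not meaningful for integer data.  The PSNR degradation
ratio `D_PSNR = (PSNR_ref - PSNR_test)/PSNR_ref x 100%` compares the swarm
against the exhaustive baseline; it is 0 by convention when both
compensations are exact, and it is ill-conditioned when the reference is
exact and the test is not — a 2-pixel error out of 625 can produce a
double-digit `D_PSNR` against an exact reference, which says more about
the metric than about the field.  Efficiency is compared by
fitness-evaluation counts (each fitness computation increments a counter
exactly once), summarized as the computation-saving ratio
`CSR = (cost_ref - cost_test)/cost_ref x 100%`; counts are
hardware-independent, unlike wall-clock times.  Ground-truth comparisons
on phantoms additionally report the mean endpoint error and the fraction
of exactly recovered vectors.

## The synthetic phantom

`generate_sequence()` emulates the two degradations that make ultrasound
tracking hard: correlated speckle texture and temporal decorrelation.  A
real-valued white-noise scatterer grid is smoothed with an isotropic
Gaussian of standard deviation `psf_sigma` (default 2 px — a speckle cell
of a few pixels), the magnitude envelope is taken, rescaled to `[0, 255]`
with one fixed scale per sequence, and quantized to 8 bits.  Motion
(uniform translation, affine, or sinusoidal shear) warps the scatterer
field; for integer translations the frames are exact crops of one rendered
grid, so the true displacement attains block MSE exactly 0 — the sharpest
possible oracle.  Independent zero-mean Gaussian noise of scale
`decorrelation_noise_sigma` is then added per frame and re-quantized.
Truth fields use the backward convention (the vector at a pixel of frame
`k` points to its source in frame `k - 1`), directly comparable to
estimator output; for non-integer motion the truth is continuous and its
rounded version is approximate.

What the phantom does *not* emulate: anisotropic point-spread functions,
depth-dependent attenuation and focusing, scan conversion geometry,
out-of-plane motion, or physically modeled RF speckle.  Passing tests on
phantoms therefore demonstrate correctness of the estimator mathematics
and robustness to the modeled degradations — not clinical performance on
in-vivo sequences.

## Numerical choices

* Replicate (edge-clamp) padding wherever a block or a displaced read
  leaves the frame: keeps MSE defined everywhere without biasing toward
  zero intensity.
* Continuous positions are rounded half-away-from-zero before evaluation
  (base R's `round()` rounds half to even, which would bias the search
  grid).
* IFSA ties break to the first maximizer in row-major `(uy, ux)` scan
  order from `(-W, -W)` — deterministic and documented.
* The comparison of an `m x 2` swarm against `(2W+1)^2` candidates is
  guarded: `swarm_size` may not exceed the candidate count.
* Degenerate inputs: an all-zero scatterer grid renders a constant frame;
  an empty neighbor set yields SC 0; `psnr(0)` is `+Inf` by convention.

## Problem sizes used by the test suite

The suite validates on sizes chosen to exercise every code path while
keeping runs small: 32-64 px frames, 6 x 6 to 25 x 25 ROIs, 10-20 seeds
per stochastic property, and the full default operating point (25 x 25
ROI, W = 7, m = 5, l = 200) for the headline recovery checks.  The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch at those sizes.

## Known limitations

* Matching is integer-resolution; no subpixel interpolation is offered,
  so sub-pixel tissue motion rounds to the nearest pixel.
* The smoothness recursion assumes the ROI is meaningful as a coupled
  field; disjoint moving structures inside one ROI will be smoothed
  across their boundary.
* `D_PSNR` against an exact reference is degenerate (see above); prefer
  endpoint error on phantoms where ground truth is available.
* Wall-clock comparisons are intentionally out of scope; evaluation
  counts are the supported efficiency measure.
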