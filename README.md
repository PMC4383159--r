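# specklemotion

Dense block-matching motion estimation for speckle-corrupted grayscale
image sequences — the B-mode ultrasound setting, where granular speckle
texture moves with the tissue but decorrelates over time and defeats
methods that assume intensity constancy.  The package is aimed at people
studying tissue-motion estimators: it provides the estimators themselves,
a ground-truth phantom generator to validate them, and the standard
quality/efficiency metrics to compare them.

## The method

For each pixel of a region of interest (ROI), the displacement
`u = (u_x, u_y)`, `|u_x|, |u_y| ≤ W`, is chosen to maximize a
smoothness-regularized matching fitness between consecutive frames
`f_{k-1}` and `f_k`:

```
MSE(u)  = (1/n²) Σ [ f_k(x+dx, y+dy) − f_{k−1}(x+u_x+dx, y+u_y+dy) ]²
SC(uᵗ)  = (1/|N|) Σ_{i∈N} [ (uᵗ_x − u^{t−1}_{i,x})² + (uᵗ_y − u^{t−1}_{i,y})² ]
fitness = 1 / (1 + MSE + λ·SC)
```

with `n × n` blocks, the 8-connected neighbor vectors `u^{t−1}_i` taken
from the previous iteration (so the field is estimated by synchronous
Jacobi sweeps), and λ weighting spatial continuity against similarity.
Two estimators maximize this fitness:

* **IFSA** — iterative full search: every sweep evaluates all `(2W+1)²`
  integer displacements per pixel.  Deterministic reference.
* **IFA** — iterative firefly algorithm: per pixel a swarm of `m`
  candidate displacements whose brightness is the fitness; dimmer
  fireflies move toward brighter ones by
  `x_i ← (1−β)x_i + βx_j + w`, `β = min(1, β₀ e^{−γr})`, `r = ‖x_i−x_j‖`,
  with uniform walks `w ∈ (−0.5, 0.5)²`, the brightest firefly walking
  greedily, and the best-ever evaluated vector (`u_BestCu`) reported.

Quality is measured by motion-compensated `PSNR = 10·log₁₀(255²/MSE)`,
the PSNR degradation ratio
`D_PSNR = (PSNR_IFSA − PSNR_IFA)/PSNR_IFSA × 100%`, and efficiency by
fitness-evaluation counts summarized as a computation-saving ratio
`CSR = (cost_IFSA − cost_IFA)/cost_IFSA × 100%`.

See `vignettes/speckle-motion-estimation.Rmd` for the full model,
parameter rationale, and design decisions.

## Worked example

Generate a noiseless speckle phantom translating by (2, 1) px/frame,
estimate the field with the firefly swarm at the default operating point
(`n = 7`, `W = 7`, `λ = 1`, `γ = 1`, `m = 5`, `l = 200`), and check it
against the known truth:

```r
library(specklemotion)

ph  <- generate_sequence(phantom_config(64, 64, motion_translation(2, 1),
                                        seed = 42))
r   <- roi(20, 20, 25, 25)
res <- estimate_field(ph$sequence, 2, r, search_config(seed = 1),
                      method = "ifa")
res
#> estimation_result (ifa): 25 x 25 field, 200 iterations, 1063791 fitness evaluations

tru <- ph$truth[[1]]
endpoint_error(res$field,
               motion_field(tru$ux[r$y + 1:25, r$x + 1:25],
                            tru$uy[r$y + 1:25, r$x + 1:25], r))
#> $mean_error
#> [1] 0
#> $exact_fraction
#> [1] 1
```

Every one of the 625 vectors equals the ground truth, at a cost of about
1.06M fitness evaluations — versus `625 × 225 × 20 = 2.81M` for the
exhaustive baseline run to its usual 20 sweeps.  The side-by-side report:

```r
compare_methods(ph$sequence, 2,
                list(roi(16, 16, 15, 15), roi(30, 28, 15, 15)),
                search_config(seed = 1), ifsa_iterations = 20)
#>       roi mse_ifsa psnr_ifsa mse_ifa psnr_ifa d_psnr_percent evals_ifsa evals_ifa csr_percent
#> 1   ROI 1        0       Inf       0      Inf              0    1012500    382813       62.19
#> 2   ROI 2        0       Inf       0      Inf              0    1012500    382847       62.19
#> 3 average        0       Inf       0      Inf              0    1012500    382830       62.19
```

Both estimators compensate the noiseless phantom perfectly (MSE 0, PSNR
reported as `Inf`), the degradation ratio is 0, and the swarm saves ~62%
of the fitness evaluations.

The same workflow is available from a shell via the bundled entry point:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "specklemotion.R", package = "specklemotion"))')
Rscript "$CLI" simulate --size 64x64 --motion translation:2,1 --seed 42 --out phantom/
Rscript "$CLI" estimate --frames phantom/ --roi 20,20,25,25 --method ifa --seed 1 --out run/
Rscript "$CLI" compare  --frames phantom/ --roi 16,16,15,15 --roi 30,28,15,15 --seed 1 --out cmp/
```

Each run writes a `config.yaml` echo with all parameters and the seed,
sufficient to reproduce it bit-exactly.

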