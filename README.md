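# sfdiops

Optical-property estimation for two-frequency spatial frequency domain
imaging (SFDI) of turbid media.

SFDI projects sinusoidal light patterns onto a scattering sample and
measures how strongly the modulation is attenuated in the remitted
light. For a homogeneous, semi-infinite medium the calibrated diffuse
reflectance at a planar spatial frequency, `R0`, and at one modulated
frequency, `Rn` (here `fn = 0.2 mm⁻¹`), maps one-to-one onto the
absorption coefficient `μa` and the reduced scattering coefficient `μs′`
(both mm⁻¹). This package implements the full estimation stack for that
two-frequency scheme, aimed at quantitative wide-field tissue imaging:

* **Forward models.** A white (scattering-only) Monte-Carlo photon
  transport kernel for a semi-infinite medium with Fresnel boundaries
  (`run_white_mc()`), re-weighted by `exp(−μa·L)` and similarity-rescaled
  so one simulation serves every property pair, then tabulated for fast
  bulk evaluation (`sfdi_forward()`); and the closed-form diffusion
  approximation
  `Rd = 3A a′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A))`
  with `μtr = μa + μs′`, `a′ = μs′/μtr`,
  `μeff′ = sqrt(3 μa μtr + (2π fx)²)` (`diffusion_rd()`).
* **Processing.** Exact three-phase demodulation
  `A = √2/3 · sqrt((I1−I2)² + (I2−I3)² + (I3−I1)²)` and
  reference-phantom calibration `R = A/A_ref · R_ref`
  (`demodulate_ac()`, `demodulate_dc()`, `calibrate()`).
* **Inversion.** Four back-ends behind one `predict(model, R0, Rn)`
  interface (`sfdi_inverse()`): dense 1000×1000 and low-resolution
  100×100 Monte-Carlo lookup tables with exact-at-node inverse bilinear
  interpolation, diffusion-model root finding, and a random-forest
  regressor (15 trees, minimum leaf 2) trained on simulated data —
  megapixel property maps in seconds.
* **Synthetic scenes.** A generator for piecewise-homogeneous phantom
  scenes under structured illumination with camera noise
  (`scene_spec()`, `render_scene()`), and an end-to-end pipeline
  (`run_pipeline()`) producing per-pixel `μa`/`μs′` maps with status
  flags and per-region statistics.

## Worked example

Simulate the forward model, train an inverse, and process a synthetic
six-phantom scene end-to-end:

```r
library(sfdiops)

cfg  <- mc_config(n_photons = 2e5, seed = 7)   # 1e7 for production tables
hist <- run_white_mc(cfg)
hist
#> Monte-Carlo exit-weight histogram
#>   launched: 200000   exited: 181147   absorbed/lost: 18853
#>   bins: 5000 radial x 4000 path   mu_s = 10 mm^-1 (g = 0.9)

fwd <- sfdi_forward(hist)
reflectance(fwd, 0.0117, 1.0827, c(0, 0.2))   # calibration phantom
#> [1] 0.6003411 0.1077474

model <- sfdi_inverse(fwd, method = "rfr", n_train = 2e5,
                      training_seed = 11, seed = 12)

sp    <- six_phantom_scene()                   # mu_a 0.0135..0.0437 mm^-1
scene <- render_scene(sp, fwd)
ref   <- render_scene(scene_spec(shape = sp$shape), fwd)
regions <- lapply(sp$regions, function(r) list(rows = r$rows, cols = r$cols))
names(regions) <- vapply(sp$regions, `[[`, "", "name")

out <- run_pipeline(list(sample = scene$stack_fn, reference = ref$stack_fn,
                         model = model, forward = fwd, regions = regions))
out$report[, c("region", "mean_mu_a", "mean_mu_s_prime")]
#>     region mean_mu_a mean_mu_s_prime
#> 1 phantom1    0.0145           0.989
#> 2 phantom2    0.0181           1.065
#> 3 phantom3    0.0262           1.126
#> 4 phantom4    0.0324           1.189
#> 5 phantom5    0.0366           1.254
#> 6 phantom6    0.0448           1.322
```

The recovered patch means track the true patch properties
(`μa` 0.0135–0.0437, `μs′` 0.982–1.326 mm⁻¹); at this reduced training
scale the forest resolves `μa` to a few 10⁻³ mm⁻¹. Accuracy on an
independent simulated test set:

```r
test <- generate_training_set(fwd, 1e5, seed = 21)
mean_relative_error(predict(model, test$R0, test$Rn), test)
#> Mean relative error: mu_a 0.7188% (n = 99942, 0.06% excluded below 0.001), mu_s' 0.5913% (n = 100000)
```

The absorption metric excludes true `μa < 1e−3 mm⁻¹`, where a relative
error is undefined; the excluded fraction is always reported.

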