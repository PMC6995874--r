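---
title: "Estimating optical properties from two-frequency SFDI: models, inversion back-ends and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating optical properties from two-frequency SFDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spatial frequency domain imaging (SFDI) projects sinusoidal intensity
patterns onto a turbid sample and measures how strongly the pattern is
attenuated in the remitted light. A scattering-dominated medium acts as a
low-pass filter in spatial frequency, and the attenuation carries enough
information to separate absorption from scattering: the calibrated diffuse
reflectance at a planar frequency, `R0`, and at one modulated frequency,
`Rn` (here `fn = 0.2` mm⁻¹), determines the absorption coefficient `μa`
and the reduced scattering coefficient `μs′` of a homogeneous,
semi-infinite medium through a one-to-one nonlinear mapping.

`sfdiops` implements the whole chain for this two-frequency scheme:

1. a **white Monte-Carlo forward model** of diffuse reflectance,
2. the **closed-form diffusion approximation** as an analytic baseline,
3. **three-phase demodulation** and **reference-phantom calibration** of
   raw structured-illumination image stacks,
4. four **inversion back-ends** mapping `(R0, Rn) → (μa, μs′)`: a dense
   (1000×1000) and a low-resolution (100×100) lookup table, diffusion
   root-finding, and a random-forest regressor trained on simulated data,
5. a **synthetic scene generator** standing in for phantom and in-vivo
   acquisitions, and a per-pixel processing pipeline.

## The white Monte-Carlo forward model

A pencil beam enters a semi-infinite homogeneous medium (refractive index
1.43 against 1.0 outside) at the origin. Photons random-walk with
scattering coefficient `μs = μs′/(1−g)` and Henyey–Greenstein anisotropy
`g`, and the unpolarized Fresnel coefficient decides reflection or escape
at every boundary encounter. The walk is *scattering-only*: absorption is
applied afterwards by weighting each recorded exit event with
`exp(−μa·L)` over its total path length `L`, and a single reference run at
`μs′ = 1` mm⁻¹ serves every property pair through similarity rescaling of
all lengths by `μs′_ref/μs′`. One simulation therefore supports the
millions of forward evaluations needed for lookup tables and training
sets.

Exit weight is binned by exit radius and path length. Two tabulated
kernels collapse this histogram into the function actually queried,

    G(α, φ) = Σ_{r,l} W[r,l] · exp-avg(−α l) · J0-avg(2π φ r),

with `α = μa·scale` and `φ = fx·scale` both measured in the reference
frame. The modulated reflectance is the zero-order Hankel transform of
the radial profile; `G(α, 0)` is the planar reflectance. `G` is stored on
grids uniform in `log1p(α)` and `log1p(φ)` (defaults 512 × 384) and
queried by bilinear interpolation; the `mc_forward()` route evaluates the
same sums directly without tabulation and is used as the internal
cross-check.

Numerical choices worth recording:

* **Bin-averaged kernels.** The absorption factor and the Bessel kernel
  are averaged analytically over each bin (`sinh(αh/2)/(αh/2)` and the
  `r J1` primitive) instead of evaluated at bin centres. Midpoint
  quadrature would bias the reflectance by a factor `sinh(αh/2)/(αh/2)`
  (17% at `αh = 2`); the averaged kernels remove that bias at identical
  cost, which is why the default bins (0.02 mm radial, 0.25 mm path) can
  stay coarse enough to keep the histogram near 160 MB.
* **Exact conservation.** Every termination books its weight into an
  `absorbed_or_lost` ledger (including continuously absorbed weight and
  the weight created/destroyed by Russian roulette), so
  `launched = exited + lost` holds to floating-point rounding — the test
  suite asserts `< 1e−9` relative.
* **Exact early termination.** A photon needs at least its current depth
  in remaining path to regain the surface, so any photon with
  `z > max_path − path` is terminated immediately. This prunes the deep
  random-walk tail without approximation (≈3× faster at `g = 0.9`).
* **Path truncation.** `max_path` defaults to 1000 mm in the reference
  frame. With zero absorption ~9% of the launched weight is still inside
  at that point, so `Rd(0; μa = 0)` saturates near 0.91 rather than 1;
  for `μa ≳ 0.005` mm⁻¹ the truncated tail is absorbed anyway and the
  effect is negligible. All inversion benchmarks are self-consistent
  (the same forward model generates and inverts the data), so this
  truncation does not bias them.
* **RNG.** The kernel uses its own xoshiro256++ generator seeded from
  `mc_config(seed=)`; runs are bit-for-bit reproducible and independent
  of R's RNG state.

**Anisotropy.** The two-frequency workflow does not itself fix `g`; we default to
`g = 0.9`, typical of tissue. Similarity scaling makes the planar
reflectance insensitive to `g` (measured < 0.3% between `g = 0.7` and
`0.95`), but at `fx = 0.2` mm⁻¹ the phase function is *not* fully
absorbed by `μs′`: we measure ~8% variation of `Rd(0.2)` across the
tissue-realistic range and ~45% against an isotropic walk. The tests
therefore assert the weaker, true property over `g ∈ [0.7, 0.95]`, and
`g` is exposed in `mc_config()` so users can match their tissue.

## The diffusion baseline

With `μtr = μa + μs′`, `a′ = μs′/μtr`, `k = 2π fx` and
`μeff′ = sqrt(3 μa μtr + k²)`,

    Rd = 3A a′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A)),

where `A = (1 − R_eff)/(2(1 + R_eff))` and
`R_eff ≈ 0.0636 n + 0.668 + 0.710/n − 1.440/n²` (0.5513 at `n = 1.43`).
At `μa = 0, fx = 0` the expression collapses to exactly 1.

Inversion exploits a nested monotone structure instead of 2-D root
finding: at `fx = 0` the reflectance depends on the albedo `a′` alone, so
`R0` fixes `a′` by a bracketed one-dimensional root; `Rn` then fixes
`μtr` (monotone at fixed `a′`). Round-trips close to below 1e−6 mm⁻¹,
and degenerate pixels (`Rn ≥ R0`, values outside `(0,1)`) are flagged
rather than raised, since megapixel maps always contain out-of-model
pixels.

Against the Monte-Carlo model the diffusion approximation behaves as
expected for `g = 0.9`: within ~1% at `fx = 0` and within 15% at
`fx = 0.2` for diffusive-regime points (`μs′/μa ≥ 100`), degrading as
`fx/μtr` grows. Feeding Monte-Carlo reflectance into the diffusion
inverse underestimates `μa` by roughly 10–20% and `μs′` by 5–12% in that
regime — the characteristic bias of the diffusion baseline, asserted as a
characterization test.

## Demodulation and calibration

For phases spaced `2π/3`,

    A  = √2/3 · sqrt((I1−I2)² + (I2−I3)² + (I3−I1)²)
    A0 = (I1 + I2 + I3)/3

are exact for ideal sinusoidal illumination — the AC formula is invariant
to the global pattern phase, and the DC mean cancels the sinusoid
exactly. By default the planar amplitude is taken from the *modulated*
stack's phase mean, so a single three-phase acquisition yields both
channels; a separately rendered planar stack is also supported.

Calibration converts amplitudes to absolute reflectance through a
reference phantom with known properties
(`R = A/A_ref · R_ref`, with `R_ref` forward-modelled at the phantom's
`μa = 0.0117`, `μs′ = 1.0827` mm⁻¹). Camera gain and illumination
amplitude cancel in the ratio — asserted as a scale-invariance property.
Pixels with reference amplitude below `1e−6` of its maximum are flagged
invalid; calibrated reflectance outside `[0, 1]` is flagged but *not*
clamped, leaving the out-of-domain policy to the inversion stage.

## Inversion back-ends

All four back-ends share `predict(model, R0, Rn)` returning `μa`, `μs′`
and a per-pixel status (0 ok, 1 out-of-domain, 2 invalid input).

**Lookup tables** are built on uniform grids over
`μa ∈ [0, 2] × μs′ ∈ [0.01, 15]` mm⁻¹. Inverse bilinear interpolation
runs in continuous grid coordinates: the admissible `μa` interval for a
given `R0` is found by bisecting the table's two monotone edge profiles,
`b(a)` along a row is an exact linear solve, and the remaining `Rn`
residual is bisected. Grid nodes are recovered exactly (to ~1e−12 of a
cell), off-manifold queries return the nearest clamped solution plus an
out-of-domain flag, and a megapixel map inverts in seconds.

**The random-forest inverse** is trained on property pairs sampled
uniformly over the domain with forward reflectances attached (production-scale
default 10⁶ pairs). Hyperparameters follow the recorded configuration: 15
trees, minimum terminal node size 2, both features available at every
split, bootstrap resampling, single-threaded and seeded. Because no
installed R learner offers joint multi-output forests, one forest is
fitted per target; we verified on identical data that this matches the
reference multi-output implementation for `μs′` (0.583% vs 0.586% at
2×10⁵ training pairs) and is *more* accurate for `μa` (0.70% vs 0.95%),
since joint splits are dominated by the larger-variance `μs′` target.

**Error metric.** Mean relative error in percent, per parameter. The
sampled domain includes `μa = 0`, where relative error diverges; samples
with true `μa < 1e−3` mm⁻¹ (≈0.05% of a uniform draw) are excluded from
the absorption metric and the excluded fraction is reported. This floor
moves the headline `μa` numbers and is therefore configurable and
prominently reported. No floor is applied to `μs′`; as a consequence the
`μs′` metrics are dominated by the rare `μs′ < 0.2` mm⁻¹ corner, where
relative grid cells are huge — e.g. the low-resolution table's μs′ error
is ~10% inside that corner and ~0.02% elsewhere.

At the full 10⁶/10⁶ scale (2×10⁶ photons, seed 1) the package reproduces
the expected structure of the error table: the dense table is the most
accurate (≈0.02%/0.01%), the forest is intermediate (≈0.3%/0.24%), and
the low-resolution table trades accuracy for memory (≈0.5%/0.16%), with
the dense-vs-low μa ratio ≈ 26×. These numbers are recomputed from
scratch by `scripts/acceptance.R`; the unit-test suite demonstrates the
same structure at 2×10⁵/10⁵ scale.

## The synthetic scene generator

`scene_spec()` describes piecewise-homogeneous scenes (a mandatory
background plus rectangular/disk inclusions) illuminated by a three-phase
sinusoid; `render_scene()` computes per-region reflectance with the
chosen forward model and synthesizes the raw camera frames with a linear
gain, optional additive Gaussian read noise, and optional Poisson shot
noise, last. `six_phantom_scene()` arranges six patches spanning
`μa 0.0135–0.0437`, `μs′ 0.982–1.326` mm⁻¹ — a synthetic analogue of a
six-phantom validation bench.

What the generator deliberately does *not* emulate: lateral photon
transport across region boundaries (each pixel is locally homogeneous,
so patch edges are unphysically sharp and only patch-interior statistics
are meaningful), projector MTF, vignetting, specular reflections, and
surface profile. Passing the closure tests therefore shows the
*processing chain* is correct and self-consistent; it does not validate
the forward model against real tissue.

Defaults: gain 1000 counts, planar amplitude 1, modulation amplitude 0.5,
noise off. The noise test uses σ = 1% of the planar signal level, a
realistic read-noise figure for a scientific CCD; under it, 40×40-pixel
patch means stay within ~10% (μa) and ~3% (μs′) of truth, and the
flagged-pixel fraction grows monotonically with σ.

## Problem sizes and reproducibility

Defaults are chosen for a desk-scale build: the reference simulation uses
10⁷ photons (`mc_config()` default) for production tables, the acceptance
script runs 2×10⁶ photons with 10⁶-pair training and test sets in ~7
minutes on one core, and the test suite uses 6×10⁴–2×10⁵ photons with
2×10⁵/10⁵-pair sets. Every stochastic stage — photon walk, set sampling,
tree growth, scene noise — takes an explicit integer seed, and
bit-for-bit reproducibility at fixed seed is asserted by tests. Artifacts
(histograms, tables, models) are saved as versioned archives whose format
version is checked on load.

## Known limitations

* Semi-infinite homogeneous media only: no layers, no heterogeneity in
  depth, no time domain, no polarization, no fluorescence.
* Two spatial frequencies; multi-frequency fitting and chromophore
  unmixing are out of scope.
* The white-MC path truncation biases near-zero-absorption reflectance
  (documented above).
* Similarity scaling leaves a real anisotropy dependence at
  `fx = 0.2` mm⁻¹; quantitative use at high frequency should match `g`
  to the tissue.
* Relative-error metrics over a domain that includes zero absorption
  depend strongly on the near-zero exclusion floor; always report the
  floor together with the numbers.
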