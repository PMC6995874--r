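# Shared simulation fixtures, built once per test run and memoised.
# Photon counts are kept modest: every check that uses them is either
# self-consistent (the same forward model generates and inverts the data,
# so MC noise cancels) or carries a tolerance derived from the counting
# noise at this scale.

.fx <- new.env(parent = emptyenv())

test_cfg <- function(n_photons = 6e4, seed = 42L, ...) {
  mc_config(n_photons = n_photons, seed = seed,
            radial_bin_width = 0.05, max_radius = 100,
            path_bin_width = 0.5, max_path = 1000, ...)
}

test_hist <- function() {
  if (is.null(.fx$hist)) .fx$hist <- run_white_mc(test_cfg())
  .fx$hist
}

test_forward <- function() {
  if (is.null(.fx$fwd))
    .fx$fwd <- sfdi_forward(test_hist(), n_alpha = 384L, n_phi = 256L)
  .fx$fwd
}

# larger histogram for the acceptance-level checks (better MC statistics)
acc_forward <- function() {
  if (is.null(.fx$acc_fwd)) {
    .fx$acc_hist <- run_white_mc(test_cfg(n_photons = 2e5, seed = 7L))
    .fx$acc_fwd <- sfdi_forward(.fx$acc_hist)
  }
  .fx$acc_fwd
}

acc_hist <- function() {
  acc_forward()
  .fx$acc_hist
}

# small lookup table shared by inversion tests
test_lut <- function() {
  if (is.null(.fx$lut)) .fx$lut <- build_forward_lut(test_forward(), 200, 200)
  .fx$lut
}
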