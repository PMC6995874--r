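#' Fit an SFDI inverse model
#'
#' Single entry point constructing any of the four inversion back-ends
#' that map calibrated two-frequency diffuse reflectance `(R0, Rn)` to
#' optical properties `(mu_a, mu_s_prime)`:
#' \describe{
#'   \item{`"rfr"`}{random-forest regressor trained on a simulated set
#'     ([generate_training_set()] + [fit_rfr()]); production-scale defaults are
#'     1e6 training pairs, 15 trees, minimum leaf size 2.}
#'   \item{`"lut"`}{dense 1000 x 1000 forward lookup table inverted by
#'     bilinear inverse interpolation ([build_forward_lut()]).}
#'   \item{`"lut_low"`}{the fast low-resolution 100 x 100 table.}
#'   \item{`"diffusion"`}{root finding on the closed-form diffusion
#'     approximation ([diffusion_invert()]); no training or tabulation.}
#' }
#' All returned objects share the `predict(object, R0, Rn)` interface and
#' return per-pixel property maps with status flags.
#'
#' @param forward forward-model handle used to simulate reflectance
#'   (ignored by `method = "diffusion"`, which carries its own model).
#' @param method inversion back-end.
#' @param fx_n modulated spatial frequency, mm^-1.
#' @param n_train training-set size for `"rfr"`.
#' @param training_seed,seed seeds for training-set sampling and tree
#'   randomness.
#' @param n_trees,min_leaf forest hyperparameters for `"rfr"`.
#' @param grid_size optional `c(p, q)` override of the LUT resolution.
#' @param n_rel refractive index ratio for `"diffusion"`.
#' @return An object inheriting from `sfdi_inverse`.
#' @examples
#' \donttest{
#' cfg <- mc_config(n_photons = 2e5, seed = 7)
#' fwd <- sfdi_forward(run_white_mc(cfg))
#' inv <- sfdi_inverse(fwd, method = "lut_low")
#' r <- reflectance(fwd, 0.05, 1.2, c(0, 0.2))
#' predict(inv, r[1], r[2])
#' }
#' @export
sfdi_inverse <- function(forward,
                         method = c("rfr", "lut", "lut_low", "diffusion"),
                         fx_n = 0.2, n_train = 1e6, training_seed = 1L,
                         seed = 1L, n_trees = 15L, min_leaf = 2L,
                         grid_size = NULL, n_rel = 1.43) {
  method <- match.arg(method)
  switch(method,
    rfr = {
      ts <- generate_training_set(forward, n_train, fx_n, training_seed)
      fit_rfr(ts, n_trees = n_trees, min_leaf = min_leaf, seed = seed)
    },
    lut = {
      gs <- if (is.null(grid_size)) c(1000L, 1000L) else grid_size
      build_forward_lut(forward, gs[1], gs[2], fx_n)
    },
    lut_low = {
      gs <- if (is.null(grid_size)) c(100L, 100L) else grid_size
      build_forward_lut(forward, gs[1], gs[2], fx_n)
    },
    diffusion = structure(
      list(params = diffusion_params(n_rel), fx_n = fx_n),
      class = c("sfdi_diffusion_inverse", "sfdi_inverse")))
}

#' @rdname predict.sfdi_rfr
#' @export
predict.sfdi_lut <- function(object, R0, Rn, ...) {
  lut_invert(object, R0, Rn)
}

#' @rdname predict.sfdi_rfr
#' @export
predict.sfdi_diffusion_inverse <- function(object, R0, Rn, ...) {
  diffusion_invert(R0, Rn, fx_n = object$fx_n, params = object$params)
}

#' @export
print.sfdi_diffusion_inverse <- function(x, ...) {
  cat(sprintf(
    "Diffusion-approximation inverse (n = %g, fx_n = %g mm^-1)\n",
    x$params$n_rel, x$fx_n))
  invisible(x)
}
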