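#' Diffusion-approximation boundary parameters
#'
#' Effective reflection coefficient and extrapolated-boundary constant of
#' the standard diffusion approximation for a planar refractive-index
#' mismatch.  Uses the cubic-polynomial fit
#' `R_eff(n) = 0.0636 n + 0.668 + 0.710 / n - 1.440 / n^2` and
#' `A = (1 - R_eff) / (2 (1 + R_eff))`.
#'
#' @param n_rel medium-to-exterior refractive index ratio (default 1.43,
#'   tissue to air).
#' @return An object of class `diffusion_params` with fields `n_rel`,
#'   `R_eff` and `A`.
#' @export
diffusion_params <- function(n_rel = 1.43) {
  if (n_rel < 1) stop("refractive index ratio must be >= 1")
  R_eff <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  structure(list(n_rel = n_rel, R_eff = R_eff,
                 A = (1 - R_eff) / (2 * (1 + R_eff))),
            class = "diffusion_params")
}

#' Diffuse reflectance in the diffusion approximation
#'
#' Closed-form spatial-frequency-domain diffuse reflectance of a
#' semi-infinite homogeneous medium.  With `mu_tr = mu_a + mu_s_prime`,
#' reduced albedo `a' = mu_s_prime / mu_tr`, `k = 2 pi fx` and
#' `mu_eff' = sqrt(3 mu_a mu_tr + k^2)`:
#' \deqn{R_d = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)
#'   (\mu_{eff}'/\mu_{tr} + 3A)}}{
#'   Rd = 3 A a' / ((mu_eff'/mu_tr + 1) (mu_eff'/mu_tr + 3A))}
#' At `mu_a = 0`, `fx = 0` the formula collapses to exactly 1.
#'
#' @param mu_a,mu_s_prime optical properties, mm^-1 (vectors, recycled).
#' @param fx spatial frequency, mm^-1 (recycled).
#' @param params a [diffusion_params()].
#' @return Diffuse reflectance, dimensionless, in `[0, 1]`.
#' @export
diffusion_rd <- function(mu_a, mu_s_prime, fx = 0,
                         params = diffusion_params()) {
  if (any(mu_a < 0) || any(mu_s_prime <= 0))
    stop("require mu_a >= 0 and mu_s_prime > 0")
  if (any(fx < 0)) stop("fx must be >= 0")
  mu_tr <- mu_a + mu_s_prime
  a_prime <- mu_s_prime / mu_tr
  k <- 2 * pi * fx
  x <- sqrt(3 * mu_a * mu_tr + k^2) / mu_tr   # mu_eff' / mu_tr
  3 * params$A * a_prime / ((x + 1) * (x + 3 * params$A))
}

#' Invert the diffusion model at two spatial frequencies
#'
#' Recovers `(mu_a, mu_s_prime)` from calibrated diffuse reflectance
#' `(R0, Rn)` at `fx = 0` and `fx = fx_n` by exploiting the model's nested
#' monotone structure: at `fx = 0` the reflectance depends on the reduced
#' albedo `a'` alone, so `R0` fixes `a'` by one-dimensional root finding;
#' `Rn` then fixes the transport coefficient `mu_tr` (monotone increasing
#' in `mu_tr` at fixed `a'`), and `mu_a = (1 - a') mu_tr`,
#' `mu_s_prime = a' mu_tr`.  Forward-model outputs round-trip to better
#' than 1e-6 mm^-1.
#'
#' Per-pixel failures are flagged, never raised: status 0 = ok, 1 =
#' degenerate or out-of-domain input (e.g. `Rn >= R0`, which carries no
#' scattering information in the model's monotone regime, or a solution
#' outside the supported property domain), 2 = non-finite input.
#'
#' @param R0,Rn reflectance at `fx = 0` and `fx = fx_n` (equal-length
#'   vectors or matrices).
#' @param fx_n modulated spatial frequency, mm^-1.
#' @param params a [diffusion_params()].
#' @return A list with numeric `mu_a`, `mu_s_prime` (mm^-1) and integer
#'   `status`, each shaped like `R0`.
#' @export
diffusion_invert <- function(R0, Rn, fx_n = 0.2,
                             params = diffusion_params()) {
  if (length(R0) != length(Rn)) stop("R0 and Rn must have equal length")
  n <- length(R0)
  mu_a <- mu_s <- rep(NA_real_, n)
  status <- integer(n)
  k <- 2 * pi * fx_n
  A3 <- 3 * params$A

  rd0_of_albedo <- function(a) {
    x <- sqrt(3 * (1 - a))
    A3 * a / ((x + 1) * (x + A3))
  }

  for (p in seq_len(n)) {
    r0 <- R0[p]; rn <- Rn[p]
    if (!is.finite(r0) || !is.finite(rn)) { status[p] <- 2L; next }
    if (r0 <= 0 || r0 >= 1 || rn <= 0 || rn >= r0) { status[p] <- 1L; next }
    a <- if (r0 >= rd0_of_albedo(1)) 1 else
      uniroot(function(a) rd0_of_albedo(a) - r0, c(1e-12, 1),
              tol = 1e-14)$root
    resid_mutr <- function(mu_tr) {
      x <- sqrt(3 * (1 - a) + (k / mu_tr)^2)
      A3 * a / ((x + 1) * (x + A3)) - rn
    }
    lo <- 1e-6; hi <- 1e6
    if (resid_mutr(lo) > 0 || resid_mutr(hi) < 0) { status[p] <- 1L; next }
    mu_tr <- uniroot(resid_mutr, c(lo, hi), tol = 1e-12)$root
    mu_a[p] <- (1 - a) * mu_tr
    mu_s[p] <- a * mu_tr
    if (mu_a[p] > .domain$mu_a[2] ||
        mu_s[p] < .domain$mu_s_prime[1] || mu_s[p] > .domain$mu_s_prime[2])
      status[p] <- 1L
  }

  shape <- function(v) { dim(v) <- dim(R0); v }
  list(mu_a = shape(mu_a), mu_s_prime = shape(mu_s),
       status = shape(status))
}

#' Diffusion-approximation forward model handle
#'
#' Wraps [diffusion_rd()] in the common forward-model interface shared with
#' the tabulated Monte-Carlo model, so lookup tables, training sets and
#' calibration can be driven by either light-propagation model.
#'
#' @param n_rel medium-to-exterior refractive index ratio.
#' @return An object of classes `sfdi_forward_diffusion`, `sfdi_forward`.
#' @export
sfdi_forward_diffusion <- function(n_rel = 1.43) {
  structure(list(params = diffusion_params(n_rel)),
            class = c("sfdi_forward_diffusion", "sfdi_forward"))
}

#' @rdname reflectance
#' @export
reflectance.sfdi_forward_diffusion <- function(model, mu_a, mu_s_prime, fx,
                                               ...) {
  diffusion_rd(mu_a, mu_s_prime, fx, model$params)
}

#' @export
print.sfdi_forward_diffusion <- function(x, ...) {
  cat(sprintf(
    "Diffusion-approximation forward model (n = %g, R_eff = %.4f, A = %.4f)\n",
    x$params$n_rel, x$params$R_eff, x$params$A))
  invisible(x)
}
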