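#' Build the tabulated white-MC forward model
#'
#' Reduces the white-MC histogram to a dense two-dimensional table from
#' which diffuse reflectance can be evaluated for millions of
#' `(mu_a, mu_s_prime, fx)` queries in microseconds each.  Under similarity
#' rescaling every query collapses to two coordinates measured in the
#' reference frame of the white run:
#' \describe{
#'   \item{`alpha = mu_a * scale`}{absorption per unit reference path,}
#'   \item{`phi = fx * scale`}{spatial frequency in reference units,}
#' }
#' with `scale = reference_mu_s_prime / mu_s_prime`.  The table stores
#' `G(alpha, phi) = sum_{r,l} W[r,l] expavg(-alpha l) J0avg(2 pi phi r)`
#' (bin-averaged kernels) on grids uniform in `log1p(alpha)` and
#' `log1p(phi)`; queries are answered by bilinear interpolation.  `phi = 0`
#' is a grid point, so planar reflectance involves no interpolation in
#' frequency.
#'
#' @param hist an `mc_histogram` from [run_white_mc()].
#' @param fx_max largest spatial frequency (mm^-1) the table must support
#'   over the full property domain; sets the `phi` range.
#' @param n_alpha,n_phi table resolution.  The defaults keep bilinear
#'   interpolation error well below the Monte-Carlo noise floor.
#' @return An object of class `sfdi_forward_mc`; evaluate it with
#'   [reflectance()].
#' @seealso [reflectance()], [mc_forward()] for the exact direct route.
#' @export
sfdi_forward <- function(hist, fx_max = 0.2, n_alpha = 512L, n_phi = 384L) {
  stopifnot(inherits(hist, "mc_histogram"))
  cfg <- hist$config
  scale_max <- cfg$reference_mu_s_prime / .domain$mu_s_prime[1]
  alpha_max <- 1.05 * .domain$mu_a[2] * scale_max
  phi_max <- 1.05 * fx_max * scale_max
  s <- 1e-3  # log1p softening, alpha/phi scale below which grid is ~linear

  u_grid <- seq(0, log1p(alpha_max / s), length.out = n_alpha)
  v_grid <- seq(0, log1p(phi_max / s), length.out = n_phi)
  alphas <- expm1(u_grid) * s
  phis <- expm1(v_grid) * s
  phis[1] <- 0

  lc <- (hist$path_edges[-1] + hist$path_edges[-length(hist$path_edges)]) / 2
  E <- matrix(0, n_alpha, length(lc))
  for (i in seq_len(n_alpha))
    E[i, ] <- .exp_bin_avg(alphas[i], lc, cfg$path_bin_width)
  J <- matrix(0, nrow(hist$weights), n_phi)
  for (j in seq_len(n_phi))
    J[, j] <- .j0_bin_avg(phis[j], hist$radial_edges)

  launched <- max(hist$launched_weight, 1)
  G <- E %*% crossprod(hist$weights, J) / launched

  structure(list(
    G = G, u_grid = u_grid, v_grid = v_grid, s = s,
    alpha_max = alpha_max, phi_max = phi_max,
    reference_mu_s_prime = cfg$reference_mu_s_prime,
    fx_max = fx_max, config = cfg,
    mc_seed = cfg$seed, n_photons = hist$launched_weight),
    class = c("sfdi_forward_mc", "sfdi_forward"))
}

#' @export
print.sfdi_forward_mc <- function(x, ...) {
  cat("White Monte-Carlo forward model (tabulated)\n")
  cat(sprintf("  table: %d x %d (log-absorption x log-frequency)\n",
              nrow(x$G), ncol(x$G)))
  cat(sprintf("  photons: %g   MC seed: %d   fx up to %g mm^-1\n",
              x$n_photons, x$mc_seed, x$fx_max))
  invisible(x)
}

#' Evaluate a forward model
#'
#' Diffuse reflectance of a semi-infinite homogeneous medium at spatial
#' frequency `fx`, for one of the package's forward models: the tabulated
#' white Monte-Carlo model ([sfdi_forward()]) or the diffusion
#' approximation ([sfdi_forward_diffusion()]).
#'
#' @param model a forward-model object.
#' @param mu_a,mu_s_prime optical properties, mm^-1 (equal-length vectors).
#' @param fx spatial frequency, mm^-1; scalar or vector recycled against the
#'   properties.
#' @param ... passed to methods.
#' @return Numeric vector of diffuse reflectance values.
#' @export
reflectance <- function(model, mu_a, mu_s_prime, fx, ...) {
  UseMethod("reflectance")
}

#' @rdname reflectance
#' @export
reflectance.sfdi_forward_mc <- function(model, mu_a, mu_s_prime, fx, ...) {
  .check_props(mu_a, mu_s_prime)
  scale <- model$reference_mu_s_prime / mu_s_prime
  alpha <- mu_a * scale
  phi <- fx * scale
  if (any(alpha > model$alpha_max) || any(phi > model$phi_max))
    stop("query outside the tabulated range; rebuild with a larger fx_max ",
         "or use mc_forward() directly")
  G <- model$G
  na <- nrow(G); np <- ncol(G)
  du <- model$u_grid[2] - model$u_grid[1]
  dv <- model$v_grid[2] - model$v_grid[1]
  tu <- log1p(alpha / model$s) / du
  tv <- log1p(phi / model$s) / dv
  i <- pmin.int(pmax.int(floor(tu), 0), na - 2L)
  j <- pmin.int(pmax.int(floor(tv), 0), np - 2L)
  fu <- tu - i
  fv <- tv - j
  base <- i + 1L + j * na
  (1 - fu) * (1 - fv) * G[base] + fu * (1 - fv) * G[base + 1L] +
    (1 - fu) * fv * G[base + na] + fu * fv * G[base + na + 1L]
}
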