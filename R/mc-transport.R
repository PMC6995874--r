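#' Monte-Carlo simulation configuration
#'
#' Bundles the parameters of the photon-transport kernel: medium optics,
#' boundary refractive indices, histogram binning, and termination rules.
#' The walk simulates a pencil beam normally incident on a semi-infinite
#' homogeneous medium and tallies photon weight exiting the top surface by
#' exit radius and total path length.
#'
#' The default run is a "white" (scattering-only) simulation at a reference
#' reduced scattering `reference_mu_s_prime`; absorption and other scattering
#' levels are obtained afterwards by path-length re-weighting and similarity
#' rescaling (see [apply_absorption()]), so one simulation serves every
#' property pair in the supported domain.
#'
#' @param n_photons number of photons to launch.
#' @param n_inside refractive index of the medium (tissue-like default 1.43).
#' @param n_outside refractive index of the exterior.
#' @param g Henyey-Greenstein anisotropy, in `[0, 1)`.  The scattering
#'   coefficient used in the walk is `mu_s = reference_mu_s_prime / (1 - g)`.
#' @param reference_mu_s_prime reduced scattering of the reference run,
#'   mm^-1.
#' @param radial_bin_width,max_radius exit-radius binning, mm.
#' @param path_bin_width,max_path path-length binning, mm.  Photons whose
#'   cumulative path exceeds `max_path` are terminated and their weight
#'   booked as lost.
#' @param weight_min,survival_factor Russian-roulette threshold and survival
#'   weight multiplier (engages only when the walk carries absorption).
#' @param seed integer seed of the kernel's own xoshiro256++ generator; runs
#'   are bit-for-bit reproducible for a given seed.
#'
#' @return An object of class `mc_config`.
#' @seealso [run_white_mc()], [sfdi_forward()]
#' @export
mc_config <- function(n_photons = 1e7, n_inside = 1.43, n_outside = 1.0,
                      g = 0.9, reference_mu_s_prime = 1.0,
                      radial_bin_width = 0.02, max_radius = 100,
                      path_bin_width = 0.25, max_path = 1000,
                      weight_min = 1e-4, survival_factor = 10,
                      seed = 1L) {
  stopifnot(n_photons >= 0, n_photons == floor(n_photons))
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)")
  if (n_inside < 1 || n_outside < 1) stop("refractive indices must be >= 1")
  if (reference_mu_s_prime <= 0) stop("reference_mu_s_prime must be > 0")
  n_radial <- max_radius / radial_bin_width
  n_path <- max_path / path_bin_width
  if (abs(n_radial - round(n_radial)) > 1e-9 ||
      abs(n_path - round(n_path)) > 1e-9)
    stop("max_radius / radial_bin_width and max_path / path_bin_width ",
         "must be whole numbers of bins")
  structure(list(
    n_photons = n_photons, n_inside = n_inside, n_outside = n_outside,
    g = g, reference_mu_s_prime = reference_mu_s_prime,
    radial_bin_width = radial_bin_width, max_radius = max_radius,
    n_radial = as.integer(round(n_radial)),
    path_bin_width = path_bin_width, max_path = max_path,
    n_path = as.integer(round(n_path)),
    weight_min = weight_min, survival_factor = survival_factor,
    seed = as.integer(seed)), class = "mc_config")
}

#' @export
print.mc_config <- function(x, ...) {
  cat("Monte-Carlo configuration\n")
  cat(sprintf("  photons: %g   g: %g   n: %g / %g   seed: %d\n",
              x$n_photons, x$g, x$n_inside, x$n_outside, x$seed))
  cat(sprintf("  reference mu_s': %g mm^-1 (mu_s = %g mm^-1 in the walk)\n",
              x$reference_mu_s_prime, x$reference_mu_s_prime / (1 - x$g)))
  cat(sprintf("  radial bins: %d x %g mm   path bins: %d x %g mm\n",
              x$n_radial, x$radial_bin_width, x$n_path, x$path_bin_width))
  invisible(x)
}

.run_mc <- function(config, mu_a, mu_s, projection_fx = numeric(0),
                    seed = config$seed) {
  if (config$n_photons == 0) {
    res <- list(weights = matrix(0, config$n_radial, config$n_path),
                launched_weight = 0, absorbed_or_lost_weight = 0,
                projection = rep(0, length(projection_fx)),
                projection_total = 0)
  } else {
    res <- .mc_walk(config$n_photons, mu_s, mu_a, config$g,
                    config$n_inside, config$n_outside,
                    config$radial_bin_width, config$n_radial,
                    config$path_bin_width, config$n_path,
                    config$weight_min, config$survival_factor,
                    as.numeric(projection_fx), as.numeric(seed))
  }
  structure(list(
    weights = res$weights,
    radial_edges = seq(0, config$max_radius, by = config$radial_bin_width),
    path_edges = seq(0, config$max_path, by = config$path_bin_width),
    launched_weight = res$launched_weight,
    absorbed_or_lost_weight = res$absorbed_or_lost_weight,
    projection = res$projection, projection_fx = projection_fx,
    projection_total = res$projection_total,
    mu_a = mu_a, mu_s = mu_s, config = config), class = "mc_histogram")
}

#' Run the white (scattering-only) Monte-Carlo reference simulation
#'
#' Launches `config$n_photons` photons as a pencil beam normally incident on
#' a semi-infinite medium with scattering coefficient
#' `reference_mu_s_prime / (1 - g)` and no absorption, applying unpolarized
#' Fresnel reflection/refraction at the index-mismatched planar boundary.
#' Exit weight is binned by exit radius and total internal path length.
#' The resulting histogram is the reusable forward-model kernel: absorption
#' and arbitrary scattering levels are applied afterwards by
#' [apply_absorption()] without re-simulating.
#'
#' Energy is conserved exactly by construction:
#' `sum(weights) + absorbed_or_lost_weight == launched_weight` up to
#' floating-point rounding.
#'
#' @param config an [mc_config()].
#' @return An object of class `mc_histogram` with fields `weights`
#'   (radius x path matrix of exit weight), `radial_edges`, `path_edges`,
#'   `launched_weight`, `absorbed_or_lost_weight` and the generating
#'   `config`.
#' @export
run_white_mc <- function(config) {
  .run_mc(config, mu_a = 0,
          mu_s = config$reference_mu_s_prime / (1 - config$g))
}

#' Run a Monte-Carlo simulation with explicit in-walk absorption
#'
#' Brute-force counterpart of the white-MC + re-weighting route: the walk is
#' performed at the requested `(mu_a, mu_s_prime)` directly, with photon
#' weight decaying as `exp(-mu_a * path)` along every segment and Russian
#' roulette on low weights.  Optionally accumulates direct
#' spatial-frequency projections `sum w * cos(2 pi fx x_exit)` over exit
#' events, giving an unbinned estimate of the modulated diffuse reflectance.
#' Mainly used to validate the fast white-MC route.
#'
#' @param config an [mc_config()]; its `reference_mu_s_prime` is ignored.
#' @param mu_a,mu_s_prime optical properties of the medium, mm^-1.
#' @param projection_fx numeric vector of spatial frequencies (mm^-1) at
#'   which to accumulate direct projections.
#' @param seed kernel seed, defaulting to `config$seed`.
#' @return An `mc_histogram`; when `projection_fx` is non-empty the fields
#'   `projection` (raw cosine-weighted sums) and `projection_total` (total
#'   exit weight) allow `Rd(fx) = projection / launched_weight`.
#' @export
run_absorption_mc <- function(config, mu_a, mu_s_prime,
                              projection_fx = numeric(0),
                              seed = config$seed) {
  .check_props(mu_a, mu_s_prime)
  stopifnot(length(mu_a) == 1)
  .run_mc(config, mu_a = mu_a, mu_s = mu_s_prime / (1 - config$g),
          projection_fx = projection_fx, seed = seed)
}

#' @export
print.mc_histogram <- function(x, ...) {
  cat("Monte-Carlo exit-weight histogram\n")
  cat(sprintf("  launched: %g   exited: %g   absorbed/lost: %g\n",
              x$launched_weight, sum(x$weights),
              x$absorbed_or_lost_weight))
  cat(sprintf("  bins: %d radial x %d path   mu_s = %g mm^-1 (g = %g)\n",
              nrow(x$weights), ncol(x$weights), x$mu_s, x$config$g))
  if (x$mu_a > 0) cat(sprintf("  explicit absorption mu_a = %g mm^-1\n",
                              x$mu_a))
  invisible(x)
}

# Path-average of exp(-alpha * l) over a bin of width h centred at lc,
# assuming uniform within-bin density: exp(-alpha*lc) * sinh(alpha h/2)/(..).
# Removes the first-order midpoint-quadrature bias of the absorption factor.
.exp_bin_avg <- function(alpha, centers, h) {
  f <- exp(-alpha * centers)
  if (alpha > 0) {
    x <- alpha * h / 2
    f <- f * (if (x < 1e-6) 1 + x^2 / 6 else sinh(x) / x)
  }
  f
}

# Area-average of J0(2 pi phi r) over an annular bin [r0, r1], assuming
# uniform area density: integral of J0 r dr is r J1 / (2 pi phi).
.j0_bin_avg <- function(phi, edges) {
  if (phi == 0) return(rep(1, length(edges) - 1L))
  k <- 2 * pi * phi
  prim <- edges * besselJ(k * edges, 1) / k
  (2 * diff(prim)) / diff(edges^2)
}

#' Re-weight the white-MC histogram to a target optical-property pair
#'
#' Converts the scattering-only reference histogram into the spatially
#' resolved diffuse reflectance of a medium with absorption `mu_a` and
#' reduced scattering `mu_s_prime`, using the similarity rescaling of the
#' white Monte-Carlo method: all lengths shrink by
#' `scale = reference_mu_s_prime / mu_s_prime`, and each cell is weighted by
#' the bin-averaged absorption factor `exp(-mu_a * scale * path)`.
#'
#' @param hist an `mc_histogram` from [run_white_mc()].
#' @param mu_a,mu_s_prime target optical properties, mm^-1.
#' @return An object of class `radial_profile`: reflectance per unit area
#'   `R` over rescaled radial bins (`radial_edges`, mm), and the total
#'   diffuse reflectance `total_reflectance`.
#' @export
apply_absorption <- function(hist, mu_a, mu_s_prime) {
  stopifnot(inherits(hist, "mc_histogram"))
  .check_props(mu_a, mu_s_prime)
  stopifnot(length(mu_a) == 1)
  cfg <- hist$config
  scale <- cfg$reference_mu_s_prime / mu_s_prime
  lc <- (hist$path_edges[-1] + hist$path_edges[-length(hist$path_edges)]) / 2
  decay <- .exp_bin_avg(mu_a * scale, lc, cfg$path_bin_width)
  w_r <- as.numeric(hist$weights %*% decay)   # exit weight per radial bin
  edges <- hist$radial_edges * scale
  area <- pi * diff(edges^2)
  launched <- max(hist$launched_weight, 1)
  structure(list(
    R = w_r / (area * launched),
    radial_edges = edges,
    total_reflectance = sum(w_r) / launched,
    scale = scale, mu_a = mu_a, mu_s_prime = mu_s_prime),
    class = "radial_profile")
}

#' Project a radial reflectance profile into the spatial frequency domain
#'
#' Evaluates the zero-order Hankel transform
#' `Rd(fx) = 2 pi * integral R(rho) J0(2 pi fx rho) rho d rho` on the binned
#' profile, using the exact area-average of the Bessel kernel over each
#' annular bin.  `Rd(0)` equals the profile's total reflectance.
#'
#' @param profile a `radial_profile` from [apply_absorption()].
#' @param fx spatial frequency, mm^-1 (vectorized).
#' @return Diffuse reflectance at each `fx`, dimensionless.
#' @export
project_to_frequency <- function(profile, fx) {
  stopifnot(inherits(profile, "radial_profile"))
  if (any(fx < 0)) stop("fx must be >= 0")
  area <- pi * diff(profile$radial_edges^2)
  vapply(fx, function(f) {
    sum(profile$R * area * .j0_bin_avg(f, profile$radial_edges))
  }, numeric(1))
}

#' Diffuse reflectance from the white-MC histogram (direct route)
#'
#' Composition of [apply_absorption()] and [project_to_frequency()]: the
#' exact (non-interpolated) white Monte-Carlo forward model.  Intended for
#' small numbers of property pairs; bulk evaluation over many pairs should
#' use the tabulated fast path built by [sfdi_forward()].
#'
#' @param hist an `mc_histogram` from [run_white_mc()].
#' @param mu_a,mu_s_prime optical properties, mm^-1 (vectorized, equal
#'   length).
#' @param fx spatial frequencies, mm^-1 (default the two working
#'   frequencies 0 and 0.2).
#' @return A matrix with `length(mu_a)` rows and `length(fx)` columns of
#'   diffuse reflectance values.
#' @export
mc_forward <- function(hist, mu_a, mu_s_prime, fx = c(0, 0.2)) {
  .check_props(mu_a, mu_s_prime)
  out <- matrix(NA_real_, length(mu_a), length(fx),
                dimnames = list(NULL, paste0("fx_", fx)))
  for (i in seq_along(mu_a)) {
    prof <- apply_absorption(hist, mu_a[i], mu_s_prime[i])
    out[i, ] <- project_to_frequency(prof, fx)
  }
  out
}
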