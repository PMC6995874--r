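#' Build a forward lookup table over the optical-property domain
#'
#' Tabulates diffuse reflectance `(R0, Rn)` on a uniform `p x q` grid of
#' `(mu_a, mu_s_prime)` covering the supported domain `[0, 2] x [0.01, 15]`
#' mm^-1, using a single shared forward model for every node.  The two
#' standard configurations are the dense 1000 x 1000 table and the fast
#' low-resolution 100 x 100 table.
#'
#' @param forward forward-model handle ([sfdi_forward()] or
#'   [sfdi_forward_diffusion()]).
#' @param p,q grid sizes along `mu_a` and `mu_s_prime` (>= 2).
#' @param fx_n modulated spatial frequency, mm^-1.
#' @return An object of class `sfdi_lut` with the two axes, the `p x q`
#'   reflectance matrices `R0` and `Rn`, and provenance metadata.
#' @seealso [lut_invert()]
#' @export
build_forward_lut <- function(forward, p = 1000L, q = 1000L, fx_n = 0.2) {
  stopifnot(p >= 2, q >= 2)
  mu_a_axis <- seq(.domain$mu_a[1], .domain$mu_a[2], length.out = p)
  mu_s_axis <- seq(.domain$mu_s_prime[1], .domain$mu_s_prime[2],
                   length.out = q)
  grid_a <- rep(mu_a_axis, times = q)
  grid_s <- rep(mu_s_axis, each = p)
  R0 <- matrix(reflectance(forward, grid_a, grid_s, 0), p, q)
  Rn <- matrix(reflectance(forward, grid_a, grid_s, fx_n), p, q)
  if (any(!is.finite(R0)) || any(!is.finite(Rn))) {
    bad <- which(!is.finite(R0) | !is.finite(Rn), arr.ind = TRUE)[1, ]
    stop(sprintf("forward model failed at node mu_a = %g, mu_s' = %g",
                 mu_a_axis[bad[1]], mu_s_axis[bad[2]]))
  }
  structure(list(
    mu_a_axis = mu_a_axis, mu_s_axis = mu_s_axis,
    R0 = R0, Rn = Rn, fx_n = fx_n,
    forward_class = class(forward)[1],
    mc_seed = if (!is.null(forward$mc_seed)) forward$mc_seed else NA_integer_),
    class = c("sfdi_lut", "sfdi_inverse"))
}

#' @export
print.sfdi_lut <- function(x, ...) {
  cat(sprintf("SFDI forward lookup table: %d x %d nodes, fx_n = %g mm^-1\n",
              length(x$mu_a_axis), length(x$mu_s_axis), x$fx_n))
  cat(sprintf("  mu_a in [%g, %g], mu_s' in [%g, %g] mm^-1 (%s)\n",
              min(x$mu_a_axis), max(x$mu_a_axis),
              min(x$mu_s_axis), max(x$mu_s_axis), x$forward_class))
  invisible(x)
}

#' Plot the forward-mapped reflectance manifold of a lookup table
#'
#' Draws a subsampled image of the `(R0, Rn)` grid: iso-`mu_a` and
#' iso-`mu_s_prime` lines in reflectance space, the curvilinear mesh on
#' which inverse interpolation operates.
#'
#' @param x an `sfdi_lut`.
#' @param every draw every `every`-th grid line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sfdi_lut <- function(x, every = max(1L, length(x$mu_a_axis) %/% 25L),
                          ...) {
  ii <- unique(c(seq(1, length(x$mu_a_axis), by = every),
                 length(x$mu_a_axis)))
  jj <- unique(c(seq(1, length(x$mu_s_axis), by = every),
                 length(x$mu_s_axis)))
  graphics::plot(range(x$R0), range(x$Rn), type = "n",
                 xlab = "R0 (planar)", ylab = "Rn (modulated)", ...)
  for (i in ii) graphics::lines(x$R0[i, ], x$Rn[i, ], col = "grey40")
  for (j in jj) graphics::lines(x$R0[, j], x$Rn[, j], col = "steelblue")
  invisible(x)
}

#' Invert reflectance maps through a lookup table
#'
#' Maps calibrated reflectance pairs back to optical properties by inverse
#' bilinear interpolation on the forward-mapped grid: for each query the
#' unique preimage on the monotone `(R0, Rn)` manifold is located by nested
#' monotone root finding in continuous grid coordinates (exact at grid
#' nodes).  Queries off the manifold are answered with the nearest clamped
#' solution and flagged out-of-domain; non-finite inputs are flagged
#' invalid.
#'
#' @param lut an `sfdi_lut` from [build_forward_lut()].
#' @param R0,Rn reflectance maps (equal-shape vectors or matrices).
#' @return A list with `mu_a`, `mu_s_prime` (mm^-1) and integer `status`
#'   (0 ok, 1 out-of-domain, 2 invalid input), each shaped like `R0`.
#' @export
lut_invert <- function(lut, R0, Rn) {
  stopifnot(inherits(lut, "sfdi_lut"))
  if (length(R0) != length(Rn)) stop("R0 and Rn must have equal length")
  res <- .lut_invert(lut$mu_a_axis, lut$mu_s_axis, lut$R0, lut$Rn,
                     as.numeric(R0), as.numeric(Rn))
  shape <- function(v) { dim(v) <- dim(R0); v }
  list(mu_a = shape(res$mu_a), mu_s_prime = shape(res$mu_s_prime),
       status = shape(res$status))
}
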