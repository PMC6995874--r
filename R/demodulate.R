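#' Three-phase structured-illumination image stack
#'
#' Container for the three intensity images of one projected spatial
#' frequency, acquired at pattern phases 0, 2pi/3 and 4pi/3.
#'
#' @param images list of three numeric matrices of equal dimensions,
#'   non-negative camera intensities.
#' @param spatial_frequency projected spatial frequency, mm^-1.
#' @param pixel_pitch object-plane pixel size, mm/pixel.
#' @param phases pattern phases, radians.
#' @return An object of class `phase_stack`.
#' @export
phase_stack <- function(images, spatial_frequency, pixel_pitch = 0.1,
                        phases = 2 * pi * (0:2) / 3) {
  if (length(images) != 3) stop("a phase stack holds exactly three images")
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all three images must share the same dimensions")
  if (any(vapply(images, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative")
  structure(list(images = images, spatial_frequency = spatial_frequency,
                 pixel_pitch = pixel_pitch, phases = phases),
            class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Phase stack: %d x %d pixels, fx = %g mm^-1, pitch %g mm\n",
              d[1], d[2], x$spatial_frequency, x$pixel_pitch))
  invisible(x)
}

#' Demodulate the AC (modulation) amplitude of a three-phase stack
#'
#' Per-pixel modulation amplitude
#' `A = sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`,
#' exact for ideal sinusoidal illumination at phases spaced by 2pi/3 and
#' independent of the global phase offset of the pattern.
#'
#' @param stack a [phase_stack()].
#' @return Matrix of modulation amplitudes, same camera units as the input.
#' @export
demodulate_ac <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  i1 <- stack$images[[1]]; i2 <- stack$images[[2]]; i3 <- stack$images[[3]]
  sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
}

#' Demodulate the DC (planar) amplitude of a three-phase stack
#'
#' Per-pixel mean over the three phases, `A0 = (I1 + I2 + I3) / 3`.  For
#' equally spaced phases the sinusoidal component cancels exactly, leaving
#' the planar (zero-frequency) amplitude.
#'
#' @param stack a [phase_stack()].
#' @return Matrix of DC amplitudes.
#' @export
demodulate_dc <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  (stack$images[[1]] + stack$images[[2]] + stack$images[[3]]) / 3
}

#' Calibrate demodulated amplitudes against a reference phantom
#'
#' Converts sample modulation amplitudes to absolute diffuse reflectance
#' using a measurement of a reference phantom with known optical
#' properties: `R = (A / A_ref) * R_ref`, where `R_ref` is the
#' forward-modelled diffuse reflectance of the phantom at the working
#' spatial frequency.  Camera gain and illumination profile cancel in the
#' ratio, so the result is scale-invariant in the raw intensities.
#'
#' Pixels where the reference amplitude falls below
#' `floor_frac * max(a_ref)` are flagged invalid (status 2) rather than
#' producing unbounded ratios.  Calibrated reflectance is deliberately not
#' clamped to `[0, 1]`; values outside that range (possible under noise)
#' are flagged with status 1 so that downstream inversion can apply its own
#' out-of-domain policy.
#'
#' @param a_sample,a_ref demodulated amplitude maps of the sample and the
#'   reference phantom (equal shape).
#' @param ref_props list or named vector with `mu_a` and `mu_s_prime` of
#'   the reference phantom, mm^-1.  The bundled default corresponds to a
#'   silicone calibration phantom at 665 nm: `mu_a = 0.0117`,
#'   `mu_s_prime = 1.0827`.
#' @param fx spatial frequency of the amplitudes, mm^-1.
#' @param forward forward-model handle used to simulate the phantom's
#'   reflectance (see [reflectance()]).
#' @param floor_frac reference-amplitude validity floor, as a fraction of
#'   the maximum reference amplitude.
#' @return A list with `R` (calibrated reflectance map), `R_ref` (the
#'   modelled phantom reflectance, scalar) and integer `status` (0 ok,
#'   1 out of physical range, 2 invalid reference).
#' @export
calibrate <- function(a_sample, a_ref,
                      ref_props = list(mu_a = 0.0117, mu_s_prime = 1.0827),
                      fx, forward, floor_frac = 1e-6) {
  if (!identical(dim(a_sample), dim(a_ref)))
    stop("sample and reference amplitude maps must share dimensions")
  .check_props(ref_props$mu_a, ref_props$mu_s_prime, domain = TRUE)
  r_ref <- reflectance(forward, ref_props$mu_a, ref_props$mu_s_prime, fx)
  floor_val <- floor_frac * max(a_ref)
  bad_ref <- !is.finite(a_ref) | a_ref < floor_val
  R <- (a_sample / a_ref) * r_ref
  R[bad_ref] <- NA_real_
  status <- matrix(0L, nrow(a_sample), ncol(a_sample))
  status[!is.finite(R) | R < 0 | R > 1] <- 1L
  status[bad_ref] <- 2L
  list(R = R, R_ref = r_ref, status = status)
}
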