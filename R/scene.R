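#' Specify a synthetic piecewise-homogeneous SFDI scene
#'
#' Describes a turbid-slab scene imaged under sinusoidal structured
#' illumination: a mandatory homogeneous background tiled with optional
#' rectangular or disk inclusions, each locally homogeneous with its own
#' optical properties.  The rendered camera model is linear:
#' `I_k = gain * (a_dc * R0 + a_ac * R(fx) * cos(2 pi fx x + phase_k))`
#' per pixel and phase, with optional additive Gaussian read noise and
#' Poisson shot noise applied last.  Lateral light transport across region
#' boundaries is not modelled, so patch edges are sharp; patch-interior
#' statistics are the intended use.
#'
#' @param shape image size in pixels, `c(rows, cols)`.
#' @param pixel_pitch object-plane pixel size, mm/pixel.
#' @param background list with `mu_a` and `mu_s_prime` (mm^-1) of the
#'   background medium.
#' @param regions list of inclusions; each a list with `shape` (`"rect"` or
#'   `"disk"`), geometry in pixels (`rows`/`cols` ranges for rectangles,
#'   `center`/`radius` for disks), and `mu_a`, `mu_s_prime`.
#' @param fx projected spatial frequency, mm^-1.
#' @param phases pattern phases, radians.
#' @param phase_offset global phase of the projected pattern, radians.
#' @param gain linear camera gain, counts per unit reflectance.
#' @param a_dc,a_ac planar and modulation amplitudes of the illumination
#'   (arbitrary units; they cancel in calibration).
#' @param noise_sigma additive Gaussian noise standard deviation, camera
#'   counts (0 disables).
#' @param poisson logical; also apply Poisson shot noise to the counts.
#' @param seed integer seed for the noise generator.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(300L, 400L), pixel_pitch = 0.1,
                       background = list(mu_a = 0.0117,
                                         mu_s_prime = 1.0827),
                       regions = list(), fx = 0.2,
                       phases = 2 * pi * (0:2) / 3, phase_offset = 0,
                       gain = 1000, a_dc = 1, a_ac = 0.5,
                       noise_sigma = 0, poisson = FALSE, seed = 1L) {
  .check_props(background$mu_a, background$mu_s_prime, domain = TRUE)
  for (r in regions) .check_props(r$mu_a, r$mu_s_prime, domain = TRUE)
  stopifnot(length(shape) == 2, all(shape >= 1), pixel_pitch > 0,
            fx >= 0, gain > 0, a_dc > 0, a_ac >= 0, noise_sigma >= 0)
  structure(list(shape = as.integer(shape), pixel_pitch = pixel_pitch,
                 background = background, regions = regions, fx = fx,
                 phases = phases, phase_offset = phase_offset, gain = gain,
                 a_dc = a_dc, a_ac = a_ac, noise_sigma = noise_sigma,
                 poisson = poisson, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Six-patch phantom scene
#'
#' Convenience scene mirroring a bench of six small tissue-simulating
#' phantoms: absorption spanning 0.0135 to 0.0437 mm^-1 and reduced
#' scattering 0.982 to 1.326 mm^-1, arranged as a 2 x 3 array of square
#' patches on a calibration-phantom background.
#'
#' @param patch_px patch side length, pixels.
#' @param margin_px spacing between patches and to the frame edge, pixels.
#' @param ... further arguments passed to [scene_spec()].
#' @return A `scene_spec` with six rectangular inclusions; patch truth
#'   values are in `attr(, "patch_props")`.
#' @export
six_phantom_scene <- function(patch_px = 100L, margin_px = 20L, ...) {
  mu_a <- seq(0.0135, 0.0437, length.out = 6)
  mu_s <- seq(0.982, 1.326, length.out = 6)
  regions <- vector("list", 6)
  k <- 0
  for (i in 1:2) for (j in 1:3) {
    k <- k + 1
    r0 <- margin_px + (i - 1) * (patch_px + margin_px) + 1
    c0 <- margin_px + (j - 1) * (patch_px + margin_px) + 1
    regions[[k]] <- list(shape = "rect", name = paste0("phantom", k),
                         rows = c(r0, r0 + patch_px - 1),
                         cols = c(c0, c0 + patch_px - 1),
                         mu_a = mu_a[k], mu_s_prime = mu_s[k])
  }
  rows <- 2 * patch_px + 3 * margin_px
  cols <- 3 * patch_px + 4 * margin_px
  sp <- scene_spec(shape = c(rows, cols), regions = regions, ...)
  attr(sp, "patch_props") <- data.frame(
    name = vapply(regions, `[[`, "", "name"), mu_a = mu_a, mu_s_prime = mu_s)
  sp
}

.paint_property_maps <- function(spec) {
  mu_a <- matrix(spec$background$mu_a, spec$shape[1], spec$shape[2])
  mu_s <- matrix(spec$background$mu_s_prime, spec$shape[1], spec$shape[2])
  for (r in spec$regions) {
    if (identical(r$shape, "rect")) {
      sel_r <- r$rows[1]:r$rows[2]; sel_c <- r$cols[1]:r$cols[2]
      mu_a[sel_r, sel_c] <- r$mu_a
      mu_s[sel_r, sel_c] <- r$mu_s_prime
    } else if (identical(r$shape, "disk")) {
      rr <- row(mu_a) - r$center[1]; cc <- col(mu_a) - r$center[2]
      sel <- rr^2 + cc^2 <= r$radius^2
      mu_a[sel] <- r$mu_a
      mu_s[sel] <- r$mu_s_prime
    } else stop("unknown region shape: ", r$shape)
  }
  list(mu_a = mu_a, mu_s_prime = mu_s)
}

#' Render the phase stacks of a synthetic scene
#'
#' Computes per-region diffuse reflectance with the supplied forward model
#' and synthesizes the six raw camera frames of a two-frequency SFDI
#' acquisition: a planar-frequency stack (`fx = 0`) and a modulated stack
#' at the scene's spatial frequency, three phases each.  Ground-truth
#' property maps are returned alongside.  Rendering is bitwise
#' reproducible for a given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param forward forward-model handle (see [reflectance()]).
#' @return A list with `stack_f0` and `stack_fn` ([phase_stack()]s),
#'   `truth` (list of `mu_a`, `mu_s_prime` matrices), and `spec`.
#' @export
render_scene <- function(spec, forward) {
  stopifnot(inherits(spec, "scene_spec"))
  truth <- .paint_property_maps(spec)
  # region-wise constant properties: evaluate each unique pair once
  key <- paste(truth$mu_a, truth$mu_s_prime)
  uk <- !duplicated(key)
  R0 <- matrix(reflectance(forward, truth$mu_a[uk], truth$mu_s_prime[uk],
                           0)[match(key, key[uk])],
               spec$shape[1], spec$shape[2])
  Rn <- matrix(reflectance(forward, truth$mu_a[uk], truth$mu_s_prime[uk],
                           spec$fx)[match(key, key[uk])],
               spec$shape[1], spec$shape[2])

  xpos <- matrix(rep((seq_len(spec$shape[2]) - 1) * spec$pixel_pitch,
                     each = spec$shape[1]), spec$shape[1], spec$shape[2])
  render_stack <- function(fx, Rmod) {
    imgs <- lapply(spec$phases, function(ph) {
      spec$gain * (spec$a_dc * R0 +
                     spec$a_ac * Rmod *
                       cos(2 * pi * fx * xpos + spec$phase_offset + ph))
    })
    phase_stack(imgs, spatial_frequency = fx,
                pixel_pitch = spec$pixel_pitch, phases = spec$phases)
  }
  stack_f0 <- render_stack(0, R0)
  stack_fn <- render_stack(spec$fx, Rn)

  if (spec$noise_sigma > 0 || spec$poisson) {
    noisy <- .with_seed(spec$seed, {
      lapply(list(stack_f0, stack_fn), function(st) {
        st$images <- lapply(st$images, function(im) {
          if (spec$poisson)
            im <- matrix(rpois(length(im), pmax(im, 0)), nrow(im), ncol(im))
          if (spec$noise_sigma > 0)
            im <- im + rnorm(length(im), 0, spec$noise_sigma)
          pmax(im, 0)  # camera counts cannot go negative
        })
        st
      })
    })
    stack_f0 <- noisy[[1]]; stack_fn <- noisy[[2]]
  }
  list(stack_f0 = stack_f0, stack_fn = stack_fn, truth = truth, spec = spec)
}

#' Run the full SFDI processing pipeline
#'
#' Demodulate, calibrate and invert a synthetic or stored acquisition:
#' the planar amplitude is taken as the three-phase mean of the modulated
#' stack and the modulation amplitude from the standard three-phase
#' formula; both are calibrated against the reference acquisition via the
#' forward-modelled phantom reflectance; the chosen inverse model then
#' produces per-pixel property maps and a per-region statistics report.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{`sample`, `reference`}{[phase_stack()] objects or paths to
#'       multi-page TIFF stacks written by [write_phase_stack()]; the
#'       modulated (`fx = fx_n`) stacks of the sample and the calibration
#'       phantom.}
#'     \item{`model`}{an `sfdi_inverse` object or artifact path.}
#'     \item{`forward`}{forward-model object or artifact path, used for
#'       calibration.}
#'     \item{`ref_props`}{reference-phantom properties (default: the
#'       bundled silicone phantom, `mu_a = 0.0117`,
#'       `mu_s_prime = 1.0827` mm^-1).}
#'     \item{`regions`}{optional named list of `list(rows, cols)` pixel
#'       ranges over which means and standard deviations are reported.}
#'     \item{`out_dir`}{optional output directory; property maps are
#'       written as float TIFF and the report as CSV and JSON.}
#'   }
#' @return A list with `maps` (`mu_a`, `mu_s_prime`, `status`), the
#'   calibrated `R0` and `Rn` maps, and `report` (per-region data frame,
#'   `NULL` when no regions are given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(x, what) {
    if (is.null(x)) stop("pipeline config is missing the ", what, " entry")
    x
  }
  as_stack <- function(x) {
    if (inherits(x, "phase_stack")) return(x)
    if (!file.exists(x)) stop("stack file not found: ", x)
    read_phase_stack(x)
  }
  as_obj <- function(x, classes) {
    if (inherits(x, classes)) return(x)
    if (!is.character(x) || !file.exists(x))
      stop("expected an object of class ", paste(classes, collapse = "/"),
           " or an existing artifact path")
    load_artifact(x)
  }
  sample <- as_stack(need(config$sample, "sample stack"))
  reference <- as_stack(need(config$reference, "reference stack"))
  model <- as_obj(need(config$model, "inverse model"), "sfdi_inverse")
  forward <- as_obj(need(config$forward, "forward model"), "sfdi_forward")
  ref_props <- if (is.null(config$ref_props))
    list(mu_a = 0.0117, mu_s_prime = 1.0827) else config$ref_props
  fx_n <- sample$spatial_frequency

  cal0 <- calibrate(demodulate_dc(sample), demodulate_dc(reference),
                    ref_props, fx = 0, forward = forward)
  caln <- calibrate(demodulate_ac(sample), demodulate_ac(reference),
                    ref_props, fx = fx_n, forward = forward)
  maps <- predict(model, cal0$R, caln$R)
  # demodulation/calibration flags propagate into the property maps
  pre_bad <- cal0$status == 2L | caln$status == 2L
  maps$status[pre_bad] <- 2L

  report <- NULL
  if (!is.null(config$regions)) {
    rows <- lapply(names(config$regions), function(nm) {
      rg <- config$regions[[nm]]
      sel_r <- rg$rows[1]:rg$rows[2]; sel_c <- rg$cols[1]:rg$cols[2]
      ma <- maps$mu_a[sel_r, sel_c]; ms <- maps$mu_s_prime[sel_r, sel_c]
      st <- maps$status[sel_r, sel_c]
      ok <- st == 0L
      data.frame(region = nm, n_pixels = length(ma),
                 flagged_fraction = mean(!ok),
                 mean_mu_a = mean(ma[ok]), sd_mu_a = sd(ma[ok]),
                 mean_mu_s_prime = mean(ms[ok]),
                 sd_mu_s_prime = sd(ms[ok]))
    })
    report <- do.call(rbind, rows)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map_tiff(maps$mu_a, file.path(config$out_dir, "mu_a.tif"),
                   meta = list(units = "mm^-1"))
    write_map_tiff(maps$mu_s_prime,
                   file.path(config$out_dir, "mu_s_prime.tif"),
                   meta = list(units = "mm^-1"))
    if (!is.null(report)) {
      write.csv(report, file.path(config$out_dir, "report.csv"),
                row.names = FALSE)
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
  }
  list(maps = maps, R0 = cal0$R, Rn = caln$R, report = report)
}
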