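#' Save and load package artifacts
#'
#' Histograms, forward tables, lookup tables and fitted inverse models are
#' persisted as versioned archives: the object is wrapped together with a
#' format tag, a format version and its class before serialization, and
#' loading refuses archives whose format version does not match, so stale
#' artifacts fail loudly instead of silently misbehaving.
#'
#' @param object object to persist.
#' @param path file path (conventionally `.rds`).
#' @return `save_artifact()` returns `path` invisibly; `load_artifact()`
#'   returns the stored object.
#' @export
save_artifact <- function(object, path) {
  saveRDS(list(format = "sfdiops-artifact", version = 1L,
               class = class(object), created = format(Sys.time()),
               object = object), path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "sfdiops-artifact"))
    stop("not an sfdiops artifact: ", path)
  if (!identical(x$version, 1L))
    stop("unsupported artifact format version ", x$version, " in ", path)
  x$object
}

# TIFF is written as 32-bit float in [0, 1] (the writer clamps anything
# outside); values are divided by a scale recorded in a YAML sidecar so
# maps in physical units (mm^-1, camera counts) survive the round trip.
.sidecar <- function(path) paste0(path, ".yml")

#' Write and read 32-bit float TIFF maps with a metadata sidecar
#'
#' Reflectance and property maps are stored as single-channel 32-bit float
#' TIFF.  Because the TIFF writer stores normalized intensities, each map
#' is divided by a scale factor (its maximum, or 1 if already within
#' `[0, 1]`) recorded in a `<path>.yml` sidecar along with any extra
#' metadata; reading restores physical units.  Non-finite pixels are
#' stored as zero with their indices recorded in the sidecar, and restored
#' to `NA`.
#'
#' @param map numeric matrix.
#' @param path output TIFF path.
#' @param meta named list of additional metadata for the sidecar.
#' @return `write_map_tiff()` returns `path` invisibly; `read_map_tiff()`
#'   returns the matrix with its sidecar metadata in `attr(, "meta")`.
#' @export
write_map_tiff <- function(map, path, meta = list()) {
  finite <- is.finite(map)
  scale <- max(c(map[finite], 1))
  out <- map / scale
  out[!finite] <- 0
  tiff::writeTIFF(out, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(c(list(scale = scale,
                          na_indices = as.integer(which(!finite))), meta),
                   .sidecar(path))
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  meta <- if (file.exists(.sidecar(path))) yaml::read_yaml(.sidecar(path))
          else list(scale = 1)
  m <- m * meta$scale
  if (length(meta$na_indices)) m[unlist(meta$na_indices)] <- NA_real_
  attr(m, "meta") <- meta
  m
}

#' Write and read a three-phase stack as a multi-page TIFF
#'
#' The three phase images are stored as pages of one 32-bit float TIFF,
#' normalized by a common scale recorded in the YAML sidecar together with
#' the spatial frequency, pixel pitch and phase list.
#'
#' @param stack a [phase_stack()].
#' @param path output TIFF path.
#' @return `write_phase_stack()` returns `path` invisibly;
#'   `read_phase_stack()` returns a [phase_stack()].
#' @export
write_phase_stack <- function(stack, path) {
  stopifnot(inherits(stack, "phase_stack"))
  scale <- max(unlist(lapply(stack$images, max)), 1)
  tiff::writeTIFF(lapply(stack$images, function(m) m / scale), path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(scale = scale,
                        spatial_frequency = stack$spatial_frequency,
                        pixel_pitch = stack$pixel_pitch,
                        phases = stack$phases), .sidecar(path))
  invisible(path)
}

#' @rdname write_phase_stack
#' @export
read_phase_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != 3) stop("expected a three-page TIFF: ", path)
  if (!file.exists(.sidecar(path)))
    stop("missing sidecar metadata file: ", .sidecar(path))
  meta <- yaml::read_yaml(.sidecar(path))
  phase_stack(lapply(pages, function(m) m * meta$scale),
              spatial_frequency = meta$spatial_frequency,
              pixel_pitch = meta$pixel_pitch,
              phases = unlist(meta$phases))
}
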