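#' Mean relative error of estimated optical properties
#'
#' `mean(|pred - truth| / truth) * 100`, computed separately for `mu_a` and
#' `mu_s_prime`.  Because the sampled domain includes `mu_a = 0`, where a
#' relative error is undefined, samples with true `mu_a` below `floor_mu_a`
#' are excluded from the absorption metric and the excluded fraction is
#' reported.  Samples flagged invalid (status 2) or with non-finite
#' predictions are likewise excluded and reported.  The metric is
#' scale-free: rescaling predictions and truth together leaves it
#' unchanged.
#'
#' @param pred prediction, as returned by `predict()` on an `sfdi_inverse`
#'   model: a list with `mu_a`, `mu_s_prime` and optionally `status`.
#' @param truth ground truth in the same format (a data frame with `mu_a`
#'   and `mu_s_prime` columns also works).
#' @param floor_mu_a exclusion floor for the absorption metric, mm^-1.
#' @return An object of class `sfdi_error`: percentages `mu_a_pct` and
#'   `mu_s_prime_pct`, evaluated counts, and `excluded_fraction_mu_a`.
#' @export
mean_relative_error <- function(pred, truth, floor_mu_a = 1e-3) {
  pa <- as.numeric(pred$mu_a); ps <- as.numeric(pred$mu_s_prime)
  ta <- as.numeric(truth$mu_a); ts <- as.numeric(truth$mu_s_prime)
  if (length(pa) != length(ta) || length(ps) != length(ts))
    stop("prediction and truth must have matching lengths")
  if (any(ts <= 0)) stop("true mu_s_prime must be strictly positive")
  valid <- if (!is.null(pred$status)) as.numeric(pred$status) != 2
           else rep(TRUE, length(pa))

  ok_a <- valid & is.finite(pa) & ta >= floor_mu_a
  ok_s <- valid & is.finite(ps)
  if (!any(ok_a) || !any(ok_s))
    stop("no evaluable samples after exclusions")
  structure(list(
    mu_a_pct = mean(abs(pa[ok_a] - ta[ok_a]) / ta[ok_a]) * 100,
    mu_s_prime_pct = mean(abs(ps[ok_s] - ts[ok_s]) / ts[ok_s]) * 100,
    n_mu_a = sum(ok_a), n_mu_s_prime = sum(ok_s),
    excluded_fraction_mu_a = 1 - sum(ok_a) / length(ta),
    floor_mu_a = floor_mu_a), class = "sfdi_error")
}

#' @export
print.sfdi_error <- function(x, ...) {
  cat(sprintf(
    "Mean relative error: mu_a %.4g%% (n = %d, %.2f%% excluded below %g), mu_s' %.4g%% (n = %d)\n",
    x$mu_a_pct, x$n_mu_a, 100 * x$excluded_fraction_mu_a, x$floor_mu_a,
    x$mu_s_prime_pct, x$n_mu_s_prime))
  invisible(x)
}

#' Benchmark inversion back-ends on a common test set
#'
#' Runs each fitted inverse model on the reflectance pairs of an
#' independent test set and tabulates per-parameter mean relative errors,
#' mirroring the simulation-validation comparison of the four back-ends
#' (diffusion, dense LUT, low-resolution LUT, random forest).
#'
#' @param models named list of `sfdi_inverse` objects.
#' @param test_set an [generate_training_set()] result generated with a
#'   seed distinct from any training seed.
#' @param floor_mu_a exclusion floor passed to [mean_relative_error()].
#' @return A `data.frame` with one row per method: errors in percent,
#'   evaluated counts, excluded fraction and flagged-pixel fraction.
#' @export
benchmark_methods <- function(models, test_set, floor_mu_a = 1e-3) {
  out <- data.frame(method = character(0), mu_a_pct = numeric(0),
                    mu_s_prime_pct = numeric(0), n_mu_a = integer(0),
                    excluded_fraction_mu_a = numeric(0),
                    flagged_fraction = numeric(0))
  for (nm in names(models)) {
    pred <- predict(models[[nm]], test_set$R0, test_set$Rn)
    err <- mean_relative_error(pred, test_set, floor_mu_a)
    out <- rbind(out, data.frame(
      method = nm, mu_a_pct = err$mu_a_pct,
      mu_s_prime_pct = err$mu_s_prime_pct, n_mu_a = err$n_mu_a,
      excluded_fraction_mu_a = err$excluded_fraction_mu_a,
      flagged_fraction = mean(as.numeric(pred$status) != 0)))
  }
  rownames(out) <- NULL
  out
}

#' Percentage difference between two property maps
#'
#' `100 * (map - reference) / reference`, the per-pixel percentage error
#' map used to compare inversion methods against a reference method.
#'
#' @param map,reference equal-shape numeric maps.
#' @return Matrix (or vector) of percentage differences.
#' @export
percentage_difference_map <- function(map, reference) {
  if (!identical(dim(map), dim(reference)))
    stop("maps must share dimensions")
  100 * (map - reference) / reference
}
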