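#' Generate a simulated training (or test) set for the inverse problem
#'
#' Samples `n` optical-property pairs uniformly at random over the
#' supported domain `mu_a in [0, 2]`, `mu_s_prime in [0.01, 15]` mm^-1 and
#' attaches the forward-modelled diffuse reflectance at `fx = 0` and
#' `fx = fx_n`.  Reproducible bit-for-bit for a given seed; the production-scale
#' configuration uses `n = 1e6`.
#'
#' @param forward forward-model handle (see [reflectance()]).
#' @param n number of property pairs (>= 1).
#' @param fx_n modulated spatial frequency, mm^-1.
#' @param seed integer seed for the sampling.
#' @return A `data.frame` of class `sfdi_training_set` with columns `mu_a`,
#'   `mu_s_prime`, `R0`, `Rn`; sampling metadata in attributes.
#' @export
generate_training_set <- function(forward, n, fx_n = 0.2, seed = 1L) {
  stopifnot(n >= 1)
  props <- .with_seed(seed, {
    data.frame(mu_a = runif(n, .domain$mu_a[1], .domain$mu_a[2]),
               mu_s_prime = runif(n, .domain$mu_s_prime[1],
                                  .domain$mu_s_prime[2]))
  })
  props$R0 <- reflectance(forward, props$mu_a, props$mu_s_prime, 0)
  props$Rn <- reflectance(forward, props$mu_a, props$mu_s_prime, fx_n)
  structure(props, seed = as.integer(seed), fx_n = fx_n,
            forward_class = class(forward)[1],
            class = c("sfdi_training_set", "data.frame"))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Fit the random-forest inverse model
#'
#' Trains an ensemble of regression trees mapping diffuse reflectance
#' `(R0, Rn)` to optical properties `(mu_a, mu_s_prime)` on a simulated
#' training set.  One forest is fitted per target parameter with the
#' recorded hyperparameters (defaults: 15 trees, minimum terminal-node
#' size 2, all features considered at each split, bootstrap resampling),
#' single-threaded so that a given `seed` reproduces the model exactly.
#'
#' @param training_set an [generate_training_set()] result, or any data
#'   frame with columns `R0`, `Rn`, `mu_a`, `mu_s_prime`.
#' @param n_trees number of trees per forest.
#' @param min_leaf minimum number of samples in a terminal node.
#' @param seed integer seed for the tree randomness.
#' @return An object of class `c("sfdi_rfr", "sfdi_inverse")`.
#' @seealso [predict.sfdi_rfr()], [sfdi_inverse()]
#' @export
fit_rfr <- function(training_set, n_trees = 15L, min_leaf = 2L, seed = 1L) {
  req <- c("R0", "Rn", "mu_a", "mu_s_prime")
  if (!all(req %in% names(training_set)))
    stop("training set must have columns R0, Rn, mu_a, mu_s_prime")
  if (nrow(training_set) < 1) stop("training set is empty")
  x <- training_set[, c("R0", "Rn")]
  const_in <- all(x$R0 == x$R0[1]) && all(x$Rn == x$Rn[1])
  const_out <- all(training_set$mu_a == training_set$mu_a[1]) &&
    all(training_set$mu_s_prime == training_set$mu_s_prime[1])
  if (const_in && !const_out)
    stop("degenerate training set: constant reflectance inputs with ",
         "varying targets cannot be inverted")
  fit1 <- function(y, s) {
    ranger::ranger(y = y, x = x, num.trees = n_trees, mtry = 2L,
                   min.bucket = min_leaf, replace = TRUE,
                   sample.fraction = 1, num.threads = 1L, seed = s,
                   oob.error = TRUE)
  }
  forest_a <- fit1(training_set$mu_a, seed)
  forest_s <- fit1(training_set$mu_s_prime, seed + 1L)
  structure(list(
    forest_mu_a = forest_a, forest_mu_s_prime = forest_s,
    n_trees = n_trees, min_leaf = min_leaf, seed = as.integer(seed),
    n_train = nrow(training_set),
    training_seed = attr(training_set, "seed"),
    fx_n = attr(training_set, "fx_n"),
    forward_class = attr(training_set, "forward_class"),
    input_range = list(R0 = range(x$R0), Rn = range(x$Rn))),
    class = c("sfdi_rfr", "sfdi_inverse"))
}

#' Predict optical properties with a fitted inverse model
#'
#' Vectorized per-pixel prediction of `(mu_a, mu_s_prime)` from calibrated
#' reflectance maps; megapixel maps are processed in one call.  Non-finite
#' inputs are flagged invalid; predictions falling outside the supported
#' property domain are clipped to it and flagged out-of-domain (tree
#' ensembles average training targets, so this only occurs for degenerate
#' models).
#'
#' @param object a fitted `sfdi_rfr`.
#' @param R0,Rn reflectance maps (equal-shape vectors or matrices).
#' @param ... unused.
#' @return A list with `mu_a`, `mu_s_prime` (mm^-1) and integer `status`
#'   (0 ok, 1 out-of-domain, 2 invalid input), each shaped like `R0`.
#' @export
predict.sfdi_rfr <- function(object, R0, Rn, ...) {
  if (length(R0) != length(Rn)) stop("R0 and Rn must have equal length")
  ok <- is.finite(R0) & is.finite(Rn)
  newdata <- data.frame(R0 = as.numeric(R0)[ok], Rn = as.numeric(Rn)[ok])
  mu_a <- mu_s <- rep(NA_real_, length(R0))
  status <- integer(length(R0))
  status[!ok] <- 2L
  if (nrow(newdata)) {
    mu_a[ok] <- predict(object$forest_mu_a, newdata,
                        num.threads = 1L)$predictions
    mu_s[ok] <- predict(object$forest_mu_s_prime, newdata,
                        num.threads = 1L)$predictions
    out <- ok & (mu_a < .domain$mu_a[1] | mu_a > .domain$mu_a[2] |
                   mu_s < .domain$mu_s_prime[1] |
                   mu_s > .domain$mu_s_prime[2])
    mu_a[out] <- pmin(pmax(mu_a[out], .domain$mu_a[1]), .domain$mu_a[2])
    mu_s[out] <- pmin(pmax(mu_s[out], .domain$mu_s_prime[1]),
                      .domain$mu_s_prime[2])
    status[out] <- 1L
  }
  shape <- function(v) { dim(v) <- dim(R0); v }
  list(mu_a = shape(mu_a), mu_s_prime = shape(mu_s),
       status = shape(status))
}

#' @export
print.sfdi_rfr <- function(x, ...) {
  cat("Random-forest SFDI inverse model\n")
  cat(sprintf("  %d trees per target, min leaf %d, trained on %d pairs\n",
              x$n_trees, x$min_leaf, x$n_train))
  cat(sprintf("  fx_n = %s mm^-1   forward: %s   seeds: train %s / trees %d\n",
              format(x$fx_n), x$forward_class,
              format(x$training_seed), x$seed))
  invisible(x)
}

#' @export
summary.sfdi_rfr <- function(object, ...) {
  cat("Random-forest SFDI inverse model\n")
  cat(sprintf("  training pairs: %d   trees: %d   min leaf: %d\n",
              object$n_train, object$n_trees, object$min_leaf))
  cat(sprintf("  out-of-bag MSE: mu_a %.3g, mu_s' %.3g (mm^-2)\n",
              object$forest_mu_a$prediction.error,
              object$forest_mu_s_prime$prediction.error))
  cat(sprintf("  input ranges seen: R0 [%.4f, %.4f], Rn [%.4f, %.4f]\n",
              object$input_range$R0[1], object$input_range$R0[2],
              object$input_range$Rn[1], object$input_range$Rn[2]))
  invisible(object)
}
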