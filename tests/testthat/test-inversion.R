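test_that("a degenerate 2 x 2 table equals direct forward evaluations", {
  fwd <- test_forward()
  lut <- build_forward_lut(fwd, 2, 2, fx_n = 0.2)
  corners <- expand.grid(mu_a = c(0, 2), mu_s_prime = c(0.01, 15))
  expect_equal(as.numeric(lut$R0),
               reflectance(fwd, corners$mu_a, corners$mu_s_prime, 0))
  expect_equal(as.numeric(lut$Rn),
               reflectance(fwd, corners$mu_a, corners$mu_s_prime, 0.2))
})

test_that("the built table is monotone and physically ordered", {
  lut <- test_lut()
  expect_true(all(is.finite(lut$R0)) && all(is.finite(lut$Rn)))
  expect_true(all(lut$R0 >= lut$Rn))
  # along each mu_a row (excluding the constant mu_a = 0 row) R0 and Rn
  # decrease; along each mu_s' column they increase
  expect_true(all(apply(lut$R0[-1, ], 2, function(v) all(diff(v) < 0))))
  # Rn decreases strictly until it underflows towards zero at high mu_a
  expect_true(all(apply(lut$Rn[-1, ], 2,
                        function(v) all(diff(v) < 0 | v[-1] < 1e-10))))
  expect_true(all(apply(lut$Rn, 1, function(v) all(diff(v) > 0))))
})

test_that("grid nodes are recovered exactly by inverse interpolation", {
  lut <- test_lut()
  for (ij in list(c(2, 2), c(50, 120), c(101, 51), c(199, 199))) {
    inv <- lut_invert(lut, lut$R0[ij[1], ij[2]], lut$Rn[ij[1], ij[2]])
    expect_equal(inv$mu_a, lut$mu_a_axis[ij[1]], tolerance = 1e-8)
    expect_equal(inv$mu_s_prime, lut$mu_s_axis[ij[2]], tolerance = 1e-8)
    expect_equal(inv$status, 0L)
  }
})

test_that("off-grid queries are recovered to within one grid cell", {
  fwd <- test_forward()
  lut <- test_lut()
  h_a <- diff(lut$mu_a_axis[1:2])
  h_s <- diff(lut$mu_s_axis[1:2])
  set.seed(4)
  mua <- runif(200, 0.02, 1.98)
  mus <- runif(200, 0.1, 14.8)
  inv <- lut_invert(lut, reflectance(fwd, mua, mus, 0),
                    reflectance(fwd, mua, mus, 0.2))
  expect_true(all(inv$status == 0))
  # within one grid-cell diameter in (normalized) property space
  d <- sqrt(((inv$mu_a - mua) / h_a)^2 + ((inv$mu_s_prime - mus) / h_s)^2)
  expect_true(all(d <= sqrt(2)))
  expect_lt(median(d), 0.1)
})

test_that("degenerate and invalid reflectance inputs are flagged per pixel", {
  lut <- test_lut()
  zero <- lut_invert(lut, matrix(0, 3, 3), matrix(0, 3, 3))
  expect_true(all(zero$status == 1L))
  bad <- lut_invert(lut, c(NA, Inf, 0.3), c(0.1, 0.1, NaN))
  expect_equal(bad$status, c(2L, 2L, 2L))
  expect_true(all(is.na(bad$mu_a)))
})

test_that("training sets are reproducible, in range, and uniform", {
  fwd <- test_forward()
  t1 <- generate_training_set(fwd, 10, seed = 5)
  t2 <- generate_training_set(fwd, 10, seed = 5)
  t3 <- generate_training_set(fwd, 10, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1$mu_a, t3$mu_a))
  expect_true(all(t1$mu_a >= 0 & t1$mu_a <= 2))
  expect_true(all(t1$mu_s_prime >= 0.01 & t1$mu_s_prime <= 15))
  # marginal KS distance from uniform at n = 1e5 below 0.01
  tb <- generate_training_set(fwd, 1e5, seed = 11)
  ks <- function(x, lo, hi) {
    u <- sort((x - lo) / (hi - lo))
    n <- length(u)
    max(abs(u - (seq_len(n) - 0.5) / n)) + 0.5 / n
  }
  expect_lt(ks(tb$mu_a, 0, 2), 0.01)
  expect_lt(ks(tb$mu_s_prime, 0.01, 15), 0.01)
})

test_that("degenerate training sets behave as specified", {
  # one repeated point: constant model predicting that point's targets
  one <- data.frame(R0 = rep(0.4, 20), Rn = rep(0.1, 20),
                    mu_a = rep(0.3, 20), mu_s_prime = rep(2.5, 20))
  m <- fit_rfr(one, seed = 1)
  p <- predict(m, c(0.4, 0.9), c(0.1, 0.05))
  expect_equal(p$mu_a, c(0.3, 0.3))
  expect_equal(p$mu_s_prime, c(2.5, 2.5))
  # constant inputs with varying targets cannot be inverted
  bad <- data.frame(R0 = rep(0.4, 20), Rn = rep(0.1, 20),
                    mu_a = runif(20), mu_s_prime = runif(20, 1, 5))
  expect_error(fit_rfr(bad), "degenerate")
})

test_that("the forest recalls its training data better than held-out data", {
  fwd <- test_forward()
  ts <- generate_training_set(fwd, 5e3, seed = 10)
  held <- generate_training_set(fwd, 5e3, seed = 20)
  m <- fit_rfr(ts, seed = 30)
  err_train <- mean_relative_error(predict(m, ts$R0, ts$Rn), ts)
  err_held <- mean_relative_error(predict(m, held$R0, held$Rn), held)
  expect_lt(err_train$mu_a_pct, err_held$mu_a_pct)
  expect_lt(err_train$mu_s_prime_pct, err_held$mu_s_prime_pct)
})

test_that("per-pixel inversion is permutation-equivariant and shape-preserving", {
  fwd <- test_forward()
  lut <- test_lut()
  m <- fit_rfr(generate_training_set(fwd, 2e3, seed = 2), seed = 3)
  set.seed(8)
  r0 <- reflectance(fwd, runif(40, 0.05, 1.5), runif(40, 0.5, 10), 0)
  rn <- r0 * runif(40, 0.1, 0.5)
  perm <- sample(40)
  for (model in list(lut, m)) {
    p1 <- predict(model, r0, rn)
    p2 <- predict(model, r0[perm], rn[perm])
    expect_equal(p2$mu_a, p1$mu_a[perm])
    expect_equal(p2$mu_s_prime, p1$mu_s_prime[perm])
  }
  pm <- predict(m, matrix(r0, 5, 8), matrix(rn, 5, 8))
  expect_equal(dim(pm$mu_a), c(5L, 8L))
})

test_that("the error metric follows its closed-form cases", {
  t1 <- list(mu_a = 1, mu_s_prime = 2)
  expect_equal(mean_relative_error(t1, t1)$mu_a_pct, 0)
  e <- mean_relative_error(list(mu_a = 1.1, mu_s_prime = 2.2),
                           list(mu_a = 1, mu_s_prime = 2))
  expect_equal(e$mu_a_pct, 10)
  expect_equal(e$mu_s_prime_pct, 10)
  e2 <- mean_relative_error(list(mu_a = c(1.01, 2.06), mu_s_prime = c(1, 1)),
                            list(mu_a = c(1, 2), mu_s_prime = c(1, 1)))
  expect_equal(e2$mu_a_pct, 2)
  # scale invariance
  p <- list(mu_a = c(0.11, 0.5), mu_s_prime = c(1.2, 3))
  t <- list(mu_a = c(0.1, 0.52), mu_s_prime = c(1.1, 3.3))
  scale3 <- function(l) lapply(l, `*`, 3)
  expect_equal(mean_relative_error(scale3(p), scale3(t))$mu_a_pct,
               mean_relative_error(p, t)$mu_a_pct)
  # near-zero absorption exclusion is applied and reported
  e3 <- mean_relative_error(list(mu_a = c(0.5, 0.1), mu_s_prime = c(1, 1)),
                            list(mu_a = c(1e-5, 0.1), mu_s_prime = c(1, 1)))
  expect_equal(e3$n_mu_a, 1L)
  expect_equal(e3$excluded_fraction_mu_a, 0.5)
  expect_equal(e3$mu_a_pct, 0)
  expect_error(mean_relative_error(
    list(mu_a = 1, mu_s_prime = 1), list(mu_a = 1e-6, mu_s_prime = 1),
    floor_mu_a = 1e-3), "no evaluable")
})

test_that("the benchmark table compares methods on a common footing", {
  expect_equal(nrow(benchmark_methods(list(), NULL)), 0L)
  fwd <- test_forward()
  test <- generate_training_set(fwd, 3e3, seed = 77)
  models <- list(
    lut = test_lut(),
    lut_low = build_forward_lut(fwd, 40, 40),
    rfr = fit_rfr(generate_training_set(fwd, 2e4, seed = 5), seed = 6))
  tab <- benchmark_methods(models, test)
  expect_equal(tab$method, c("lut", "lut_low", "rfr"))
  expect_true(all(is.finite(tab$mu_a_pct)))
  # denser tables invert more accurately
  expect_lt(tab$mu_a_pct[1], tab$mu_a_pct[2])
  expect_lt(tab$mu_s_prime_pct[1], tab$mu_s_prime_pct[2])
})

test_that("constant megapixel maps invert to constant maps end-to-end", {
  fwd <- test_forward()
  lut <- test_lut()
  r <- reflectance(fwd, 0.05, 1.2, c(0, 0.2))
  R0 <- matrix(r[1], 1000, 1000)
  Rn <- matrix(r[2], 1000, 1000)
  out <- predict(lut, R0, Rn)
  expect_equal(dim(out$mu_a), c(1000L, 1000L))
  expect_equal(range(out$mu_a)[1], range(out$mu_a)[2])
  expect_lt(abs(out$mu_a[1] - 0.05), 0.01)
  expect_lt(abs(out$mu_s_prime[1] / 1.2 - 1), 0.02)
})
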