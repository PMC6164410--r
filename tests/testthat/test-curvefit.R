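test_that("normalize_time spans [0, 1] uniformly and rejects singletons", {
  xy <- normalize_time(rep(0, 11))
  expect_equal(xy$x, seq(0, 1, by = 0.1))
  expect_equal(normalize_time(c(1, 2))$x, c(0, 1))
  xy2 <- normalize_time(stats::rnorm(57))
  expect_equal(range(xy2$x), c(0, 1))
  expect_error(normalize_time(5), "at least 2")
})

test_that("compute_r_squared matches the closed-form cases", {
  y <- c(0, 1, 2)
  expect_identical(compute_r_squared(y, y), 1)
  expect_equal(compute_r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(compute_r_squared(y, c(2, 2, 2)), -1.5)
  # constant series: perfect fit vs any other fit
  expect_equal(compute_r_squared(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(compute_r_squared(c(5, 5, 5), c(5, 6, 5)), 0)
})

test_that("a straight line is interpolated exactly at degree 1", {
  x <- seq(0, 1, by = 0.1)
  fit <- fit_polynomial(x, 2 * x + 1, 1)
  expect_equal(unname(fit$coefficients), c(2, 1), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("polynomial fits equal the normal-equations oracle on 100 random instances", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(15:60, 1)
    # low degrees keep the explicit normal equations themselves accurate
    degree <- sample(1:3, 1)
    x <- sort(stats::runif(n))
    y <- stats::rnorm(n, sd = 2) +
      drop(outer(x, degree:0, `^`) %*% stats::runif(degree + 1, -2, 2))
    fit <- fit_polynomial(x, y, degree)
    expect_equal(unname(fit$coefficients), polyfit_oracle(x, y, degree),
                 tolerance = 1e-8)
  }
})

test_that("symmetric quadratic has near-zero slope at degree 1, R^2 as by the oracle", {
  # x symmetric about 0.5 (mapped from [-1, 1]); y = (2x-1)^2 is even around 0.5
  x <- (seq(-1, 1, length.out = 41) + 1) / 2
  y <- (2 * x - 1)^2
  fit <- fit_polynomial(x, y, 1)
  expect_lt(abs(fit$coefficients[["p1"]]), 1e-10)
  oracle <- polyfit_oracle(x, y, 1)
  y_hat <- oracle[1] * x + oracle[2]
  expect_equal(fit$r_squared, compute_r_squared(y, y_hat), tolerance = 1e-12)
})

test_that("training R^2 never decreases with polynomial degree", {
  set.seed(7)
  for (k in 1:5) {
    x <- seq(0, 1, length.out = 80)
    y <- stats::rnorm(80) + 3 * sin(5 * x)
    r2 <- vapply(1:9, function(d) fit_polynomial(x, y, d)$r_squared,
                 numeric(1))
    expect_true(all(diff(r2) >= -1e-10))
    expect_true(all(r2 <= 1))
  }
})

test_that("a single clean Gaussian peak is recovered to 1e-4", {
  x <- seq(0, 1, length.out = 200)
  y <- 2 * exp(-((x - 0.5) / 0.1)^2)
  fit <- fit_gaussian(x, y, 1)
  expect_equal(unname(fit$coefficients), c(2, 0.5, 0.1), tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  expect_true(fit$converged)
})

test_that("two well-separated peaks match a 20-restart multi-start oracle", {
  x <- seq(0, 1, length.out = 400)
  true_par <- c(1.5, 0.25, 0.05, -0.8, 0.75, 0.08)
  model <- function(p, x) {
    p[1] * exp(-((x - p[2]) / p[3])^2) + p[4] * exp(-((x - p[5]) / p[6])^2)
  }
  y <- model(true_par, x)
  fit <- fit_gaussian(x, y, 2)
  oracle <- multistart_oracle(model, x, y, true_par)
  # canonicalize component order by centroid
  sort_triples <- function(p) {
    tr <- matrix(p, nrow = 3)
    as.numeric(tr[, order(tr[2, ])])
  }
  expect_equal(sort_triples(unname(fit$coefficients)), sort_triples(oracle),
               tolerance = 1e-3)
})

test_that("a monotone ramp yields a returned Gaussian fit with low R^2, no error", {
  x <- seq(0, 1, length.out = 120)
  fit <- fit_gaussian(x, x, 1)
  expect_s3_class(fit, "curve_fit")
  expect_true(is.finite(fit$r_squared))
  expect_lte(fit$r_squared, 1)
})

test_that("a one-harmonic signal is recovered to 1e-3 including the frequency", {
  x <- (0:255) / 256
  y <- 1 + 0.5 * cos(2 * pi * x) - 0.25 * sin(2 * pi * x)
  fit <- fit_fourier(x, y, 1)
  cf <- fit$coefficients
  expect_equal(cf[["a0"]], 1, tolerance = 1e-3)
  expect_equal(cf[["a1"]], 0.5, tolerance = 1e-3)
  expect_equal(cf[["b1"]], -0.25, tolerance = 1e-3)
  expect_equal(cf[["w"]], 2 * pi, tolerance = 1e-3)
})

test_that("a two-harmonic signal matches a brute-force frequency-grid oracle", {
  x <- (0:511) / 512
  omega_true <- 2 * pi * 1.3
  y <- 0.2 + cos(omega_true * x) - 0.4 * sin(omega_true * x) +
    0.3 * cos(2 * omega_true * x) + 0.15 * sin(2 * omega_true * x)
  fit <- fit_fourier(x, y, 2)

  lin_solve <- function(w) {
    X <- cbind(1, cos(w * x), sin(w * x), cos(2 * w * x), sin(2 * w * x))
    beta <- qr.coef(qr(X), y)
    list(beta = beta, ss = sum((y - X %*% beta)^2))
  }
  spec <- Mod(stats::fft(y - mean(y)))[2:256]
  w_hat <- 2 * pi * which.max(spec) * (511 / 512)
  grid <- seq(0.5 * w_hat, 2 * w_hat, length.out = 1000)
  ss <- vapply(grid, function(w) lin_solve(w)$ss, numeric(1))
  w_best <- grid[which.min(ss)]
  oracle <- c(lin_solve(w_best)$beta, w_best)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-3)
})

test_that("a constant series gives a0 = mean and the degenerate R^2 rule", {
  x <- seq(0, 1, length.out = 50)
  y <- rep(3.7, 50)
  fit <- fit_fourier(x, y, 1)
  expect_equal(fit$coefficients[["a0"]], 3.7, tolerance = 1e-8)
  expect_lt(abs(fit$coefficients[["a1"]]), 1e-8)
  expect_lt(abs(fit$coefficients[["b1"]]), 1e-8)
  expect_equal(fit$r_squared, 1) # zero residuals on zero-variance data
})

test_that("a clean one-term exponential is recovered to 1e-4", {
  x <- seq(0, 1, length.out = 100)
  fit <- fit_exponential(x, 5 * exp(-3 * x), 1)
  expect_equal(unname(fit$coefficients), c(5, -3), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("a two-term exponential matches a multi-start oracle to 1e-2", {
  x <- seq(0, 1, length.out = 200)
  true_par <- c(2, -1, 3, -10)
  model <- function(p, x) p[1] * exp(p[2] * x) + p[3] * exp(p[4] * x)
  y <- model(true_par, x)
  fit <- fit_exponential(x, y, 2)
  oracle <- multistart_oracle(model, x, y, true_par, spread = 0.3)
  sort_pairs <- function(p) {
    m <- matrix(p, nrow = 2)
    as.numeric(m[, order(m[2, ])])
  }
  expect_equal(sort_pairs(unname(fit$coefficients)), sort_pairs(oracle),
               tolerance = 1e-2)
})

test_that("sign-alternating data yields a finite exponential fit, no crash", {
  x <- seq(0, 1, length.out = 60)
  y <- rep(c(-1, 1), 30)
  fit <- fit_exponential(x, y, 2)
  expect_s3_class(fit, "curve_fit")
  expect_true(is.finite(fit$r_squared))
  expect_true(is.logical(fit$converged))
})

test_that("domain errors are raised for out-of-range orders", {
  x <- seq(0, 1, length.out = 30)
  y <- stats::rnorm(30)
  expect_error(fit_polynomial(x, y, 0), "\\[1, 9\\]")
  expect_error(fit_polynomial(x, y, 10), "\\[1, 9\\]")
  expect_error(fit_polynomial(x[1:3], y[1:3], 5), "points")
  expect_error(fit_gaussian(x, y, 5), "\\[1, 4\\]")
  expect_error(fit_fourier(x, y, 0), "\\[1, 4\\]")
  expect_error(fit_exponential(x, y, 3), "1 or 2")
})

test_that("fit_sweep covers the grid deterministically", {
  d <- tiny_signals()
  fits <- fit_sweep(d)
  expect_equal(nrow(fits), 3 * 19)
  poly_only <- fit_sweep(d, tibble::tibble(family = "polynomial", order = 1:9))
  expect_equal(nrow(poly_only), 3 * 9)
  expect_equal(max(lengths(poly_only$coefficients)), 10)
  again <- fit_sweep(d)
  expect_identical(fits$coefficients, again$coefficients)
  expect_error(
    fit_sweep(d, tibble::tibble(family = "polynomial", order = 10)),
    "out of bounds"
  )
})

test_that("tidy/glance/autoplot work on a curve fit", {
  x <- seq(0, 1, length.out = 30)
  fit <- fit_polynomial(x, x^2, 2)
  td <- tidy(fit)
  expect_equal(td$term, c("p1", "p2", "p3"))
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
})
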