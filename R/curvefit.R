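#' Map a series onto normalized time
#'
#' Every whole-series model is fitted on normalized time x in [0, 1] so that
#' coefficients are comparable across series of unequal duration and the
#' degree-9 Vandermonde stays well conditioned. Values are untouched.
#'
#' @param values Numeric vector of samples (length >= 2).
#' @return List with `x` (uniform grid from 0 to 1) and `y` (= `values`).
#' @export
normalize_time <- function(values) {
  if (length(values) < 2) {
    stop("need at least 2 samples to normalize time", call. = FALSE)
  }
  list(x = seq(0, 1, length.out = length(values)), y = as.numeric(values))
}

#' Coefficient of determination
#'
#' `1 - SSres / SStot` with `SStot` taken about `mean(y)`. Always <= 1 and
#' may be negative: a negative value means the model fits worse than the
#' horizontal mean line. A constant series (`SStot = 0`) yields 1 when the
#' residuals are numerically zero (perfect fit) and 0 otherwise, avoiding an
#' undefined 0/0.
#'
#' @param y Observed values.
#' @param y_hat Fitted values, same length.
#' @return A single real number in (-Inf, 1].
#' @export
compute_r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(if (ss_res <= 1e-12 * length(y)) 1 else 0)
  }
  1 - ss_res / ss_tot
}

new_curve_fit <- function(family, order, coefficients, x, y, y_hat,
                          converged = TRUE) {
  structure(
    list(family = family, order = as.integer(order),
         coefficients = coefficients,
         r_squared = compute_r_squared(y, y_hat),
         converged = isTRUE(converged),
         n_obs = length(y), fitted = y_hat, x = x, y = y),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> %s (order %d), n = %d, R^2 = %.4f%s\n",
              x$family, x$order, x$n_obs, x$r_squared,
              if (x$converged) "" else " (not converged)"))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_curve Tidy the coefficients of a fit into a tibble.
#' @param x A `curve_fit` object.
#' @param ... Unused.
#' @method tidy curve_fit
#' @export
tidy.curve_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn fit_curve One-row fit summary (family, order, R^2, convergence).
#' @method glance curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(family = x$family, order = x$order,
                 r.squared = x$r_squared, converged = x$converged,
                 nobs = x$n_obs)
}

#' @describeIn fit_curve Plot data and fitted curve.
#' @param object A `curve_fit` object.
#' @method autoplot curve_fit
#' @export
autoplot.curve_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "normalized time", y = "signal (mV)",
      title = sprintf("%s fit, order %d, R^2 = %.3f",
                      object$family, object$order, object$r_squared)
    )
}

#' Polynomial least-squares fit
#'
#' Fits `y = P1 x^n + ... + Pn x + P(n+1)` by QR-based linear least squares on
#' the Vandermonde matrix of normalized time. Degree is capped at 9 so the
#' feature space never exceeds 10 coefficients.
#'
#' @param x Predictor (normalized time in [0, 1]).
#' @param y Response (mV).
#' @param degree Polynomial degree, 1-9.
#' @return A `curve_fit` with coefficients `p1..p(degree+1)` in descending
#'   powers.
#' @export
fit_polynomial <- function(x, y, degree) {
  if (degree < 1 || degree > 9) {
    stop("polynomial degree must be in [1, 9]", call. = FALSE)
  }
  if (length(y) < degree + 1) {
    stop("need at least degree + 1 points", call. = FALSE)
  }
  stopifnot(length(x) == length(y))
  V <- outer(x, degree:0, `^`)
  coeffs <- qr.coef(qr(V), y)
  names(coeffs) <- paste0("p", seq_len(degree + 1))
  new_curve_fit("polynomial", degree, coeffs, x, y,
                drop(V %*% coeffs))
}

# 9-point centered moving average with edge shrinkage.
moving_average <- function(y, width = 9L) {
  half <- width %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Initial (a, b, c) triples for a sum-of-Gaussians fit: peaks are the n
# largest local maxima of the smoothed |y - median|, widths from
# half-prominence, amplitudes (signed) from the raw deviations at the peaks.
gaussian_init <- function(x, y, n_peaks) {
  dev <- y - stats::median(y)
  mag <- moving_average(abs(dev))
  n <- length(y)
  is_peak <- c(FALSE, mag[2:(n - 1)] >= mag[1:(n - 2)] &
                 mag[2:(n - 1)] >= mag[3:n], FALSE)
  is_peak[c(1, n)] <- c(mag[1] > mag[2], mag[n] > mag[n - 1])
  idx <- which(is_peak)
  if (length(idx) == 0) idx <- which.max(mag)
  idx <- idx[order(mag[idx], decreasing = TRUE)]
  # pad with quantile positions when fewer maxima than peaks requested
  if (length(idx) < n_peaks) {
    extra <- round(stats::quantile(seq_len(n),
                                   probs = seq(0.15, 0.85,
                                               length.out = n_peaks)))
    idx <- unique(c(idx, as.integer(extra)))
  }
  idx <- idx[seq_len(n_peaks)]
  span <- max(x) - min(x)
  params <- purrr::map(idx, function(i) {
    a <- dev[i]
    if (a == 0) a <- max(abs(dev)) * 1e-3 + 1e-6
    half_height <- abs(mag[i]) / 2
    left <- i; while (left > 1 && mag[left] > half_height) left <- left - 1
    right <- i; while (right < n && mag[right] > half_height) right <- right + 1
    width <- max(x[right] - x[left], span / n) / sqrt(log(2)) / 2
    c(a = unname(a), b = unname(x[i]), c = max(width, 1e-3 * span))
  })
  unlist(params)
}

gaussian_model <- function(par, x, n_peaks) {
  out <- numeric(length(x))
  for (i in seq_len(n_peaks)) {
    a <- par[3 * i - 2]; b <- par[3 * i - 1]; cc <- par[3 * i]
    out <- out + a * exp(-((x - b) / cc)^2)
  }
  out
}

# Levenberg-Marquardt driver shared by the nonlinear families; returns the
# solution with a convergence flag instead of failing (poor fits are data,
# not errors).
run_lm <- function(par, resid_fn, lower = NULL, upper = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-10,
                                     ptol = 1e-10)
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn,
                       lower = lower, upper = upper, control = ctrl),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(par = par, converged = FALSE))
  }
  list(par = res$par, converged = res$info %in% 1:4)
}

#' Sum-of-Gaussians fit
#'
#' Fits `y = sum_i a_i exp(-((x - b_i)/c_i)^2)` (1-4 peaks) by
#' Levenberg-Marquardt. Peaks are initialized at the largest local maxima of
#' the smoothed absolute deviation from the median, widths from
#' half-prominence; widths are constrained positive. Non-convergence is
#' flagged, never an error — on trend-like (non-peaky) series this family
#' legitimately fits poorly.
#'
#' @inheritParams fit_polynomial
#' @param n_peaks Number of Gaussian components, 1-4.
#' @return A `curve_fit` with coefficients `a1,b1,c1,...`.
#' @export
fit_gaussian <- function(x, y, n_peaks) {
  if (n_peaks < 1 || n_peaks > 4) {
    stop("number of Gaussian peaks must be in [1, 4]", call. = FALSE)
  }
  if (length(y) < 3 * n_peaks) {
    stop("need at least 3 points per peak", call. = FALSE)
  }
  par0 <- gaussian_init(x, y, n_peaks)
  lower <- rep(c(-Inf, -Inf, 1e-8), n_peaks)
  fit <- run_lm(par0, function(p) y - gaussian_model(p, x, n_peaks),
                lower = lower)
  coeffs <- fit$par
  names(coeffs) <- paste0(rep(c("a", "b", "c"), n_peaks),
                          rep(seq_len(n_peaks), each = 3))
  new_curve_fit("gaussian", n_peaks, coeffs, x, y,
                gaussian_model(fit$par, x, n_peaks), fit$converged)
}

# Linear coefficients (a0, a_i, b_i) and residual SS for a fixed fundamental
# frequency omega; the Fourier model is separable in its linear part.
fourier_linear <- function(x, y, n_terms, omega) {
  X <- cbind(1, do.call(cbind, purrr::map(seq_len(n_terms), function(i) {
    cbind(cos(i * omega * x), sin(i * omega * x))
  })))
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  y_hat <- drop(X %*% beta)
  list(beta = beta, y_hat = y_hat, ss = sum((y - y_hat)^2))
}

#' Truncated Fourier-series fit
#'
#' Fits `y = a0 + sum_i a_i cos(i w x) + b_i sin(i w x)` with the fundamental
#' frequency `w` free. The model is separable: for a fixed `w` the linear
#' coefficients come from least squares, and `w` itself is initialized at the
#' dominant nonzero discrete-Fourier bin and refined by bounded 1-D
#' minimization of the residual sum of squares over `[0.5 w0, 2 w0]`.
#'
#' @inheritParams fit_polynomial
#' @param n_terms Number of harmonics, 1-4.
#' @return A `curve_fit` with coefficients `a0,a1,b1,...,w` (frequency last,
#'   rad per unit of normalized time).
#' @export
fit_fourier <- function(x, y, n_terms) {
  if (n_terms < 1 || n_terms > 4) {
    stop("number of Fourier terms must be in [1, 4]", call. = FALSE)
  }
  if (length(y) < 2 * n_terms + 2) {
    stop("need at least 2 * n_terms + 2 points", call. = FALSE)
  }
  n <- length(y)
  span <- max(x) - min(x)
  spec <- Mod(stats::fft(y - mean(y)))[2:max(2, floor(n / 2))]
  k_dom <- if (all(spec < 1e-12)) 1L else which.max(spec)
  omega0 <- 2 * pi * k_dom / (span * n / (n - 1))
  opt <- stats::optimize(
    function(w) fourier_linear(x, y, n_terms, w)$ss,
    interval = c(0.5 * omega0, 2 * omega0), tol = 1e-10
  )
  omega <- opt$minimum
  lin <- fourier_linear(x, y, n_terms, omega)
  coeffs <- c(lin$beta, omega)
  names(coeffs) <- c("a0",
                     paste0(rep(c("a", "b"), n_terms),
                            rep(seq_len(n_terms), each = 2)),
                     "w")
  new_curve_fit("fourier", n_terms, coeffs, x, y, lin$y_hat, TRUE)
}

exponential_model <- function(par, x, n_terms) {
  out <- par[1] * exp(pmin(par[2] * x, 700))
  if (n_terms == 2) out <- out + par[3] * exp(pmin(par[4] * x, 700))
  out
}

# One-term init by log-linear regression on y shifted positive; two-term adds
# a second component at five times the fitted rate.
exponential_init <- function(x, y, n_terms) {
  shift <- if (min(y) <= 0) -min(y) + 0.05 * (diff(range(y)) + 1) else 0
  lf <- stats::lm.fit(cbind(1, x), log(y + shift))
  a0 <- exp(lf$coefficients[1])
  b0 <- lf$coefficients[2]
  if (!is.finite(a0) || a0 == 0) a0 <- max(abs(y)) + 1e-6
  if (!is.finite(b0)) b0 <- -1
  if (b0 == 0) b0 <- -1e-3
  if (n_terms == 1) c(a = unname(a0), b = unname(b0))
  else c(a = unname(a0 / 2), b = unname(b0),
         c = unname(a0 / 2), d = unname(5 * b0))
}

#' One- or two-term exponential fit
#'
#' Fits `y = a e^(bx)` or `y = a e^(bx) + c e^(dx)` by Levenberg-Marquardt,
#' initialized from a log-linear regression on the shifted-positive response
#' (two-term rates start at `b` and `5 b`). Non-convergence is flagged, never
#' an error.
#'
#' @inheritParams fit_polynomial
#' @param n_terms 1 or 2.
#' @return A `curve_fit` with coefficients `a,b` or `a,b,c,d`.
#' @export
fit_exponential <- function(x, y, n_terms) {
  if (!n_terms %in% 1:2) {
    stop("exponential model has 1 or 2 terms", call. = FALSE)
  }
  if (length(y) < 2 * n_terms + 1) {
    stop("need at least 2 * n_terms + 1 points", call. = FALSE)
  }
  par0 <- exponential_init(x, y, n_terms)
  fit <- run_lm(par0, function(p) y - exponential_model(p, x, n_terms))
  coeffs <- fit$par
  names(coeffs) <- c("a", "b", "c", "d")[seq_along(coeffs)]
  new_curve_fit("exponential", n_terms, coeffs, x, y,
                exponential_model(fit$par, x, n_terms), fit$converged)
}

#' Fit one whole-series model family at one order
#'
#' Dispatcher over the four families. Orders follow the screening grid:
#' polynomial degree 1-9, Gaussian 1-4 peaks, Fourier 1-4 harmonics,
#' exponential 1-2 terms.
#'
#' @param x,y Predictor (normalized time) and response.
#' @param family One of `"polynomial"`, `"gaussian"`, `"fourier"`,
#'   `"exponential"`.
#' @param order Degree / number of peaks, harmonics or terms.
#' @return A `curve_fit` object.
#' @export
fit_curve <- function(x, y, family, order) {
  switch(match.arg(family, fit_families()),
         polynomial = fit_polynomial(x, y, order),
         gaussian = fit_gaussian(x, y, order),
         fourier = fit_fourier(x, y, order),
         exponential = fit_exponential(x, y, order))
}

#' @describeIn fit_curve The four model-family names.
#' @export
fit_families <- function() {
  c("polynomial", "gaussian", "fourier", "exponential")
}

#' Full model-screening grid
#'
#' @return A tibble with columns `family` and `order`: polynomial degrees 1-9,
#'   Gaussian 1-4 peaks, Fourier 1-4 harmonics, exponential 1-2 terms — 19
#'   cells in total.
#' @export
default_fit_grid <- function() {
  tibble::tibble(
    family = rep(fit_families(), c(9L, 4L, 4L, 2L)),
    order = c(1:9, 1:4, 1:4, 1:2)
  )
}

grid_bounds <- c(polynomial = 9L, gaussian = 4L, fourier = 4L,
                 exponential = 2L)

validate_grid <- function(grid) {
  stopifnot(all(c("family", "order") %in% names(grid)))
  bad_family <- setdiff(unique(grid$family), fit_families())
  if (length(bad_family) > 0) {
    stop("unknown fit family: ", paste(bad_family, collapse = ", "),
         call. = FALSE)
  }
  out_of_bounds <- grid$order < 1 | grid$order > grid_bounds[grid$family]
  if (any(out_of_bounds)) {
    stop("grid orders out of bounds for family ",
         paste(unique(grid$family[out_of_bounds]), collapse = ", "),
         call. = FALSE)
  }
  invisible(grid)
}

#' Fit the model-screening grid to every series
#'
#' Runs [fit_curve()] for each (family, order) cell of the grid on each
#' series' normalized time axis. Initialization rules are deterministic, so
#' repeated calls give identical coefficients.
#'
#' @param signals A signal tibble.
#' @param grid Screening grid (tibble with `family`, `order`), by default the
#'   full 19-cell grid of [default_fit_grid()].
#' @return A tibble with one row per series x grid cell: `series_id`,
#'   `stimulus`, `family`, `order`, `r_squared`, `converged`, and
#'   `coefficients` (list-column of named numeric vectors).
#' @export
fit_sweep <- function(signals, grid = default_fit_grid()) {
  validate_signals(signals)
  validate_grid(grid)
  per_series <- purrr::pmap(
    list(signals$series_id, signals$stimulus, signals$values),
    function(id, stim, v) {
      xy <- normalize_time(v)
      fits <- purrr::map2(grid$family, grid$order, function(fam, ord) {
        fit_curve(xy$x, xy$y, fam, ord)
      })
      tibble::tibble(
        series_id = id, stimulus = stim,
        family = grid$family, order = as.integer(grid$order),
        r_squared = purrr::map_dbl(fits, "r_squared"),
        converged = purrr::map_lgl(fits, "converged"),
        coefficients = purrr::map(fits, "coefficients")
      )
    }
  )
  dplyr::bind_rows(per_series)
}
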