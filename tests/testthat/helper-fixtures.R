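# Small deterministic fixtures, generated in code.

# A tiny 3-class signal tibble built directly (no simulator), with
# class-distinct linear/quadratic trends.
tiny_signals <- function(n_per_class = 1L, n_samples = 40L) {
  shapes <- list(
    NaCl = function(x) 2 * x + 1,
    H2SO4 = function(x) -3 * x + 0.5,
    O3 = function(x) 4 * x^2 - 2 * x
  )
  rows <- purrr::imap(shapes, function(f, label) {
    purrr::map(seq_len(n_per_class), function(k) {
      x <- seq(0, 1, length.out = n_samples)
      tibble::tibble(
        series_id = sprintf("%s_%02d", label, k),
        stimulus = label,
        plant_id = paste0(label, "_p", k),
        channel = 1L,
        sampling_rate_hz = 10,
        values = list(f(x) + 0.01 * k)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

# Two well-separated Gaussian clouds in `m` dimensions.
two_class_clouds <- function(n_per_class = 10, m = 2, sep = 6, sd = 1,
                             seed = 42, labels = c("A", "B")) {
  set.seed(seed)
  XA <- matrix(stats::rnorm(n_per_class * m, 0, sd), ncol = m)
  XB <- matrix(stats::rnorm(n_per_class * m, 0, sd), ncol = m)
  XB[, 1] <- XB[, 1] + sep
  X <- rbind(XA, XB)
  colnames(X) <- paste0("f", seq_len(m))
  list(X = X, labels = rep(labels, each = n_per_class))
}

features_from_matrix <- function(X, labels) {
  dplyr::bind_cols(
    tibble::tibble(series_id = sprintf("s%03d", seq_len(nrow(X))),
                   stimulus = labels),
    tibble::as_tibble(X)
  )
}

# Normal-equations polynomial least squares: the independent oracle.
polyfit_oracle <- function(x, y, degree) {
  V <- outer(x, degree:0, `^`)
  drop(solve(t(V) %*% V, t(V) %*% y))
}

# Multi-start nonlinear least-squares oracle (optim/BFGS from random
# restarts); independent of the package's Levenberg-Marquardt path.
multistart_oracle <- function(model_fn, x, y, par0, n_restarts = 20,
                              spread = 0.5, seed = 99) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- if (r == 1) par0 else par0 * (1 + spread * stats::rnorm(length(par0)))
    res <- tryCatch(
      stats::optim(p0, function(p) sum((y - model_fn(p, x))^2),
                   method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  best$par
}

# Gaussian-Bayes oracle: explicit multivariate-normal log-density + log-prior.
gauss_bayes_oracle <- function(X, means, covs, priors) {
  logpdf <- function(x, m, S) {
    d <- x - m
    -0.5 * (length(m) * log(2 * pi) + determinant(S)$modulus +
              drop(d %*% solve(S) %*% d))
  }
  apply(X, 1, function(x) {
    sA <- logpdf(x, means[[1]], covs[[1]]) + log(priors[1])
    sB <- logpdf(x, means[[2]], covs[[2]]) + log(priors[2])
    c(sA - sB)
  })
}
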