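test_that("confusion metrics follow their definitions", {
  m <- confusion_metrics(tp = 3, fp = 0, tn = 4, fn = 1)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 0.8)
  expect_equal(m$accuracy, 0.875)
})

test_that("single-class held-out counts give 50% accuracy and undefined specificity", {
  m <- confusion_metrics(tp = 2, fp = 0, tn = 0, fn = 2)
  expect_equal(m$accuracy, 0.5)
  expect_true(is.na(m$specificity)) # no negatives in the held-out set
  expect_equal(m$npv, 0)
  expect_equal(m$sensitivity, 0.5)
})

test_that("all-correct predictions give every defined metric 1", {
  m <- confusion_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(unlist(m[, c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
  expect_error(confusion_metrics(tp = 0, fp = 0, tn = 0, fn = 0),
               "at least one")
})

test_that("loocv runs one fold per row and conserves counts", {
  cl <- two_class_clouds(n_per_class = 3, m = 1, sep = 4)
  feats <- features_from_matrix(cl$X, cl$labels)
  res <- loocv(feats, kind = "lda")
  expect_equal(res$n, 6)
  expect_equal(nrow(res$predictions), 6)
  expect_equal(with(res$metrics, tp + fp + tn + fn), 6)
})

test_that("perfectly separated 1-D classes reach LOOCV accuracy 1", {
  set.seed(4)
  X <- matrix(c(stats::rnorm(10, -10, 0.1), stats::rnorm(10, 10, 0.1)),
              ncol = 1, dimnames = list(NULL, "f1"))
  feats <- features_from_matrix(X, rep(c("A", "B"), each = 10))
  res <- loocv(feats, kind = "lda")
  expect_equal(res$metrics$accuracy, 1)
})

test_that("loocv predictions equal a hand-enumerated fold-by-fold oracle", {
  X <- matrix(c(0.0, 1.0, 2.0, 4.0, 5.0, 7.0), ncol = 1,
              dimnames = list(NULL, "f1"))
  labels <- c("A", "A", "A", "B", "B", "B")
  feats <- features_from_matrix(X, labels)
  res <- loocv(feats, kind = "lda", normalize = "none", priors = "uniform")
  oracle <- character(6)
  for (i in 1:6) {
    Xtr <- X[-i, , drop = FALSE]
    ltr <- labels[-i]
    mA <- mean(Xtr[ltr == "A", 1]); mB <- mean(Xtr[ltr == "B", 1])
    vA <- stats::var(Xtr[ltr == "A", 1]); vB <- stats::var(Xtr[ltr == "B", 1])
    nA <- sum(ltr == "A"); nB <- sum(ltr == "B")
    s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    # pooled-covariance Gaussian scores with equal priors
    sA <- -0.5 * (X[i, 1] - mA)^2 / s2
    sB <- -0.5 * (X[i, 1] - mB)^2 / s2
    oracle[i] <- if (sA >= sB) "A" else "B"
  }
  expect_equal(res$predictions$predicted, oracle)
})

test_that("loocv rejects degenerate class structure", {
  cl <- two_class_clouds(n_per_class = 3, m = 1)
  feats <- features_from_matrix(cl$X, cl$labels)
  expect_error(loocv(dplyr::mutate(feats, stimulus = "A"), "lda"),
               "exactly 2")
  feats_small <- feats[-1, ]
  expect_error(loocv(feats_small, "lda"), ">= 3 rows")
})

test_that("label-permuted data scores within the 99% binomial band around 0.5", {
  set.seed(77)
  cl <- two_class_clouds(n_per_class = 20, m = 2, sep = 8, sd = 1)
  permuted <- sample(cl$labels)
  feats <- features_from_matrix(cl$X, permuted)
  res <- loocv(feats, kind = "lda")
  n <- res$n
  lo <- stats::qbinom(0.005, n, 0.5) / n
  hi <- stats::qbinom(0.995, n, 0.5) / n
  expect_gte(res$metrics$accuracy, lo)
  expect_lte(res$metrics$accuracy, hi)
})

test_that("fit quality summary computes Tukey five-number rows", {
  fits <- tibble::tibble(
    series_id = sprintf("s%02d", 1:10), stimulus = "NaCl",
    family = "polynomial", order = 5L,
    r_squared = seq(0.1, 1.0, by = 0.1), converged = TRUE,
    coefficients = replicate(10, c(p1 = 1), simplify = FALSE)
  )
  s <- fit_quality_summary(fits)
  expect_equal(nrow(s), 1)
  expect_equal(s$median, 0.55)
  expect_equal(s$n_outliers, 0L)

  const <- dplyr::mutate(fits, r_squared = 0.8)
  s2 <- fit_quality_summary(const)
  expect_equal(s2$q3 - s2$q1, 0)
  expect_equal(s2$n_outliers, 0L)
  expect_equal(s2$whisker_low, 0.8)
  expect_equal(s2$whisker_high, 0.8)
})

test_that("outliers beyond 1.5 IQR are counted and excluded from whiskers", {
  vals <- c(rep(0.5, 4), 0.52, 0.54, 0.56, 0.58, 0.6, 5)
  fits <- tibble::tibble(
    series_id = sprintf("s%02d", seq_along(vals)), stimulus = "O3",
    family = "fourier", order = 2L, r_squared = vals, converged = TRUE,
    coefficients = replicate(length(vals), c(a0 = 1), simplify = FALSE)
  )
  s <- fit_quality_summary(fits)
  expect_equal(s$n_outliers, 1L)
  expect_equal(s$whisker_high, 0.6)
})

test_that("on separable data the polynomial family out-fits gaussian/exponential", {
  cfg <- default_benchmark_config("high", 4L, seed = 12L)
  cfg$templates <- purrr::map(cfg$templates, function(tm) {
    tm$duration_s_range <- c(20, 40); tm
  })
  d <- simulate_signals(cfg)
  fits <- fit_sweep(d, tibble::tibble(
    family = c("polynomial", "gaussian", "exponential"),
    order = c(5L, 2L, 1L)
  ))
  s <- fit_quality_summary(fits)
  med <- function(fam) stats::median(s$median[s$family == fam])
  expect_gt(med("polynomial"), med("gaussian"))
  expect_gt(med("polynomial"), med("exponential"))
  expect_s3_class(autoplot(s), "ggplot")
})

test_that("run_sweep enumerates every grid cell per pair and classifier", {
  cfg <- default_benchmark_config("high", 4L, seed = 9L)
  cfg$templates <- purrr::map(cfg$templates, function(tm) {
    tm$duration_s_range <- c(15, 25); tm
  })
  d <- simulate_signals(cfg)
  grid <- tibble::tibble(family = "polynomial", order = 1:9)
  sweep <- run_sweep(d, grid)
  expect_equal(nrow(sweep), 3 * 9 * 5)
  expect_true(all(sweep$accuracy >= 0 & sweep$accuracy <= 1))
  with_fourier <- run_sweep(
    d, tibble::tibble(family = c(rep("polynomial", 9), rep("fourier", 4)),
                      order = c(1:9, 1:4))
  )
  expect_equal(nrow(with_fourier), nrow(sweep) + 3 * 4 * 5)
  sweep2 <- run_sweep(d, grid)
  expect_identical(sweep, sweep2)
  expect_s3_class(autoplot(sweep), "ggplot")
})

test_that("select_best maximizes accuracy with the documented tie-breaks", {
  base <- tibble::tibble(
    pair = "A vs B", family = "polynomial",
    sensitivity = 0.9, specificity = 0.9, ppv = 0.9, npv = 0.9
  )
  r1 <- dplyr::bind_rows(
    dplyr::mutate(base, order = 5L, classifier = "lda", accuracy = 0.88),
    dplyr::mutate(base, order = 9L, classifier = "lda", accuracy = 0.98)
  )
  expect_equal(select_best(r1)$order, 9L)

  r2 <- dplyr::bind_rows(
    dplyr::mutate(base, order = 5L, classifier = "lda", accuracy = 0.8,
                  sensitivity = 0.9, specificity = 0.5),
    dplyr::mutate(base, order = 5L, classifier = "qda", accuracy = 0.8,
                  sensitivity = 0.7, specificity = 0.7)
  )
  expect_equal(select_best(r2)$classifier, "qda")

  r3 <- dplyr::bind_rows(
    dplyr::mutate(base, order = 9L, classifier = "lda", accuracy = 0.9),
    dplyr::mutate(base, order = 5L, classifier = "lda", accuracy = 0.9)
  )
  expect_equal(select_best(r3)$order, 5L)

  r4 <- dplyr::bind_rows(
    dplyr::mutate(base, order = 5L, classifier = "mahalanobis",
                  accuracy = 0.9),
    dplyr::mutate(base, order = 5L, classifier = "diaglinear", accuracy = 0.9)
  )
  expect_equal(select_best(r4)$classifier, "diaglinear")
  expect_error(select_best(r4[0, ]), "no sweep results")
})
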