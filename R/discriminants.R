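#' The five binary discriminant kinds
#'
#' `lda` (pooled covariance), `qda` (per-class covariance), `diaglinear` and
#' `diagquadratic` (their naive-Bayes variants, off-diagonal covariance
#' entries zeroed), and `mahalanobis` (pure distance rule on per-class
#' covariances, no priors). The order returned is also the tie-break order
#' used by [select_best()].
#'
#' @return Character vector of the five kinds.
#' @export
discriminant_kinds <- function() {
  c("lda", "diaglinear", "qda", "diagquadratic", "mahalanobis")
}

# Symmetrize and, if near-singular, ridge a covariance matrix with
# lambda * (trace/M) * I, escalating tenfold until positive definite.
regularize_cov <- function(S, ridge_lambda) {
  S <- (S + t(S)) / 2
  M <- ncol(S)
  scale <- sum(diag(S)) / M
  if (scale <= 0) scale <- 1
  lam <- ridge_lambda
  for (i in 1:40) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-12 * max(abs(ev), scale)) return(S)
    S <- S + lam * scale * diag(M)
    lam <- lam * 10
  }
  stop("covariance matrix could not be regularized", call. = FALSE)
}

cov_of <- function(X) {
  if (nrow(X) < 2) stop("need >= 2 rows per class", call. = FALSE)
  stats::cov(X)
}

#' Train a binary discriminant classifier
#'
#' Gaussian discriminant analysis from first principles. All kinds estimate
#' per-class mean vectors; `lda`/`diaglinear` pool the within-class
#' covariance, `qda`/`diagquadratic`/`mahalanobis` keep per-class
#' covariances, and the diagonal kinds zero all off-diagonal entries
#' (feature-independence assumption). Near-singular covariances get a ridge
#' `lambda * (trace/M) * I`. For `lda` the explicit linear form
#' `score = w'x + b` (score of the first class minus the second) is exposed
#' alongside the Gaussian scores.
#'
#' @param features Feature tibble from [build_features()] (columns
#'   `series_id`, `stimulus`, features), or a numeric matrix if `labels` is
#'   given.
#' @param kind One of [discriminant_kinds()].
#' @param labels Class labels (needed only when `features` is a matrix).
#'   Exactly two classes, each with >= 2 rows. The first level (or first
#'   label encountered) is class A, the positive class and tie-break winner.
#' @param priors `"empirical"` (class frequencies; the default, matching the
#'   heavy class imbalance of real recording campaigns) or `"uniform"`.
#'   Ignored by `mahalanobis`, which is a pure distance rule.
#' @param ridge_lambda Ridge coefficient, default 1e-6.
#' @return An object of class `discriminant`.
#' @export
train_discriminant <- function(features, kind = discriminant_kinds(),
                               labels = NULL,
                               priors = c("empirical", "uniform"),
                               ridge_lambda = 1e-6) {
  kind <- match.arg(kind)
  priors <- match.arg(priors)
  if (is.data.frame(features)) {
    labels <- features$stimulus
    X <- features_to_matrix(features)
  } else {
    X <- as.matrix(features)
  }
  if (is.null(labels)) stop("labels required", call. = FALSE)
  if (ncol(X) < 1) stop("empty feature set", call. = FALSE)
  class_labels <- if (is.factor(labels)) {
    intersect(levels(labels), unique(as.character(labels)))
  } else {
    unique(as.character(labels))
  }
  labels <- as.character(labels)
  if (length(class_labels) != 2) {
    stop("exactly 2 classes required, got ",
         length(class_labels), call. = FALSE)
  }
  n_k <- table(factor(labels, levels = class_labels))
  if (any(n_k < 2)) {
    stop("each class needs >= 2 training rows", call. = FALSE)
  }
  XA <- X[labels == class_labels[1], , drop = FALSE]
  XB <- X[labels == class_labels[2], , drop = FALSE]
  means <- rbind(colMeans(XA), colMeans(XB))
  rownames(means) <- class_labels
  prior_vec <- if (priors == "uniform") c(0.5, 0.5) else
    as.numeric(n_k) / sum(n_k)
  names(prior_vec) <- class_labels

  pooled_kinds <- c("lda", "diaglinear")
  if (kind %in% pooled_kinds) {
    SA <- cov_of(XA); SB <- cov_of(XB)
    S <- ((nrow(XA) - 1) * SA + (nrow(XB) - 1) * SB) /
      (nrow(XA) + nrow(XB) - 2)
    if (kind == "diaglinear") S <- diag(diag(S), ncol(X))
    covs <- list(pooled = regularize_cov(S, ridge_lambda))
  } else {
    covs <- purrr::map(list(XA, XB), function(Xk) {
      S <- cov_of(Xk)
      if (kind == "diagquadratic") S <- diag(diag(S), ncol(X))
      regularize_cov(S, ridge_lambda)
    })
    names(covs) <- class_labels
  }

  model <- structure(
    list(kind = kind, class_labels = class_labels, means = means,
         covs = covs, priors = prior_vec, priors_mode = priors,
         ridge_lambda = ridge_lambda,
         feature_names = colnames(X), n_features = ncol(X)),
    class = "discriminant"
  )
  if (kind %in% pooled_kinds) {
    # explicit linear form of the pooled-covariance discriminant:
    # scoreA - scoreB = w'x + b
    Sinv <- chol2inv(chol(covs$pooled))
    w <- drop(Sinv %*% (means[1, ] - means[2, ]))
    b <- -0.5 * (drop(means[1, ] %*% Sinv %*% means[1, ]) -
                   drop(means[2, ] %*% Sinv %*% means[2, ])) +
      log(prior_vec[1] / prior_vec[2])
    model$w <- w
    model$b <- unname(b)
  }
  model
}

# Quadratic Gaussian discriminant score for one class:
# -1/2 log|S| - 1/2 (x - m)' S^-1 (x - m) + log prior, vectorized over rows.
quad_scores <- function(X, m, S, logprior) {
  R <- chol(S)
  D <- t(backsolve(R, t(sweep(X, 2, m, `-`)), transpose = TRUE))
  maha <- rowSums(D^2)
  -sum(log(diag(R))) - 0.5 * maha + logprior
}

# Squared Mahalanobis distances to one class mean.
maha_dist2 <- function(X, m, S) {
  R <- chol(S)
  D <- t(backsolve(R, t(sweep(X, 2, m, `-`)), transpose = TRUE))
  rowSums(D^2)
}

#' Predict with a trained discriminant
#'
#' Gaussian kinds assign the class with the larger discriminant score
#' (log-density plus log-prior); `mahalanobis` assigns the class with the
#' smaller covariance-scaled distance, ignoring priors. The returned `score`
#' is the signed margin (class A score minus class B score; for
#' `mahalanobis`, distance B minus distance A), positive favouring class A.
#' Exact ties go to class A.
#'
#' @param object A `discriminant`.
#' @param newdata Feature tibble or numeric matrix with the training columns.
#' @param ... Unused.
#' @return A tibble with columns `label` and `score`, one row per input row.
#' @export
predict.discriminant <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) features_to_matrix(newdata) else
    as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " features; model expects ",
         object$n_features, call. = FALSE)
  }
  cl <- object$class_labels
  if (object$kind %in% c("lda", "diaglinear")) {
    S <- object$covs$pooled
    score <- quad_scores(X, object$means[1, ], S, log(object$priors[1])) -
      quad_scores(X, object$means[2, ], S, log(object$priors[2]))
  } else if (object$kind == "mahalanobis") {
    score <- maha_dist2(X, object$means[2, ], object$covs[[2]]) -
      maha_dist2(X, object$means[1, ], object$covs[[1]])
  } else {
    score <- quad_scores(X, object$means[1, ], object$covs[[1]],
                         log(object$priors[1])) -
      quad_scores(X, object$means[2, ], object$covs[[2]],
                  log(object$priors[2]))
  }
  score <- unname(score)
  tibble::tibble(label = ifelse(score >= 0, cl[1], cl[2]), score = score)
}

#' @export
print.discriminant <- function(x, ...) {
  cat(sprintf("<discriminant> %s: %s vs %s, %d features, priors %s\n",
              x$kind, x$class_labels[1], x$class_labels[2],
              x$n_features, x$priors_mode))
  invisible(x)
}

#' @describeIn train_discriminant Per-class means (and for pooled kinds the
#'   explicit linear weights) as a tibble.
#' @param x A `discriminant` object.
#' @param ... Unused.
#' @method tidy discriminant
#' @export
tidy.discriminant <- function(x, ...) {
  out <- tibble::tibble(
    feature = rep(x$feature_names, 2),
    class = rep(x$class_labels, each = x$n_features),
    mean = c(x$means[1, ], x$means[2, ])
  )
  if (!is.null(x$w)) {
    out <- dplyr::left_join(
      out,
      tibble::tibble(feature = x$feature_names, weight = unname(x$w)),
      by = "feature"
    )
  }
  out
}

#' @describeIn train_discriminant One-row model summary.
#' @method glance discriminant
#' @export
glance.discriminant <- function(x, ...) {
  tibble::tibble(kind = x$kind, class_a = x$class_labels[1],
                 class_b = x$class_labels[2], n_features = x$n_features,
                 priors = x$priors_mode, ridge_lambda = x$ridge_lambda)
}

# Serializable list form (JSON-friendly) and its inverse.
discriminant_to_list <- function(model) {
  list(kind = model$kind, class_labels = model$class_labels,
       means = unclass(model$means), covs = purrr::map(model$covs, unclass),
       priors = as.numeric(model$priors), priors_mode = model$priors_mode,
       ridge_lambda = model$ridge_lambda,
       feature_names = model$feature_names)
}

discriminant_from_list <- function(lst) {
  means <- as.matrix(lst$means)
  rownames(means) <- lst$class_labels
  covs <- purrr::map(lst$covs, as.matrix)
  priors <- stats::setNames(as.numeric(lst$priors), lst$class_labels)
  model <- structure(
    list(kind = lst$kind, class_labels = lst$class_labels, means = means,
         covs = covs, priors = priors, priors_mode = lst$priors_mode,
         ridge_lambda = lst$ridge_lambda,
         feature_names = lst$feature_names,
         n_features = length(lst$feature_names)),
    class = "discriminant"
  )
  if (model$kind %in% c("lda", "diaglinear")) {
    Sinv <- chol2inv(chol(covs$pooled))
    model$w <- drop(Sinv %*% (means[1, ] - means[2, ]))
    model$b <- unname(
      -0.5 * (drop(means[1, ] %*% Sinv %*% means[1, ]) -
                drop(means[2, ] %*% Sinv %*% means[2, ])) +
        log(priors[1] / priors[2])
    )
  }
  model
}
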