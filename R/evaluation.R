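#' Confusion-matrix measures for a binary classifier
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive value TP/(TP+FP) and TN/(TN+FN), accuracy (TP+TN)/total. A zero
#' denominator yields `NA` (an explicit undefined marker), never an error —
#' on a single-class test set specificity is simply undefined, and reporting
#' 0 or 1 instead would silently distort it.
#'
#' @param tp,fp,tn,fn Non-negative integer counts; `tp` may also be a list or
#'   one-row data frame with components `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  total <- sum(counts)
  if (total < 1) stop("need at least one prediction", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / total
  )
}

#' Leave-one-out cross-validation of a binary discriminant
#'
#' One fold per row: the row is held out, the normalizer (when
#' `normalize = "fold"`, the leakage-free default) and the classifier are
#' fitted on the remaining rows, and the held-out row is predicted once.
#' Counts are aggregated with the positive class designated by `positive`
#' (first label by default).
#'
#' @param features Feature tibble from [build_features()] with exactly two
#'   stimulus labels, each with >= 3 rows.
#' @param kind Discriminant kind (see [discriminant_kinds()]).
#' @param positive Positive-class label; default the first label in order of
#'   appearance.
#' @param priors,ridge_lambda Passed to [train_discriminant()].
#' @param normalize `"fold"` (z-score refitted inside every fold),
#'   `"global"` (one z-score on all rows — the simpler but leaky reading) or
#'   `"none"`.
#' @return An object of class `loocv_result`: `metrics` (one-row tibble),
#'   `predictions` (per-row tibble with `series_id`, `truth`, `predicted`,
#'   `score`), plus the settings used.
#' @export
loocv <- function(features, kind = discriminant_kinds(), positive = NULL,
                  priors = c("empirical", "uniform"), ridge_lambda = 1e-6,
                  normalize = c("fold", "global", "none")) {
  kind <- match.arg(kind)
  priors <- match.arg(priors)
  normalize <- match.arg(normalize)
  labels <- as.character(features$stimulus)
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("LOOCV needs exactly 2 classes, got ", length(classes),
         call. = FALSE)
  }
  if (any(table(labels) < 3)) {
    stop("each class needs >= 3 rows for LOOCV", call. = FALSE)
  }
  positive <- positive %||% classes[1]
  stopifnot(positive %in% classes)
  negative <- setdiff(classes, positive)
  ordered_labels <- factor(labels, levels = c(positive, negative))

  X_all <- features_to_matrix(features)
  if (normalize == "global") {
    X_all <- apply_normalizer(X_all, fit_normalizer(X_all))
  }
  n <- nrow(X_all)
  preds <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    X_tr <- X_all[-i, , drop = FALSE]
    X_te <- X_all[i, , drop = FALSE]
    if (normalize == "fold") {
      norm <- fit_normalizer(X_tr)
      X_tr <- apply_normalizer(X_tr, norm)
      X_te <- apply_normalizer(X_te, norm)
    }
    model <- train_discriminant(X_tr, kind = kind,
                                labels = ordered_labels[-i],
                                priors = priors,
                                ridge_lambda = ridge_lambda)
    p <- predict(model, X_te)
    preds[i] <- p$label
    scores[i] <- p$score
  }
  counts <- list(
    tp = sum(preds == positive & labels == positive),
    fp = sum(preds == positive & labels != positive),
    tn = sum(preds != positive & labels != positive),
    fn = sum(preds != positive & labels == positive)
  )
  structure(
    list(
      metrics = confusion_metrics(counts),
      predictions = tibble::tibble(
        series_id = features$series_id, truth = labels,
        predicted = preds, score = scores
      ),
      positive = positive, kind = kind, priors = priors,
      normalize = normalize, n = n
    ),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s, %s positive, n = %d folds\n",
              x$kind, x$positive, x$n))
  print(x$metrics)
  invisible(x)
}

#' @describeIn loocv Per-fold predictions as a tibble.
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @method tidy loocv_result
#' @export
tidy.loocv_result <- function(x, ...) x$predictions

#' @describeIn loocv One-row tibble of the aggregated metrics.
#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, positive = x$positive, n = x$n),
    x$metrics
  )
}

#' Goodness-of-fit summary per family, order and stimulus
#'
#' Five-number Tukey summary of the R-squared values of a [fit_sweep()]
#' result: median, quartiles, whiskers at the most extreme values within
#' 1.5 IQR of the quartiles, and the count of points beyond them. This is the
#' tabular equivalent of the box-plot screening that rules model families in
#' or out as feature generators.
#'
#' @param fits A [fit_sweep()] tibble.
#' @return A tibble grouped by `family`, `order`, `stimulus` with columns
#'   `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
fit_quality_summary <- function(fits) {
  stopifnot(all(c("family", "order", "stimulus", "r_squared") %in%
                  names(fits)))
  out <- fits |>
    dplyr::group_by(.data$family, .data$order, .data$stimulus) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$r_squared),
      q1 = unname(stats::quantile(.data$r_squared, 0.25)),
      q3 = unname(stats::quantile(.data$r_squared, 0.75)),
      .groups = "drop"
    )
  fences <- out |>
    dplyr::mutate(lo_fence = .data$q1 - 1.5 * (.data$q3 - .data$q1),
                  hi_fence = .data$q3 + 1.5 * (.data$q3 - .data$q1))
  joined <- dplyr::left_join(
    fits, fences,
    by = c("family", "order", "stimulus")
  )
  extremes <- joined |>
    dplyr::group_by(.data$family, .data$order, .data$stimulus) |>
    dplyr::summarise(
      whisker_low = min(.data$r_squared[.data$r_squared >= .data$lo_fence],
                        na.rm = TRUE),
      whisker_high = max(.data$r_squared[.data$r_squared <= .data$hi_fence],
                         na.rm = TRUE),
      n_outliers = sum(.data$r_squared < .data$lo_fence |
                         .data$r_squared > .data$hi_fence),
      .groups = "drop"
    )
  res <- dplyr::left_join(out, extremes,
                          by = c("family", "order", "stimulus"))
  class(res) <- c("fit_quality_summary", class(res))
  res
}

#' @describeIn fit_quality_summary Box-plot style view of the R-squared
#'   summaries.
#' @param object A `fit_quality_summary` tibble.
#' @param ... Unused.
#' @method autoplot fit_quality_summary
#' @export
autoplot.fit_quality_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$order))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity"
    ) +
    ggplot2::facet_grid(ggplot2::vars(.data$stimulus),
                        ggplot2::vars(.data$family)) +
    ggplot2::labs(x = "degree / number of terms", y = expression(R^2))
}

# Canonical unordered label pairs, in order of appearance.
all_label_pairs <- function(labels) {
  labs <- unique(as.character(labels))
  utils::combn(labs, 2, simplify = FALSE)
}

pair_name <- function(pair) paste(pair[1], "vs", pair[2])

#' Screen every (pair, family, order, classifier) combination by LOOCV
#'
#' For each class pair and each grid cell, builds the coefficient features,
#' runs leave-one-out cross-validation with the requested classifier, and
#' records the confusion-matrix measures. The first stimulus of each pair is
#' the positive class. Deterministic given the fitting rules.
#'
#' @param signals A signal tibble (>= 3 series per class).
#' @param grid Screening grid, default [default_fit_grid()].
#' @param classifiers Subset of [discriminant_kinds()].
#' @param pairs List of length-2 character vectors, default every unordered
#'   label pair.
#' @param fits Optional precomputed [fit_sweep()] result for `signals`.
#' @inheritParams loocv
#' @return A `sweep_results` tibble: `pair`, `family`, `order`, `classifier`
#'   and the five metrics.
#' @export
run_sweep <- function(signals, grid = default_fit_grid(),
                      classifiers = discriminant_kinds(), pairs = NULL,
                      priors = "empirical", ridge_lambda = 1e-6,
                      normalize = "fold", fits = NULL) {
  validate_signals(signals)
  validate_grid(grid)
  stopifnot(all(classifiers %in% discriminant_kinds()))
  pairs <- pairs %||% all_label_pairs(signals$stimulus)
  fits <- fits %||% fit_sweep(signals, grid)

  cells <- tidyr::expand_grid(
    pair_idx = seq_along(pairs),
    cell_idx = seq_len(nrow(grid)),
    classifier = classifiers
  )
  rows <- purrr::pmap(cells, function(pair_idx, cell_idx, classifier) {
    pair <- pairs[[pair_idx]]
    fam <- grid$family[cell_idx]
    ord <- grid$order[cell_idx]
    feats <- build_features(
      fits[fits$stimulus %in% pair, ], fam, ord
    )
    res <- tryCatch(
      loocv(feats, kind = classifier, positive = pair[1], priors = priors,
            ridge_lambda = ridge_lambda, normalize = normalize),
      error = function(e) {
        stop("sweep cell (", pair_name(pair), ", ", fam, " ", ord, ", ",
             classifier, "): ", conditionMessage(e), call. = FALSE)
      }
    )
    dplyr::bind_cols(
      tibble::tibble(pair = pair_name(pair), family = fam,
                     order = as.integer(ord), classifier = classifier),
      res$metrics[, c("sensitivity", "specificity", "ppv", "npv",
                      "accuracy")]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_results", class(out))
  out
}

#' @describeIn run_sweep Metric profiles across orders, one panel per
#'   classifier, faceted by pair.
#' @param object A `sweep_results` tibble.
#' @param metric Metric column to draw.
#' @param ... Unused.
#' @method autoplot sweep_results
#' @export
autoplot.sweep_results <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$order, .data[[metric]],
                               colour = .data$classifier)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(ggplot2::vars(.data$pair),
                        ggplot2::vars(.data$family)) +
    ggplot2::labs(x = "degree / number of terms", y = metric)
}

#' Pick the best feature-classifier combination for a class pair
#'
#' Maximizes accuracy; ties are broken by (1) the larger of
#' `min(sensitivity, specificity)` — headline accuracy can be artificially
#' high when one class is systematically misclassified, so balance wins —
#' then (2) the lower model order, then (3) classifier simplicity in the
#' order lda < diaglinear < qda < diagquadratic < mahalanobis.
#'
#' @param results A `sweep_results` tibble.
#' @param pair Pair name (`"A vs B"`), or `NULL` to select per pair.
#' @return One row of `results` per requested pair.
#' @export
select_best <- function(results, pair = NULL) {
  if (!is.null(pair)) {
    results <- results[results$pair %in% pair, ]
  }
  if (nrow(results) == 0) stop("no sweep results to select from",
                               call. = FALSE)
  kind_rank <- stats::setNames(seq_along(c(
    "lda", "diaglinear", "qda", "diagquadratic", "mahalanobis"
  )), c("lda", "diaglinear", "qda", "diagquadratic", "mahalanobis"))
  results |>
    dplyr::mutate(
      .balance = pmin(dplyr::coalesce(.data$sensitivity, -1),
                      dplyr::coalesce(.data$specificity, -1)),
      .rank = kind_rank[.data$classifier]
    ) |>
    dplyr::group_by(.data$pair) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), dplyr::desc(.data$.balance),
                   .data$order, .data$.rank, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select(-".balance", -".rank")
}
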