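#' Build a one-versus-one decision tree from per-pair best combinations
#'
#' Trains one binary discriminant per unordered class pair, each on its own
#' best (family, order) coefficient features with its own z-score normalizer
#' fitted on the training series of its two classes. The union of (family,
#' order) cells needed by the three pair models is the "test matrix" a new
#' series must supply at prediction time.
#'
#' @param signals Training signal tibble with exactly the three classes
#'   (held-out series must not be included).
#' @param best_per_pair Tibble with one row per pair and columns `pair`
#'   (`"A vs B"`), `family`, `order`, `classifier` — typically
#'   [select_best()] output.
#' @param priors,ridge_lambda Passed to [train_discriminant()].
#' @param fits Optional precomputed [fit_sweep()] result for `signals`.
#' @return An object of class `ovo_tree`.
#' @export
build_ovo_tree <- function(signals, best_per_pair, priors = "empirical",
                           ridge_lambda = 1e-6, fits = NULL) {
  validate_signals(signals)
  classes <- unique(signals$stimulus)
  if (length(classes) != 3) {
    stop("the one-versus-one tree expects exactly 3 classes, got ",
         length(classes), call. = FALSE)
  }
  expected <- vapply(all_label_pairs(signals$stimulus), pair_name, "")
  parsed <- strsplit(best_per_pair$pair, " vs ", fixed = TRUE)
  canon <- vapply(parsed, function(p) {
    pair_name(classes[sort(match(p, classes))])
  }, "")
  if (!setequal(canon, expected) || nrow(best_per_pair) != 3) {
    stop("best_per_pair must cover each of the 3 class pairs exactly once; ",
         "expected ", paste(expected, collapse = ", "), call. = FALSE)
  }
  pair_models <- purrr::pmap(
    list(parsed, best_per_pair$family, best_per_pair$order,
         best_per_pair$classifier),
    function(pair, family, order, classifier) {
      sub <- signals[signals$stimulus %in% pair, ]
      sub_fits <- if (is.null(fits)) {
        fit_sweep(sub, tibble::tibble(family = family, order = order))
      } else {
        fits[fits$stimulus %in% pair, ]
      }
      feats <- build_features(sub_fits, family, order)
      feats$stimulus <- factor(feats$stimulus, levels = pair)
      norm <- fit_normalizer(feats)
      Xn <- apply_normalizer(feats, norm)
      model <- train_discriminant(
        Xn, kind = classifier, labels = feats$stimulus,
        priors = priors, ridge_lambda = ridge_lambda
      )
      list(pair = pair, family = family, order = as.integer(order),
           classifier = classifier, normalizer = norm, model = model)
    }
  )
  structure(
    list(pair_models = pair_models, classes = classes,
         vote_rule = "majority_margin"),
    class = "ovo_tree"
  )
}

#' @export
print.ovo_tree <- function(x, ...) {
  cat("<ovo_tree> majority vote over 3 pairwise discriminants\n")
  for (pm in x$pair_models) {
    cat(sprintf("  %s: %s order %d, %s\n", pair_name(pm$pair), pm$family,
                pm$order, pm$classifier))
  }
  invisible(x)
}

#' @describeIn build_ovo_tree Pair-model summary as a tibble.
#' @param x An `ovo_tree`.
#' @param ... Unused.
#' @method tidy ovo_tree
#' @export
tidy.ovo_tree <- function(x, ...) {
  purrr::map_dfr(x$pair_models, function(pm) {
    tibble::tibble(pair = pair_name(pm$pair), family = pm$family,
                   order = pm$order, classifier = pm$classifier)
  })
}

#' @describeIn build_ovo_tree One-row tree summary.
#' @method glance ovo_tree
#' @export
glance.ovo_tree <- function(x, ...) {
  tibble::tibble(
    n_pairs = length(x$pair_models), vote_rule = x$vote_rule,
    families = paste(unique(purrr::map_chr(x$pair_models, "family")),
                     collapse = ","),
    orders = paste(sort(unique(purrr::map_int(x$pair_models, "order"))),
                   collapse = ",")
  )
}

# The (family, order) cells any series must be fitted with before the tree
# can vote on it.
required_grid <- function(tree) {
  dplyr::distinct(tibble::tibble(
    family = purrr::map_chr(tree$pair_models, "family"),
    order = purrr::map_int(tree$pair_models, "order")
  ))
}

#' Predict stimulus classes with a one-versus-one tree
#'
#' Each series is fitted with every (family, order) the tree requires, each
#' pair model normalizes its own coefficients and votes for one of its two
#' classes, and the majority of the three votes wins. A 1-1-1 cycle is broken
#' by the vote of the pair model with the largest absolute margin. Votes and
#' margins are returned for audit.
#'
#' @param tree An `ovo_tree`.
#' @param signals Signal tibble of series to classify.
#' @return A tibble: `series_id`, `stimulus` (truth, if present), `predicted`,
#'   `n_votes`, and one `vote_*`/`margin_*` column pair per pair model.
#' @export
predict_ovo <- function(tree, signals) {
  stopifnot(inherits(tree, "ovo_tree"))
  validate_signals(signals)
  fits <- fit_sweep(signals, required_grid(tree))
  votes <- purrr::map(tree$pair_models, function(pm) {
    feats <- build_features(fits, pm$family, pm$order)
    Xn <- apply_normalizer(feats, pm$normalizer)
    p <- predict(pm$model, Xn)
    dplyr::mutate(p, series_id = feats$series_id)
  })
  per_series <- purrr::map(seq_len(nrow(signals)), function(i) {
    id <- signals$series_id[i]
    vl <- purrr::map_chr(votes, function(v) v$label[v$series_id == id])
    vs <- purrr::map_dbl(votes, function(v) v$score[v$series_id == id])
    tally <- table(vl)
    winner <- if (max(tally) >= 2) {
      names(tally)[which.max(tally)]
    } else {
      vl[which.max(abs(vs))] # 1-1-1 cycle: trust the largest margin
    }
    row <- tibble::tibble(series_id = id, predicted = winner,
                          n_votes = as.integer(max(tally)))
    for (k in seq_along(tree$pair_models)) {
      nm <- gsub(" ", "_", pair_name(tree$pair_models[[k]]$pair))
      row[[paste0("vote_", nm)]] <- vl[k]
      row[[paste0("margin_", nm)]] <- vs[k]
    }
    row
  })
  out <- dplyr::bind_rows(per_series)
  if ("stimulus" %in% names(signals)) {
    out <- dplyr::left_join(
      signals[, c("series_id", "stimulus")], out, by = "series_id"
    )
  }
  out
}

#' Per-class report of a prospective (held-out) test
#'
#' @param tree An `ovo_tree` trained without the held-out series.
#' @param heldout Held-out signal tibble; its labels must all be classes of
#'   the tree.
#' @return A tibble per stimulus: `n_heldout`, `n_correct`, `accuracy`.
#' @export
prospective_report <- function(tree, heldout) {
  validate_signals(heldout)
  unknown <- setdiff(unique(heldout$stimulus), tree$classes)
  if (length(unknown) > 0) {
    stop("held-out label(s) absent from the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  preds <- predict_ovo(tree, heldout)
  preds |>
    dplyr::group_by(stimulus = .data$stimulus) |>
    dplyr::summarise(
      n_heldout = dplyr::n(),
      n_correct = sum(.data$predicted == .data$stimulus),
      accuracy = .data$n_correct / .data$n_heldout,
      .groups = "drop"
    )
}

#' Serialize / restore a one-versus-one tree as JSON
#'
#' @param tree An `ovo_tree`.
#' @param path Output (input) JSON file path.
#' @return `write_ovo_tree` returns `path` invisibly; `read_ovo_tree` the
#'   restored `ovo_tree`.
#' @export
write_ovo_tree <- function(tree, path) {
  stopifnot(inherits(tree, "ovo_tree"))
  payload <- list(
    vote_rule = tree$vote_rule, classes = tree$classes,
    pair_models = purrr::map(tree$pair_models, function(pm) {
      list(pair = pm$pair, family = pm$family, order = pm$order,
           classifier = pm$classifier,
           normalizer = list(means = as.numeric(pm$normalizer$means),
                             sds = as.numeric(pm$normalizer$sds),
                             dropped = pm$normalizer$dropped,
                             feature_names = pm$normalizer$feature_names),
           model = discriminant_to_list(pm$model))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ovo_tree
#' @export
read_ovo_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  pair_models <- purrr::map(payload$pair_models, function(pm) {
    norm <- structure(
      list(means = stats::setNames(as.numeric(pm$normalizer$means),
                                   pm$normalizer$feature_names),
           sds = stats::setNames(as.numeric(pm$normalizer$sds),
                                 pm$normalizer$feature_names),
           dropped = as.integer(pm$normalizer$dropped %||% integer()),
           feature_names = pm$normalizer$feature_names),
      class = "normalizer"
    )
    list(pair = unlist(pm$pair), family = pm$family,
         order = as.integer(pm$order), classifier = pm$classifier,
         normalizer = norm, model = discriminant_from_list(pm$model))
  })
  structure(
    list(pair_models = pair_models, classes = unlist(payload$classes),
         vote_rule = payload$vote_rule),
    class = "ovo_tree"
  )
}
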