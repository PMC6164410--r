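#' Assemble a feature table from curve-fit coefficients
#'
#' One row per series, one column per coefficient of the chosen (family,
#' order): the full coefficient vector is always taken together — the
#' screening works at the level of whole model families, never individual
#' coefficients.
#'
#' @param fits Output of [fit_sweep()] (must contain the requested family and
#'   order for every series).
#' @param family Model family (see [fit_families()]).
#' @param order Degree / number of terms.
#' @param series_ids Series that must be present; defaults to every series in
#'   `fits`. A series without the requested fit is an error, named.
#' @return A tibble: `series_id`, `stimulus`, then one numeric column per
#'   coefficient (named after the coefficient). No non-finite entries.
#' @export
build_features <- function(fits, family, order,
                           series_ids = unique(fits$series_id)) {
  family <- match.arg(family, fit_families())
  sel <- fits[fits$family == family & fits$order == order, ]
  all_ids <- series_ids
  missing_ids <- setdiff(all_ids, sel$series_id)
  if (length(missing_ids) > 0 || nrow(sel) == 0) {
    stop("no ", family, " order ", order, " fit for series: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  bad <- purrr::map_lgl(sel$coefficients, function(cf) any(!is.finite(cf)))
  if (any(bad)) {
    stop("non-finite coefficients for series: ",
         paste(sel$series_id[bad], collapse = ", "), call. = FALSE)
  }
  X <- do.call(rbind, sel$coefficients)
  colnames(X) <- names(sel$coefficients[[1]])
  dplyr::bind_cols(
    tibble::tibble(series_id = sel$series_id, stimulus = sel$stimulus),
    tibble::as_tibble(X)
  )
}

feature_columns <- function(features) {
  setdiff(names(features), c("series_id", "stimulus"))
}

# Numeric matrix of the feature columns.
features_to_matrix <- function(features) {
  as.matrix(features[, feature_columns(features), drop = FALSE])
}

#' Fit a per-feature z-score normalizer
#'
#' Stores the per-column mean and sample standard deviation (n - 1
#' denominator) of the training matrix. Zero-variance columns are recorded as
#' dropped rather than perturbed.
#'
#' @param X Numeric training matrix (>= 2 rows), or a feature tibble from
#'   [build_features()].
#' @return An object of class `normalizer`: `means`, `sds`, `dropped`
#'   (column indices) and `feature_names`.
#' @export
fit_normalizer <- function(X) {
  if (is.data.frame(X)) X <- features_to_matrix(X)
  if (nrow(X) < 2) {
    stop("need at least 2 training rows to fit a normalizer", call. = FALSE)
  }
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- which(sds == 0)
  structure(
    list(means = means, sds = sds, dropped = unname(dropped),
         feature_names = colnames(X)),
    class = "normalizer"
  )
}

#' Apply a fitted normalizer
#'
#' Z-scores retained columns with the stored training means/sds and removes
#' dropped (zero-variance) columns. Applied back to its own training matrix
#' the result has column means 0 and sds 1.
#'
#' @param X Numeric matrix or feature tibble with the same columns the
#'   normalizer was fitted on.
#' @param params A `normalizer` from [fit_normalizer()].
#' @return Numeric matrix of the retained, z-scored columns.
#' @export
apply_normalizer <- function(X, params) {
  stopifnot(inherits(params, "normalizer"))
  if (is.data.frame(X)) X <- features_to_matrix(X)
  if (ncol(X) != length(params$means)) {
    stop("feature count (", ncol(X), ") does not match normalizer (",
         length(params$means), ")", call. = FALSE)
  }
  keep <- setdiff(seq_len(ncol(X)), params$dropped)
  if (length(keep) == 0) {
    stop("all features dropped (zero training variance); nothing to classify",
         call. = FALSE)
  }
  Z <- sweep(X[, keep, drop = FALSE], 2, params$means[keep], `-`)
  sweep(Z, 2, params$sds[keep], `/`)
}
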