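#' Stimulus labels used throughout the package
#'
#' The three chemical stimuli the classifier distinguishes: soil salinity
#' (NaCl), acid-rain surrogate (H2SO4) and tropospheric ozone (O3). The label
#' set is extensible: every function accepting a `labels` argument takes any
#' character vector.
#'
#' @return Character vector of the three default stimulus labels.
#' @export
default_stimuli <- function() c("NaCl", "H2SO4", "O3")

#' Per-stimulus series counts of the reference study design
#'
#' Number of post-stimulus time series per stimulus in the recording campaign
#' the simulator emulates (two electrode channels per plant, each channel a
#' separate series). These counts motivate the package defaults: a feature
#' space capped at 10 coefficients and empirical class priors under heavy
#' imbalance.
#'
#' @return A tibble with columns `stimulus` and `n_series`.
#' @export
#' @examples
#' sum(reference_study_counts()$n_series)
reference_study_counts <- function() {
  tibble::tibble(
    stimulus = c("NaCl", "H2SO4", "O3"),
    n_series = c(16L, 52L, 343L)
  )
}

#' Count series per stimulus label
#'
#' @param signals A signal tibble (see [read_signals()]).
#' @return A tibble with columns `stimulus` and `n`.
#' @export
label_counts <- function(signals) {
  validate_signals(signals, allow_empty = TRUE)
  dplyr::count(signals, .data$stimulus, name = "n")
}

#' Validate a signal tibble
#'
#' A signal tibble holds one labeled post-stimulus series per row:
#' `series_id`, `stimulus`, `plant_id`, `channel` (integer >= 1),
#' `sampling_rate_hz` (> 0) and `values`, a list-column of numeric millivolt
#' samples. Time is implicit: sample i sits at `(i - 1) / sampling_rate_hz`
#' seconds after stimulus application.
#'
#' @param signals Candidate signal tibble.
#' @param allow_empty Accept zero rows?
#' @param min_length Minimum samples per series (10 by default: one more than
#'   the largest model coefficient count is needed for fitting).
#' @return `signals`, invisibly, if valid; otherwise an error.
#' @export
validate_signals <- function(signals, allow_empty = FALSE, min_length = 10L) {
  required <- c("series_id", "stimulus", "plant_id", "channel",
                "sampling_rate_hz", "values")
  missing_cols <- setdiff(required, names(signals))
  if (length(missing_cols) > 0) {
    stop("signal tibble is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(signals) == 0) {
    if (!allow_empty) stop("signal tibble has no rows", call. = FALSE)
    return(invisible(signals))
  }
  if (anyDuplicated(signals$series_id)) {
    stop("duplicate series_id in signal tibble", call. = FALSE)
  }
  if (any(signals$sampling_rate_hz <= 0)) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  if (any(signals$channel < 1)) stop("channel must be >= 1", call. = FALSE)
  bad <- purrr::map_lgl(signals$values, function(v) {
    !is.numeric(v) || length(v) < min_length || anyNA(v) || !all(is.finite(v))
  })
  if (any(bad)) {
    stop("series ", paste(signals$series_id[bad], collapse = ", "),
         ": values must be finite numeric with at least ", min_length,
         " samples", call. = FALSE)
  }
  invisible(signals)
}

#' Load a labeled signal dataset from a manifest and per-series CSV files
#'
#' The manifest is a CSV with columns `file,stimulus,plant_id,channel`; each
#' referenced file is a CSV with columns `time_s,value_mV` holding one
#' post-stimulus series sampled uniformly (10 Hz by default). Files with
#' non-monotone time or sample spacing deviating more than 10% from
#' `1 / sampling_rate_hz` are rejected rather than interpolated.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param signals_dir Directory holding the per-series files; defaults to the
#'   manifest's directory.
#' @param sampling_rate_hz Expected sampling rate (Hz).
#' @param labels Permitted stimulus labels, or `NULL` to accept any.
#' @return A signal tibble, rows in manifest order.
#' @export
read_signals <- function(manifest_path,
                         signals_dir = dirname(manifest_path),
                         sampling_rate_hz = 10,
                         labels = default_stimuli()) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("file", "stimulus", "plant_id", "channel")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns file,stimulus,plant_id,channel",
         call. = FALSE)
  }
  if (nrow(manifest) == 0) {
    return(tibble::tibble(
      series_id = character(), stimulus = character(),
      plant_id = character(), channel = integer(),
      sampling_rate_hz = numeric(), values = list()
    ))
  }
  if (!is.null(labels)) {
    unknown <- setdiff(unique(manifest$stimulus), labels)
    if (length(unknown) > 0) {
      stop("unknown stimulus label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  dt_nominal <- 1 / sampling_rate_hz
  values <- purrr::map(manifest$file, function(f) {
    path <- file.path(signals_dir, f)
    if (!file.exists(path)) {
      stop("signal file not found: ", path, call. = FALSE)
    }
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("time_s", "value_mV") %in% names(d))) {
      stop(f, ": expected columns time_s,value_mV", call. = FALSE)
    }
    dt <- diff(d$time_s)
    if (any(dt <= 0)) {
      stop(f, ": time_s must be strictly increasing", call. = FALSE)
    }
    if (any(abs(dt - dt_nominal) > 0.1 * dt_nominal)) {
      stop(f, ": sample spacing deviates more than 10% from 1/",
           sampling_rate_hz, " s; gaps are not interpolated", call. = FALSE)
    }
    d$value_mV
  })
  out <- tibble::tibble(
    series_id = tools::file_path_sans_ext(basename(manifest$file)),
    stimulus = as.character(manifest$stimulus),
    plant_id = as.character(manifest$plant_id),
    channel = as.integer(manifest$channel),
    sampling_rate_hz = sampling_rate_hz,
    values = values
  )
  validate_signals(out, allow_empty = TRUE)
  out
}

#' Write a signal dataset as per-series CSV files plus a manifest
#'
#' Inverse of [read_signals()]: the round trip preserves labels exactly and
#' values to better than 1e-9.
#'
#' @param signals A signal tibble.
#' @param out_dir Output directory (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
write_signals <- function(signals, out_dir) {
  validate_signals(signals, allow_empty = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  files <- paste0(signals$series_id, ".csv")
  if (nrow(signals) > 0) {
    purrr::pwalk(
      list(files, signals$values, signals$sampling_rate_hz),
      function(f, v, rate) {
        readr::write_csv(
          tibble::tibble(time_s = (seq_along(v) - 1) / rate, value_mV = v),
          file.path(out_dir, f), progress = FALSE
        )
      }
    )
  }
  manifest <- tibble::tibble(
    file = files,
    stimulus = signals$stimulus %||% character(),
    plant_id = signals$plant_id %||% character(),
    channel = signals$channel %||% integer()
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path, progress = FALSE)
  invisible(manifest_path)
}

#' Plot signal traces by stimulus
#'
#' @param signals A signal tibble.
#' @param max_per_class Traces drawn per stimulus (first `max_per_class` rows).
#' @return A ggplot object: value (mV) against time (s), faceted by stimulus.
#' @export
plot_signals <- function(signals, max_per_class = 5L) {
  validate_signals(signals)
  shown <- signals |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::ungroup()
  long <- shown |>
    dplyr::mutate(time_s = purrr::map2(
      .data$values, .data$sampling_rate_hz,
      function(v, r) (seq_along(v) - 1) / r
    )) |>
    dplyr::select("series_id", "stimulus", "time_s", "values") |>
    tidyr::unnest(c("time_s", "values"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$values,
                                     group = .data$series_id)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus), scales = "free_y") +
    ggplot2::labs(x = "time since stimulus (s)", y = "signal (mV)")
}
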