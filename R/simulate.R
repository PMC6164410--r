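#' Define a class-conditional signal template
#'
#' A template describes the post-stimulus response morphology of one stimulus
#' class: a polynomial trend on normalized time x in [0, 1], a multiplicative
#' lognormal amplitude jitter, an occasional polarity reversal (as observed
#' for system-potential-type responses), and additive AR(1) noise.
#'
#' @param label Stimulus label.
#' @param trend_coeffs Polynomial trend coefficients, highest degree first
#'   (at most 10, mirroring the largest feature space).
#' @param amplitude_jitter_sd Lognormal sigma of the per-series amplitude
#'   multiplier (0 = none).
#' @param polarity_flip_prob Probability the whole series is sign-reversed.
#' @param noise_sd_mv Innovation standard deviation of the AR(1) noise (mV).
#' @param ar1_phi AR(1) coefficient in [0, 1); electrophysiological baselines
#'   are strongly autocorrelated, so the benchmark default is 0.95.
#' @param duration_s_range Length-2 vector, min and max series duration (s).
#' @return An object of class `class_template`.
#' @export
class_template <- function(label, trend_coeffs,
                           amplitude_jitter_sd = 0,
                           polarity_flip_prob = 0,
                           noise_sd_mv = 0,
                           ar1_phi = 0,
                           duration_s_range = c(60, 120)) {
  stopifnot(
    is.character(label), length(label) == 1,
    is.numeric(trend_coeffs), length(trend_coeffs) >= 1,
    length(trend_coeffs) <= 10,
    amplitude_jitter_sd >= 0,
    polarity_flip_prob >= 0, polarity_flip_prob <= 1,
    noise_sd_mv >= 0,
    ar1_phi >= 0, ar1_phi < 1,
    length(duration_s_range) == 2, all(duration_s_range > 0),
    duration_s_range[1] <= duration_s_range[2]
  )
  structure(
    list(label = label, trend_coeffs = as.numeric(trend_coeffs),
         amplitude_jitter_sd = amplitude_jitter_sd,
         polarity_flip_prob = polarity_flip_prob,
         noise_sd_mv = noise_sd_mv, ar1_phi = ar1_phi,
         duration_s_range = as.numeric(duration_s_range)),
    class = "class_template"
  )
}

#' Assemble a simulation configuration
#'
#' @param templates List of [class_template()] objects, one per label.
#' @param n_per_class Named integer vector: series count per label, or a
#'   single unnamed integer applied to every template label.
#' @param sampling_rate_hz Sampling rate (Hz), default 10.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(templates, n_per_class, sampling_rate_hz = 10,
                       seed = 1L) {
  if (inherits(templates, "class_template")) templates <- list(templates)
  stopifnot(all(purrr::map_lgl(templates, inherits, "class_template")),
            sampling_rate_hz > 0)
  tmpl_labels <- purrr::map_chr(templates, "label")
  if (anyDuplicated(tmpl_labels)) {
    stop("one template per label required", call. = FALSE)
  }
  if (is.null(names(n_per_class))) {
    stopifnot(length(n_per_class) == 1)
    n_per_class <- stats::setNames(rep(as.integer(n_per_class),
                                       length(tmpl_labels)), tmpl_labels)
  }
  orphan <- setdiff(names(n_per_class), tmpl_labels)
  if (length(orphan) > 0) {
    stop("n_per_class label(s) without a template: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1", call. = FALSE)
  structure(
    list(templates = templates, n_per_class = n_per_class,
         sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Stationary AR(1) noise with innovation sd `sd` and coefficient `phi`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n, 0, sd)
  if (phi == 0) return(z)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (t in 2:n) e[t] <- phi * e[t - 1] + z[t]
  e
}

#' Simulate a labeled dataset of post-stimulus signals
#'
#' Each series is `s * g * P(x) + eps`, with `P` the template trend polynomial
#' on normalized time x in [0, 1], `g` a lognormal amplitude multiplier,
#' `s = -1` with the template's polarity-flip probability (else +1), and `eps`
#' stationary AR(1) noise. Duration is drawn uniformly from the template's
#' range; output is fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A signal tibble (see [validate_signals()]).
#' @export
simulate_signals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rate <- config$sampling_rate_hz
  rows <- purrr::map(config$templates, function(tm) {
    n_series <- config$n_per_class[[tm$label]]
    if (is.null(n_series)) return(NULL)
    purrr::map(seq_len(n_series), function(k) {
      duration <- stats::runif(1, tm$duration_s_range[1],
                               tm$duration_s_range[2])
      n <- max(10L, as.integer(round(duration * rate)) + 1L)
      x <- seq(0, 1, length.out = n)
      g <- stats::rlnorm(1, 0, tm$amplitude_jitter_sd)
      s <- if (stats::runif(1) < tm$polarity_flip_prob) -1 else 1
      v <- s * g * polyval(tm$trend_coeffs, x) + ar1_noise(n, tm$noise_sd_mv,
                                                           tm$ar1_phi)
      tibble::tibble(
        series_id = sprintf("%s_%03d", tm$label, k),
        stimulus = tm$label,
        plant_id = sprintf("%s_plant_%03d", tm$label, (k + 1L) %/% 2L),
        channel = as.integer((k - 1L) %% 2L + 1L),
        sampling_rate_hz = rate,
        values = list(v)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  validate_signals(out)
  out
}

# Fixed degree-5 trend shapes of the three-class benchmark, in mV on x in
# [0, 1]. Shapes are benchmark conventions (distinct global morphologies:
# slow hyperpolarizing drift with partial recovery, fast depolarization with
# plateau, transient hump), not claims about real plants.
benchmark_trends <- function() {
  list(
    NaCl  = c(12, -30, 20, 2, -6, 0),
    H2SO4 = c(40, -130, 160, -92, 24, -1),
    O3    = c(-48, 120, -100, 24, 4, 0.5)
  )
}

#' Default three-class simulation benchmark
#'
#' Three stimulus classes with distinct degree-5 trend templates at 10 Hz,
#' AR(1) noise (phi 0.95), lognormal amplitude jitter (sigma 0.15) and
#' durations of 60-120 s. `separation` sets the noise level relative to each
#' template's trend peak-to-peak amplitude: `"high"` gives a signal-to-noise
#' ratio of 25 (>= 20), `"low"` an SNR of 1.5 (<= 2), where SNR = trend
#' peak-to-peak / stationary noise sd. The AR(1) innovation sd stored in the
#' template is the stationary sd scaled by `sqrt(1 - phi^2)`.
#'
#' @param separation `"high"` or `"low"`.
#' @param n_per_class Series per class (>= 4).
#' @param seed Integer seed.
#' @return A [sim_config()] with three templates.
#' @export
default_benchmark_config <- function(separation = c("high", "low"),
                                     n_per_class = 20L, seed = 1L) {
  separation <- match.arg(separation)
  stopifnot(n_per_class >= 4)
  snr <- if (separation == "high") 25 else 1.5
  xg <- seq(0, 1, length.out = 2001)
  templates <- purrr::imap(benchmark_trends(), function(coeffs, label) {
    trend <- polyval(coeffs, xg)
    ptp <- diff(range(trend))
    class_template(
      label = label, trend_coeffs = coeffs,
      amplitude_jitter_sd = 0.15, polarity_flip_prob = 0,
      noise_sd_mv = (ptp / snr) * sqrt(1 - 0.95^2), ar1_phi = 0.95,
      duration_s_range = c(60, 120)
    )
  })
  sim_config(unname(templates), n_per_class = as.integer(n_per_class),
             sampling_rate_hz = 10, seed = seed)
}
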