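#' @importFrom rlang .data %||%
#' @importFrom stats predict
NULL

# Horner evaluation of a polynomial with coefficients in descending powers.
polyval <- function(coeffs, x) {
  out <- rep(coeffs[1], length(x))
  if (length(coeffs) > 1) {
    for (k in 2:length(coeffs)) out <- out * x + coeffs[k]
  }
  out
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
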