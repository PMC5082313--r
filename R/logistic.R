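#' Four-parameter logistic splicing dose-response curves
#'
#' A cassette exon's inclusion level \eqn{\Psi} responds to the concentration
#' of functional MBNL protein as a sigmoid on the log-concentration axis:
#' \deqn{\Psi(x) = \Psi_{min} + \frac{\Psi_{max} - \Psi_{min}}
#'   {1 + 10^{(\log_{10} EC_{50} - x)\,\cdot\, slope}}}
#' where \eqn{x} is log10 relative MBNL concentration. This is the
#' "log(agonist) vs response, variable slope" model standard in pharmacology.
#' The slope's sign encodes direction: negative means MBNL promotes exon
#' skipping (inclusion falls with concentration), positive means MBNL promotes
#' inclusion.
#'
#' `sigmoid_params()` builds a validated parameter set. Plateaus are stored
#' ordered (`psi_min <= psi_max`); the direction of response lives entirely in
#' the slope sign.
#'
#' @param psi_min,psi_max Lower and upper plateau inclusion levels, in `[0,1]`.
#' @param ec50 Concentration (relative, arbitrary units, > 0) at which the
#'   response is halfway between the plateaus.
#' @param slope Hill-type slope, finite and nonzero for an identifiable curve.
#' @param sigma Optional residual noise SD on the psi scale (>= 0).
#' @return A list with class `"sigmoid_params"`.
#' @examples
#' wt <- sigmoid_params(psi_min = 0.41, psi_max = 0.98, ec50 = 0.19, slope = -1.8)
#' logistic_psi(log10(0.19), wt)  # midpoint: (0.41 + 0.98) / 2
#' @export
sigmoid_params <- function(psi_min, psi_max, ec50, slope, sigma = NA_real_) {
  stopifnot(is.numeric(psi_min), is.numeric(psi_max), is.numeric(ec50),
            is.numeric(slope))
  if (!all(is.finite(c(psi_min, psi_max, ec50, slope)))) {
    abort("sigmoid parameters must be finite", class = "mbnldose_invalid_argument")
  }
  if (psi_min < 0 || psi_max > 1 || psi_min > 1 || psi_max < 0) {
    abort("plateaus psi_min and psi_max must lie in [0, 1]",
          class = "mbnldose_invalid_argument")
  }
  if (ec50 <= 0) {
    abort("ec50 must be positive", class = "mbnldose_invalid_argument")
  }
  if (!is.na(sigma) && (!is.finite(sigma) || sigma < 0)) {
    abort("sigma must be a nonnegative number", class = "mbnldose_invalid_argument")
  }
  # canonical orientation: ordered plateaus, direction carried by slope sign
  if (psi_min > psi_max) {
    tmp <- psi_min; psi_min <- psi_max; psi_max <- tmp
    slope <- -slope
  }
  structure(
    list(psi_min = psi_min, psi_max = psi_max, ec50 = ec50, slope = slope,
         sigma = sigma),
    class = "sigmoid_params"
  )
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf(
    "4PL splicing curve: psi_min=%.3g psi_max=%.3g EC50=%.3g slope=%.3g%s\n",
    x$psi_min, x$psi_max, x$ec50, x$slope,
    if (is.na(x$sigma)) "" else sprintf(" sigma=%.3g", x$sigma)))
  invisible(x)
}

#' Evaluate the four-parameter logistic at log10 concentration
#'
#' @param log_conc Numeric vector of log10 relative MBNL concentrations.
#'   `-Inf` is accepted and returns the appropriate plateau.
#' @param params A [sigmoid_params()] object (or a list with the same fields).
#' @return Numeric vector of predicted inclusion levels, each within
#'   `[psi_min, psi_max]`.
#' @details The curve is point-symmetric about `log10(ec50)`:
#'   `logistic_psi(x) + logistic_psi(2*log10(ec50) - x) == psi_min + psi_max`.
#'   A zero slope with distinct plateaus has no defined direction and is
#'   rejected as degenerate.
#' @export
logistic_psi <- function(log_conc, params) {
  p <- params
  if (p$slope == 0 && p$psi_min != p$psi_max) {
    abort("slope = 0 with distinct plateaus is a degenerate model",
          class = "mbnldose_degenerate_model")
  }
  if (p$slope == 0 || p$psi_min == p$psi_max) {
    return(rep((p$psi_min + p$psi_max) / 2, length(log_conc)))
  }
  e <- (log10(p$ec50) - log_conc) * p$slope
  # e = +/-Inf at log_conc = -Inf is intended: the curve hits its plateau
  p$psi_min + (p$psi_max - p$psi_min) / (1 + 10^pmin(e, 300))
}

#' Invert the logistic: concentration giving an observed inclusion level
#'
#' Closed-form inverse of [logistic_psi()] for psi strictly between the
#' plateaus: `m* = ec50 * 10^(-(1/slope) * log10((psi_max - psi)/(psi - psi_min)))`.
#'
#' @param psi Inclusion level strictly inside `(psi_min, psi_max)`.
#' @param params A [sigmoid_params()] object.
#' @return Concentration (same relative units as `ec50`).
#' @export
invert_logistic <- function(psi, params) {
  p <- params
  if (any(psi <= p$psi_min | psi >= p$psi_max)) {
    abort("psi must lie strictly between the plateaus to invert",
          class = "mbnldose_invalid_argument")
  }
  p$ec50 * 10^(-(1 / p$slope) * log10((p$psi_max - psi) / (psi - p$psi_min)))
}
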