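#' Fit a constrained four-parameter logistic to a dose series
#'
#' Least-squares fit of the variable-slope logistic ([logistic_psi()]) to
#' observed inclusion levels against log10 relative concentration, with both
#' plateaus restricted to `[0, 1]`. The optimum is found by L-BFGS-B from a
#' deterministic grid of starting points spanning the parameter box (12
#' starts), which avoids the local optima a single start can fall into when
#' the slope sign or EC50 decade is wrong. Ties are broken by lowest residual
#' sum of squares, then smallest absolute slope.
#'
#' Interval estimates for EC50 and slope are curvature-based: the
#' Gauss-Newton covariance \eqn{\hat\sigma^2 (J'J)^{-1}} at the optimum, with
#' the EC50 interval computed on the log10 scale and back-transformed. They
#' describe local curvature of the objective, not a profile or bootstrap.
#'
#' @param series Data frame with columns `log_conc` (log10 relative MBNL) and
#'   `psi` (inclusion, in `[0,1]`); alternatively a column `conc` of raw
#'   concentrations, which is log10-transformed.
#' @param bounds Length-2 numeric, bounds for both plateaus (default `c(0, 1)`).
#' @return An object of class `"dose_fit"`: list with `params`
#'   ([sigmoid_params()] with `sigma` set to the residual SD), `r_squared`,
#'   `conf_int` (tibble for `ec50` and `slope`), `sse`, `n`, and `data`.
#' @examples
#' wt <- sigmoid_params(0.41, 0.98, 0.19, -1.8)
#' x <- seq(log10(0.01), log10(10), length.out = 12)
#' fit <- fit_dose_response(tibble::tibble(log_conc = x, psi = logistic_psi(x, wt)))
#' tidy(fit)
#' @export
fit_dose_response <- function(series, bounds = c(0, 1)) {
  series <- as_tibble(series)
  if (!"log_conc" %in% names(series)) {
    if (!"conc" %in% names(series)) {
      abort("series needs a log_conc or conc column",
            class = "mbnldose_invalid_argument")
    }
    series$log_conc <- log10(series$conc)
  }
  keep <- is.finite(series$log_conc) & is.finite(series$psi)
  series <- series[keep, , drop = FALSE]
  x <- series$log_conc
  y <- series$psi
  if (length(unique(x)) < 4) {
    abort("need at least 4 distinct concentrations for a 4-parameter fit",
          class = "mbnldose_insufficient_data")
  }
  if (any(y < 0 | y > 1)) {
    abort("psi observations must lie in [0, 1]",
          class = "mbnldose_invalid_argument")
  }
  if (diff(range(y)) < sqrt(.Machine$double.eps)) {
    abort("all psi values identical: curve is unidentifiable",
          class = "mbnldose_unidentifiable_fit")
  }

  # theta = (psi_min, psi_max, log10 ec50, slope); plateaus unordered here,
  # canonicalized at the end
  curve <- function(theta, x) {
    theta[1] + (theta[2] - theta[1]) /
      (1 + 10^pmin((theta[3] - x) * theta[4], 300))
  }
  sse <- function(theta) sum((y - curve(theta, x))^2)

  lec_lim <- range(x) + c(-1, 1)
  lower <- c(bounds[1], bounds[1], lec_lim[1], -20)
  upper <- c(bounds[2], bounds[2], lec_lim[2], 20)
  starts <- tidyr::expand_grid(
    lo = min(y), hi = max(y),
    lec = quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    slope = c(-3, -0.7, 0.7, 3)
  )
  fits <- purrr::pmap(starts, function(lo, hi, lec, slope) {
    optim(c(lo, hi, lec, slope), sse, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 500, factr = 1e4))
  })
  vals <- purrr::map_dbl(fits, "value")
  slopes <- abs(purrr::map_dbl(fits, ~ .x$par[4]))
  best <- order(vals, slopes)[1]
  theta <- fits[[best]]$par
  if (theta[1] > theta[2]) {
    # canonical labeling: ordered plateaus, direction on the slope sign
    theta <- c(theta[2], theta[1], theta[3], -theta[4])
  }

  n <- length(y)
  dof <- max(n - 4, 1)
  sigma_hat <- sqrt(fits[[best]]$value / dof)
  params <- sigmoid_params(psi_min = theta[1], psi_max = theta[2],
                           ec50 = 10^theta[3], slope = theta[4],
                           sigma = sigma_hat)

  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - fits[[best]]$value / ss_tot

  conf <- .gauss_newton_ci(theta, curve, x, y, sigma_hat, dof)
  structure(
    list(params = params, r_squared = r2, conf_int = conf,
         sse = fits[[best]]$value, n = n, data = series),
    class = "dose_fit"
  )
}

# 95% curvature-based intervals for ec50 (via log10 scale) and slope
.gauss_newton_ci <- function(theta, curve, x, y, sigma_hat, dof) {
  eps <- 1e-6
  J <- vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    (curve(up, x) - curve(dn, x)) / (2 * eps)
  }, numeric(length(x)))
  cov <- tryCatch(sigma_hat^2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, 4, 4))
  tq <- stats::qt(0.975, dof)
  se <- sqrt(pmax(diag(cov), 0))
  tibble(
    term = c("ec50", "slope"),
    estimate = c(10^theta[3], theta[4]),
    conf_low = c(10^(theta[3] - tq * se[3]), theta[4] - tq * se[4]),
    conf_high = c(10^(theta[3] + tq * se[3]), theta[4] + tq * se[4])
  )
}

#' @export
print.dose_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "4PL fit (n=%d): EC50=%.3g slope=%.3g psi_min=%.3g psi_max=%.3g R^2=%.4f\n",
    x$n, p$ec50, p$slope, p$psi_min, p$psi_max, x$r_squared))
  invisible(x)
}

#' @describeIn fit_dose_response One row per parameter, with 95% curvature
#'   intervals where available.
#' @param x A `dose_fit` object.
#' @param ... Unused.
#' @export
tidy.dose_fit <- function(x, ...) {
  p <- x$params
  est <- tibble(
    term = c("psi_min", "psi_max", "ec50", "slope", "sigma"),
    estimate = c(p$psi_min, p$psi_max, p$ec50, p$slope, p$sigma)
  )
  left_join(est, select(x$conf_int, -"estimate"), by = "term")
}

#' @describeIn fit_dose_response One-row fit summary (R^2, SSE, n).
#' @export
glance.dose_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, sse = x$sse, sigma = x$params$sigma, n = x$n)
}

#' @describeIn fit_dose_response Observed points with the fitted curve.
#' @param object A `dose_fit` object.
#' @export
autoplot.dose_fit <- function(object, ...) {
  grid <- tibble(log_conc = seq(min(object$data$log_conc),
                                max(object$data$log_conc), length.out = 200))
  grid$psi <- logistic_psi(grid$log_conc, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$log_conc, .data$psi)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "log10 relative [MBNL]", y = expression(Psi)) +
    ggplot2::ylim(0, 1)
}

#' Mean absolute inclusion shift of a sample from a reference
#'
#' Total splicing dysregulation of one sample: the mean over events of the
#' absolute difference between the sample's inclusion and a reference
#' (typically the control-group mean) for the same event. Missing entries in
#' either vector are excluded.
#'
#' @param psi_sample,psi_reference Aligned numeric vectors of per-event
#'   inclusion levels; `NA` allowed.
#' @return A single nonnegative number.
#' @export
mean_delta_psi <- function(psi_sample, psi_reference) {
  if (length(psi_sample) != length(psi_reference)) {
    abort("vectors must be aligned on the same events",
          class = "mbnldose_invalid_argument")
  }
  d <- abs(psi_sample - psi_reference)
  if (all(is.na(d))) {
    abort("no overlapping non-missing events",
          class = "mbnldose_undefined_statistic")
  }
  mean(d, na.rm = TRUE)
}
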