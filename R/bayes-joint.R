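#' Prior specification for joint inference
#'
#' Priors for the joint model: plateaus and latent concentration uniform on
#' `[0,1]`, log10 EC50 Normal(0.5, 1), slope Normal(0, 1), and a per-event
#' observation-noise SD uniform on `[0,1]`. The bounded concentration prior
#' anchors the scale of the otherwise shift-invariant log-concentration axis;
#' the log-EC50 prior is mildly informative for the same reason.
#'
#' @param log_ec50_mean,log_ec50_sd Normal prior on log10 EC50.
#' @param slope_mean,slope_sd Normal prior on the slope.
#' @return A list with class `"prior_spec"`.
#' @export
prior_spec <- function(log_ec50_mean = 0.5, log_ec50_sd = 1,
                       slope_mean = 0, slope_sd = 1) {
  vals <- c(log_ec50_mean, log_ec50_sd, slope_mean, slope_sd)
  if (any(!is.finite(vals)) || log_ec50_sd <= 0 || slope_sd <= 0) {
    abort("prior hyperparameters must be finite with positive SDs",
          class = "mbnldose_invalid_argument")
  }
  structure(list(log_ec50_mean = log_ec50_mean, log_ec50_sd = log_ec50_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd),
            class = "prior_spec")
}

.joint_model_string <- function() {
  "model {
    for (e in 1:E) {
      pmin_raw[e] ~ dunif(0, 1)
      pmax_raw[e] ~ dunif(0, 1)
      lec[e] ~ dnorm(lec_mu, lec_tau)
      slope[e] ~ dnorm(slope_mu, slope_tau)
      sigma[e] ~ dunif(0, 1)
      tau[e] <- pow(sigma[e], -2)
    }
    for (s in 1:S) {
      mbnl[s] ~ dunif(0, 1)
    }
    for (k in 1:N) {
      mu[k] <- pmin_raw[ev[k]] + (pmax_raw[ev[k]] - pmin_raw[ev[k]]) /
        (1 + pow(10, (lec[ev[k]] - log(mbnl[sa[k]]) / log(10)) * slope[ev[k]]))
      psi[k] ~ dnorm(mu[k], tau[ev[k]])
    }
  }"
}

#' Joint Bayesian inference of curve parameters and per-sample concentration
#'
#' Fits the full hierarchical model to an inclusion matrix alone: every event
#' gets a four-parameter logistic curve (plus an observation-noise SD), every
#' sample gets a latent functional MBNL concentration on `[0,1]`, and each
#' present matrix cell contributes a Normal likelihood term centred on the
#' curve value at that sample's log10 concentration. Missing cells contribute
#' nothing. Posteriors are obtained by MCMC (JAGS); with no data at all the
#' posterior is the prior, which is then sampled directly.
#'
#' Plateau priors are uniform and unordered, so each event's labeling is only
#' identified jointly with its slope sign; retained draws are canonicalized
#' per draw (plateaus ordered, slope sign flipped when they swap — the two
#' labelings give the identical curve) before summarizing.
#'
#' @param psi_long Data frame with columns `event`, `sample`, `psi` (long
#'   form, one row per cell; `NA` psi rows are treated as missing). A wide
#'   matrix read by [read_psi_table()] is also accepted.
#' @param priors A [prior_spec()].
#' @param iterations Retained MCMC iterations per chain (default 1000).
#' @param warmup Discarded adaptation + burn-in iterations (default 1000).
#' @param chains Number of chains (default 4).
#' @param seed Integer seed controlling all chains' RNG.
#' @param anchor_slopes Optional named numeric vector giving the known sign of
#'   the regulatory direction for one or more events (positive = the factor
#'   promotes inclusion, negative = promotes skipping). The inclusion matrix
#'   alone cannot distinguish a solution from its mirror image (all
#'   concentrations reflected on the log axis with every slope sign flipped),
#'   so when the direction of at least one event is known experimentally —
#'   as it is for validated MBNL-responsive exons — supplying it here pins
#'   the orientation. Without anchors the denser posterior mode is reported.
#' @return An object of class `"cohort_posterior"`: list with
#'   \describe{
#'     \item{event_params}{tibble of posterior mean and 5%/95% quantiles for
#'       `psi_min`, `psi_max`, `log_ec50`, `slope`, `sigma` per event.}
#'     \item{mbnl}{tibble of posterior mean and 5%/95% quantiles of `[MBNL]`
#'       per sample.}
#'     \item{draws}{matrix of retained draws (canonicalized).}
#'     \item{diagnostics}{list with `min_ess`, `ess`, `n_draws`, `warnings`.}
#'   }
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(4, 8, sigma = 0.03, seed = 2)
#' post <- infer_joint(cohort$psi, iterations = 400, warmup = 400,
#'                     chains = 1, seed = 9)
#' post$mbnl
#' }
#' @export
infer_joint <- function(psi_long, priors = prior_spec(),
                        iterations = 1000, warmup = 1000, chains = 4,
                        seed = 1L, anchor_slopes = NULL) {
  if (!inherits(priors, "prior_spec")) {
    abort("priors must be a prior_spec()", class = "mbnldose_invalid_argument")
  }
  psi_long <- as_tibble(psi_long)
  stopifnot(all(c("event", "sample", "psi") %in% names(psi_long)))
  present <- psi_long[!is.na(psi_long$psi), , drop = FALSE]
  if (nrow(present) > 0 && any(present$psi < 0 | present$psi > 1)) {
    abort("psi values must lie in [0, 1]", class = "mbnldose_invalid_argument")
  }
  events <- sort(unique(psi_long$event))
  samples <- sort(unique(psi_long$sample))
  warnings <- character(0)
  if (length(events) < 2 || length(samples) < 3) {
    warnings <- c(warnings,
                  "fewer than 2 events or 3 samples: posterior will be weakly identified")
  }

  if (nrow(present) == 0) {
    draws <- .prior_draws(events, samples, priors, chains * iterations, seed)
    ess <- rep(nrow(draws), ncol(draws))
  } else {
    data <- list(
      E = length(events), S = length(samples), N = nrow(present),
      ev = match(present$event, events), sa = match(present$sample, samples),
      psi = present$psi,
      lec_mu = priors$log_ec50_mean, lec_tau = priors$log_ec50_sd^-2,
      slope_mu = priors$slope_mean, slope_tau = priors$slope_sd^-2
    )
    inits <- .orientation_inits(present, events, samples, chains, seed)
    n_adapt <- max(100L, floor(warmup / 2))
    n_burn <- warmup - n_adapt
    jm <- rjags::jags.model(textConnection(.joint_model_string()),
                            data = data, inits = inits, n.chains = chains,
                            n.adapt = n_adapt, quiet = TRUE)
    if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
    sm <- rjags::coda.samples(
      jm, c("pmin_raw", "pmax_raw", "lec", "slope", "sigma", "mbnl"),
      n.iter = iterations, progress.bar = "none")
    sel <- .select_orientation(sm, data, priors,
                               anchor = anchor_slopes, events = events)
    if (length(sel$dropped) > 0) {
      warnings <- c(warnings, sprintf(
        "orientation multimodality detected: %d of %d chains sampled the mirrored mode and were dropped",
        length(sel$dropped), chains))
    }
    kept <- sm[sel$kept]
    class(kept) <- "mcmc.list"
    ess <- tryCatch(coda::effectiveSize(kept), error = function(e) NULL)
    draws <- .canonicalize_draws(do.call(rbind, lapply(kept, as.matrix)),
                                 events, samples)
  }

  event_params <- purrr::map_dfr(seq_along(events), function(e) {
    purrr::map_dfr(
      c(psi_min = "psi_min", psi_max = "psi_max", log_ec50 = "log_ec50",
        slope = "slope", sigma = "sigma"),
      function(par) .summarise_draws(draws[, sprintf("%s[%d]", par, e)]),
      .id = "parameter")
  }, .id = "idx") |>
    mutate(event = events[as.integer(.data$idx)], .before = 1) |>
    select(-"idx")

  mbnl <- purrr::map_dfr(seq_along(samples), function(s) {
    .summarise_draws(draws[, sprintf("mbnl[%d]", s)])
  }) |>
    mutate(sample = samples, .before = 1)

  min_ess <- if (is.null(ess)) NA_real_ else min(ess)
  if (is.finite(min_ess) && min_ess < 50) {
    warnings <- c(warnings, sprintf(
      "low effective sample size (min %.0f): consider more iterations", min_ess))
  }
  structure(
    list(event_params = event_params, mbnl = mbnl, draws = draws,
         events = events, samples = samples,
         diagnostics = list(min_ess = min_ess, ess = ess,
                            n_draws = nrow(draws), warnings = warnings)),
    class = "cohort_posterior"
  )
}

# The likelihood is invariant under mirroring all log10 concentrations about
# a constant with every slope sign flipped (m -> 10^c / m, lec -> c - lec,
# slope -> -slope), so the posterior has a mirrored minor mode. The true mode
# carries vastly more mass (the mirror compresses the bounded concentrations
# toward 0, shrinking its volume), but single chains can get trapped. Chains
# are therefore seeded in both orientations from a PC1-based pre-estimate and
# per-event quick curve fits, and the dominant orientation is selected
# afterwards by the Laplace-motivated mass statistic sum_s log(m_s).
.orientation_inits <- function(present, events, samples, chains, seed) {
  S <- length(samples)
  wide <- matrix(NA_real_, length(events), S,
                 dimnames = list(events, samples))
  wide[cbind(match(present$event, events), match(present$sample, samples))] <-
    present$psi
  z <- t(apply(wide, 1, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    if (sd(r) > 0) (r - mean(r)) / sd(r) else r * 0
  }))
  score <- tryCatch(svd(z, nu = 0, nv = 1)$v[, 1], error = function(e) rep(0, S))
  if (all(score == 0)) score <- seq_len(S)
  m0 <- (rank(score, ties.method = "first") - 0.5) / S

  event_inits <- function(m) {
    fits <- lapply(events, function(e) {
      rows <- present[present$event == e, ]
      d <- tibble(log_conc = log10(m[match(rows$sample, samples)]),
                  psi = rows$psi)
      tryCatch({
        f <- fit_dose_response(d)
        p <- f$params
        list(pmin = p$psi_min, pmax = p$psi_max, lec = log10(p$ec50),
             slope = max(min(p$slope, 8), -8),
             sigma = min(max(p$sigma, 0.02), 0.9))
      }, error = function(err) {
        list(pmin = max(min(rows$psi), 0.01), pmax = min(max(rows$psi), 0.99),
             lec = 0, slope = 0.5, sigma = 0.1)
      })
    })
    list(pmin_raw = purrr::map_dbl(fits, "pmin"),
         pmax_raw = purrr::map_dbl(fits, "pmax"),
         lec = purrr::map_dbl(fits, "lec"),
         slope = purrr::map_dbl(fits, "slope"),
         sigma = purrr::map_dbl(fits, "sigma"),
         mbnl = m)
  }
  orient <- list(event_inits(m0), if (chains > 1) event_inits(1 - m0) else NULL)
  lapply(seq_len(chains), function(ch) {
    ini <- orient[[if (ch %% 2 == 1) 1 else 2]]
    c(ini, list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed) * 1000L + ch))
  })
}

# unnormalized log joint density (likelihood + non-flat prior terms) of one draw
.log_joint <- function(draw, data, priors) {
  E <- data$E; S <- data$S
  pmin <- draw[sprintf("pmin_raw[%d]", seq_len(E))]
  pmax <- draw[sprintf("pmax_raw[%d]", seq_len(E))]
  lec <- draw[sprintf("lec[%d]", seq_len(E))]
  sl <- draw[sprintf("slope[%d]", seq_len(E))]
  sg <- draw[sprintf("sigma[%d]", seq_len(E))]
  m <- draw[sprintf("mbnl[%d]", seq_len(S))]
  e <- data$ev; s <- data$sa
  mu <- pmin[e] + (pmax[e] - pmin[e]) /
    (1 + 10^pmin((lec[e] - log10(m[s])) * sl[e], 300))
  sum(dnorm(data$psi, mu, sg[e], log = TRUE)) +
    sum(dnorm(lec, priors$log_ec50_mean, priors$log_ec50_sd, log = TRUE)) +
    sum(dnorm(sl, priors$slope_mean, priors$slope_sd, log = TRUE))
}

# Keep the chain cluster in the preferred orientation. With slope-sign
# anchors the orientation agreeing with the known regulatory directions
# wins; otherwise the cluster with higher mean log joint density does (the
# mirror mode typically sits lower).
.select_orientation <- function(sm, data, priors, anchor = NULL,
                                events = NULL) {
  cn <- colnames(as.matrix(sm[[1]]))
  mb_cols <- grep("mbnl", cn, fixed = TRUE)
  chain_mat <- lapply(sm, as.matrix)
  means <- lapply(chain_mat, function(m) colMeans(m[, mb_cols, drop = FALSE]))
  S <- length(mb_cols)
  same_as_1 <- vapply(means, function(mu) {
    if (S < 3 || sd(mu) == 0 || sd(means[[1]]) == 0) TRUE
    else cor(mu, means[[1]]) >= 0
  }, logical(1))
  groups <- list(which(same_as_1), which(!same_as_1))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 1) {
    return(list(kept = groups[[1]], dropped = integer(0)))
  }
  gscore <- if (!is.null(anchor) && length(anchor) > 0) {
    anchored <- intersect(names(anchor), events)
    cols <- sprintf("slope[%d]", match(anchored, events))
    vapply(groups, function(g) {
      sl <- colMeans(do.call(rbind, lapply(chain_mat[g], function(m)
        m[, cols, drop = FALSE])))
      mean(sign(sl) == sign(anchor[anchored]))
    }, numeric(1))
  } else {
    vapply(groups, function(g) {
      mean(vapply(chain_mat[g], function(m) {
        idx <- unique(round(seq(1, nrow(m), length.out = min(100, nrow(m)))))
        mean(apply(m[idx, , drop = FALSE], 1, .log_joint, data, priors))
      }, numeric(1)))
    }, numeric(1))
  }
  best <- which.max(gscore)
  list(kept = groups[[best]], dropped = unlist(groups[-best]))
}

# direct prior sampling for the no-data case (posterior = prior)
.prior_draws <- function(events, samples, priors, n, seed) {
  set.seed(seed)
  E <- length(events); S <- length(samples)
  cols <- list()
  for (e in seq_len(E)) {
    a <- runif(n); b <- runif(n)
    cols[[sprintf("psi_min[%d]", e)]] <- pmin(a, b)
    cols[[sprintf("psi_max[%d]", e)]] <- pmax(a, b)
    cols[[sprintf("log_ec50[%d]", e)]] <- rnorm(n, priors$log_ec50_mean,
                                                priors$log_ec50_sd)
    sl <- rnorm(n, priors$slope_mean, priors$slope_sd)
    cols[[sprintf("slope[%d]", e)]] <- ifelse(a <= b, sl, -sl)
    cols[[sprintf("sigma[%d]", e)]] <- runif(n)
  }
  for (s in seq_len(S)) cols[[sprintf("mbnl[%d]", s)]] <- runif(n)
  do.call(cbind, cols)
}

# order plateaus within each draw; a swap flips the slope sign (identical curve)
.canonicalize_draws <- function(m, events, samples) {
  E <- length(events)
  out <- m
  rename_map <- colnames(m)
  for (e in seq_len(E)) {
    lo <- m[, sprintf("pmin_raw[%d]", e)]
    hi <- m[, sprintf("pmax_raw[%d]", e)]
    sl <- m[, sprintf("slope[%d]", e)]
    swap <- lo > hi
    out[, sprintf("pmin_raw[%d]", e)] <- ifelse(swap, hi, lo)
    out[, sprintf("pmax_raw[%d]", e)] <- ifelse(swap, lo, hi)
    out[, sprintf("slope[%d]", e)] <- ifelse(swap, -sl, sl)
  }
  rename_map <- sub("^pmin_raw", "psi_min", rename_map)
  rename_map <- sub("^pmax_raw", "psi_max", rename_map)
  rename_map <- sub("^lec", "log_ec50", rename_map)
  colnames(out) <- rename_map
  out
}

.summarise_draws <- function(x) {
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  tibble(mean = mean(x), q05 = q[1], q95 = q[2])
}

#' Summarize retained MCMC draws
#'
#' Posterior mean and empirical 5%/95% quantiles per parameter column.
#'
#' @param draws Matrix of retained draws (>= 100 rows), columns named by
#'   parameter.
#' @return Tibble with `parameter`, `mean`, `q05`, `q95`.
#' @export
posterior_summaries <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100) {
    abort("need at least 100 retained draws to summarize",
          class = "mbnldose_insufficient_draws")
  }
  if (is.null(colnames(draws))) {
    colnames(draws) <- sprintf("param_%d", seq_len(ncol(draws)))
  }
  purrr::map_dfr(colnames(draws), function(nm) {
    s <- .summarise_draws(draws[, nm])
    mutate(s, parameter = nm, .before = 1)
  })
}

#' @export
print.cohort_posterior <- function(x, ...) {
  cat(sprintf(
    "Joint splicing posterior: %d events, %d samples, %d draws (min ESS %.0f)\n",
    length(x$events), length(x$samples), x$diagnostics$n_draws,
    x$diagnostics$min_ess))
  for (w in x$diagnostics$warnings) cat(" note:", w, "\n")
  invisible(x)
}

#' @describeIn infer_joint Long tibble of posterior summaries for every
#'   parameter (event curves and per-sample concentrations).
#' @param x A `cohort_posterior` object.
#' @param ... Unused.
#' @export
tidy.cohort_posterior <- function(x, ...) {
  bind_rows(
    x$event_params |>
      rename(unit = "event") |>
      mutate(kind = "event", .before = 1),
    x$mbnl |>
      mutate(parameter = "mbnl") |>
      rename(unit = "sample") |>
      mutate(kind = "sample", .before = 1)
  )
}

#' @describeIn infer_joint One-row summary with dimensions and diagnostics.
#' @export
glance.cohort_posterior <- function(x, ...) {
  tibble(n_events = length(x$events), n_samples = length(x$samples),
         n_draws = x$diagnostics$n_draws, min_ess = x$diagnostics$min_ess,
         n_warnings = length(x$diagnostics$warnings))
}

#' @describeIn infer_joint Inferred per-sample concentration with 90%
#'   credible bars.
#' @param object A `cohort_posterior` object.
#' @export
autoplot.cohort_posterior <- function(object, ...) {
  d <- arrange(object$mbnl, .data$mean)
  d$sample <- factor(d$sample, levels = d$sample)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q05, ymax = .data$q95)) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "inferred functional [MBNL]", x = NULL) +
    ggplot2::ylim(0, 1)
}

#' Extract trained event curves from a joint posterior
#'
#' Posterior-mean curve parameters per event, with the observation-noise SD
#' recomputed directly from the training data residuals (so that events whose
#' observed inclusion hugs the fitted curve act as sharper biomarkers). An
#' event whose residual SD underflows is floored at `sigma_floor`, since a
#' zero-noise curve would put infinite weight on one observation.
#'
#' @param posterior A `cohort_posterior` from [infer_joint()].
#' @param psi_long The training data the posterior was fitted to.
#' @param sigma_floor Minimum allowed sigma (default 0.01 psi units).
#' @return Tibble with columns `event`, `psi_min`, `psi_max`, `ec50`,
#'   `slope`, `sigma`.
#' @export
trained_curves <- function(posterior, psi_long, sigma_floor = 0.01) {
  wide <- posterior$event_params |>
    select("event", "parameter", "mean") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "mean") |>
    mutate(ec50 = 10^.data$log_ec50) |>
    select("event", "psi_min", "psi_max", "ec50", "slope")
  mhat <- setNames(posterior$mbnl$mean, posterior$mbnl$sample)
  resid <- psi_long |>
    filter(!is.na(.data$psi)) |>
    left_join(wide, by = "event") |>
    mutate(
      pred = purrr::pmap_dbl(
        list(.data$psi_min, .data$psi_max, .data$ec50, .data$slope,
             .data$sample),
        function(lo, hi, ec, sl, sa) {
          logistic_psi(log10(mhat[[sa]]),
                       list(psi_min = lo, psi_max = hi, ec50 = ec, slope = sl))
        }),
      resid = .data$psi - .data$pred
    ) |>
    group_by(.data$event) |>
    summarise(sigma = sqrt(mean(.data$resid^2)), .groups = "drop")
  wide |>
    left_join(resid, by = "event") |>
    mutate(sigma = pmax(.data$sigma, sigma_floor))
}
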