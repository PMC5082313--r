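#' Cross-validation configuration
#'
#' @param train_frac Fraction of samples used for training (default 0.70).
#' @param n_trials Number of random train/test divisions (default 120).
#' @param seed Integer seed; together with a trial index it fully determines
#'   each split.
#' @return A list with class `"crossval_config"`.
#' @export
crossval_config <- function(train_frac = 0.70, n_trials = 120, seed = 1L) {
  if (!is.finite(train_frac) || train_frac <= 0 || train_frac >= 1) {
    abort("train_frac must lie strictly in (0, 1)",
          class = "mbnldose_invalid_argument")
  }
  if (n_trials < 1) {
    abort("n_trials must be >= 1", class = "mbnldose_invalid_argument")
  }
  structure(list(train_frac = train_frac, n_trials = n_trials,
                 seed = as.integer(seed)),
            class = "crossval_config")
}

#' Split a cohort into training and test samples
#'
#' Disjoint, exhaustive split with `round(train_frac * n)` training samples,
#' reproducible from `(seed, trial_index)`.
#'
#' @param sample_ids Character vector of sample identifiers (>= 2).
#' @param config A [crossval_config()].
#' @param trial_index 1-based trial number.
#' @return List with `train` and `test` character vectors.
#' @export
split_cohort <- function(sample_ids, config = crossval_config(),
                         trial_index = 1L) {
  n <- length(sample_ids)
  if (n < 2) {
    abort("need at least 2 samples to split", class = "mbnldose_invalid_argument")
  }
  set.seed(config$seed * 10000L + as.integer(trial_index))
  n_train <- min(max(round(config$train_frac * n), 1L), n - 1L)
  train <- sort(sample(sample_ids, n_train))
  list(train = train, test = sort(setdiff(sample_ids, train)))
}

#' Disease-severity stratum from inferred concentration
#'
#' Samples are stratified by functional MBNL concentration: severe below
#' 0.33, moderate from 0.33 up to (but excluding) 0.66, mild at 0.66 and
#' above. Lower boundaries are assigned to the less-severe stratum they
#' open.
#'
#' @param mbnl Numeric vector in `[0,1]`.
#' @return Factor with levels `severe`, `moderate`, `mild`.
#' @examples
#' severity_group(c(0.20, 0.50, 0.90))
#' @export
severity_group <- function(mbnl) {
  if (any(!is.finite(mbnl) | mbnl < 0 | mbnl > 1)) {
    abort("mbnl must lie in [0, 1]", class = "mbnldose_invalid_argument")
  }
  cut(mbnl, breaks = c(-Inf, 0.33, 0.66, Inf), right = FALSE,
      labels = c("severe", "moderate", "mild"))
}

# shared cross-validation engine: per trial, per event, per test sample,
# the unnormalized log-likelihood grid of [MBNL]; power at full-data truth.
# Returns a long tibble (trial, event, sample, stratum, truth) plus the
# log-grid list for panel combination.
.cv_engine <- function(psi_long, config, truth, grid_size, mcmc,
                       anchor_slopes = NULL) {
  psi_long <- as_tibble(psi_long)
  samples <- sort(unique(psi_long$sample))
  events <- sort(unique(psi_long$event))
  grid <- seq(0, 1, length.out = grid_size)
  lg <- log10(grid)

  purrr::map(seq_len(config$n_trials), function(trial) {
    split <- split_cohort(samples, config, trial)
    train_data <- filter(psi_long, .data$sample %in% split$train)
    covered <- train_data |>
      filter(!is.na(.data$psi)) |>
      distinct(.data$event) |>
      pull("event")
    skipped <- setdiff(events, covered)
    post <- infer_joint(filter(train_data, .data$event %in% covered),
                        iterations = mcmc$iterations, warmup = mcmc$warmup,
                        chains = mcmc$chains,
                        seed = config$seed * 1000L + trial,
                        anchor_slopes = anchor_slopes)
    curves <- trained_curves(post, filter(train_data,
                                          .data$event %in% covered))
    cells <- psi_long |>
      filter(.data$sample %in% split$test, !is.na(.data$psi),
             .data$event %in% covered)
    loggrids <- purrr::pmap(
      list(cells$event, cells$psi),
      function(e, psi) {
        p <- curves[curves$event == e, ]
        mu <- logistic_psi(lg, list(psi_min = p$psi_min, psi_max = p$psi_max,
                                    ec50 = p$ec50, slope = p$slope))
        dnorm(psi, mu, p$sigma, log = TRUE)
      })
    list(trial = trial, cells = cells, loggrids = loggrids,
         skipped = skipped, grid = grid)
  })
}

.power_from_loggrid <- function(grid, loglik, truth) {
  d <- .normalize_density(grid, loglik)
  predictive_power(d, truth)
}

#' Default scaled-down MCMC settings for cross-validation
#'
#' Cross-validation refits the joint model once per trial; these reduced
#' settings (single chain, shorter runs) keep that affordable while leaving
#' enough draws for stable posterior means.
#'
#' @param iterations,warmup,chains MCMC settings per training fit.
#' @return List passed to the `mcmc` argument of [evaluate_single_biomarkers()]
#'   and [greedy_select()].
#' @export
cv_mcmc_control <- function(iterations = 500, warmup = 500, chains = 1) {
  list(iterations = iterations, warmup = warmup, chains = chains)
}

#' Cross-validated predictive power of each splicing event
#'
#' For each of `n_trials` random train/test divisions, the joint model is
#' fitted to the training samples; each held-out sample then gets, per event,
#' a grid posterior over its concentration from that single event, scored by
#' [predictive_power()] against the sample's full-data "true" concentration.
#' Powers are averaged overall and within severity strata (strata assigned
#' from the full-data truth).
#'
#' @param psi_long Long inclusion tibble (`event`, `sample`, `psi`).
#' @param config A [crossval_config()].
#' @param truth Optional named numeric of "true" `[MBNL]` per sample. By
#'   default the posterior mean from a full-data [infer_joint()] run, per the
#'   definition of predictive power.
#' @param grid_size Grid resolution for the posteriors (default 1001).
#' @param mcmc MCMC settings per training fit; see [cv_mcmc_control()].
#' @param full_mcmc MCMC settings for the full-data truth fit (defaults to
#'   `mcmc` with 4 chains).
#' @return List of class `"biomarker_eval"` with
#'   \describe{
#'     \item{power}{tibble `event`, `stratum` (incl. `"overall"`), `mean_power`,
#'       `n_obs`.}
#'     \item{per_cell}{tibble of every (trial, event, test sample) power.}
#'     \item{truth}{the per-sample truth used.}
#'     \item{skipped}{tibble of events skipped per trial for lack of training
#'       data.}
#'   }
#' @export
evaluate_single_biomarkers <- function(psi_long, config = crossval_config(),
                                       truth = NULL, grid_size = 1001,
                                       mcmc = cv_mcmc_control(),
                                       full_mcmc = NULL, anchor_slopes = NULL) {
  psi_long <- as_tibble(psi_long)
  ref <- .resolve_truth(psi_long, truth, config, mcmc, full_mcmc, anchor_slopes)
  truth <- ref$truth
  anchor_slopes <- ref$anchor_slopes
  strata <- setNames(as.character(severity_group(truth)), names(truth))
  runs <- .cv_engine(psi_long, config, truth, grid_size, mcmc, anchor_slopes)

  per_cell <- purrr::map_dfr(runs, function(run) {
    if (nrow(run$cells) == 0) return(tibble())
    pw <- purrr::map2_dbl(run$loggrids, run$cells$sample, function(lgld, sa) {
      .power_from_loggrid(run$grid, lgld, truth[[sa]])
    })
    tibble(trial = run$trial, event = run$cells$event,
           sample = run$cells$sample, power = pw,
           stratum = strata[run$cells$sample])
  })
  power <- bind_rows(
    per_cell |> group_by(.data$event) |>
      summarise(mean_power = mean(.data$power), n_obs = n(), .groups = "drop") |>
      mutate(stratum = "overall"),
    per_cell |> group_by(.data$event, .data$stratum) |>
      summarise(mean_power = mean(.data$power), n_obs = n(), .groups = "drop")
  ) |>
    select("event", "stratum", "mean_power", "n_obs") |>
    arrange(.data$event, .data$stratum)
  skipped <- purrr::map_dfr(runs, function(run) {
    if (length(run$skipped) == 0) return(tibble())
    tibble(trial = run$trial, event = run$skipped)
  })
  structure(list(power = power, per_cell = per_cell, truth = truth,
                 skipped = skipped, config = config),
            class = "biomarker_eval")
}

# full-data reference: the "true" [MBNL] per sample and, unless supplied,
# orientation anchors (posterior slope signs) reused by every training fit so
# all trials share one orientation of the concentration axis
.resolve_truth <- function(psi_long, truth, config, mcmc, full_mcmc,
                           anchor_slopes = NULL) {
  if (!is.null(truth) && !is.null(anchor_slopes)) {
    return(list(truth = truth, anchor_slopes = anchor_slopes))
  }
  full_mcmc <- full_mcmc %||% modifyList(mcmc, list(chains = max(mcmc$chains, 2)))
  full <- infer_joint(psi_long, iterations = full_mcmc$iterations,
                      warmup = full_mcmc$warmup, chains = full_mcmc$chains,
                      seed = config$seed, anchor_slopes = anchor_slopes)
  slopes <- full$event_params |>
    filter(.data$parameter == "slope")
  list(truth = truth %||% setNames(full$mbnl$mean, full$mbnl$sample),
       anchor_slopes = anchor_slopes %||%
         setNames(sign(slopes$mean), slopes$event))
}

#' @export
print.biomarker_eval <- function(x, ...) {
  top <- x$power |> filter(.data$stratum == "overall") |>
    arrange(dplyr::desc(.data$mean_power))
  cat(sprintf("Biomarker cross-validation: %d events, %d trials\n",
              nrow(top), x$config$n_trials))
  print(head(top, 5))
  invisible(x)
}

#' @export
autoplot.biomarker_eval <- function(object, ...) {
  d <- object$power
  ov <- d |> filter(.data$stratum == "overall") |> arrange(.data$mean_power)
  d$event <- factor(d$event, levels = ov$event)
  ggplot2::ggplot(d, ggplot2::aes(.data$event, .data$mean_power,
                                  fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "mean predictive power", x = NULL)
}

#' Greedy construction of a splicing-biomarker panel
#'
#' Exhaustive panel search is combinatorially infeasible, so the panel is
#' grown one event at a time: starting from the single event with the
#' highest mean combined predictive power, each step adds the event that
#' maximizes the panel's mean power, where a panel's posterior for a sample
#' is the product of its events' posteriors ([combine_posteriors()]). Ties
#' break toward higher power, then lexicographically smaller event id.
#'
#' @inheritParams evaluate_single_biomarkers
#' @param k Panel size to grow to (1 <= k <= number of events).
#' @return List of class `"biomarker_panel"` with `panel` (ordered event
#'   ids) and `curve` (tibble `size`, `event_added`, `mean_power`).
#' @export
greedy_select <- function(psi_long, k, config = crossval_config(),
                          truth = NULL, grid_size = 1001,
                          mcmc = cv_mcmc_control(), full_mcmc = NULL,
                          anchor_slopes = NULL) {
  psi_long <- as_tibble(psi_long)
  events <- sort(unique(psi_long$event))
  if (k < 1) abort("k must be >= 1", class = "mbnldose_invalid_argument")
  if (k > length(events)) {
    abort("k exceeds the number of events", class = "mbnldose_invalid_argument")
  }
  ref <- .resolve_truth(psi_long, truth, config, mcmc, full_mcmc, anchor_slopes)
  truth <- ref$truth
  runs <- .cv_engine(psi_long, config, truth, grid_size, mcmc,
                     ref$anchor_slopes)

  # mean combined power of a candidate panel across all (trial, test sample)
  panel_power <- function(panel) {
    vals <- purrr::map(runs, function(run) {
      cells <- run$cells
      idx <- which(cells$event %in% panel)
      if (length(idx) == 0) return(numeric(0))
      by_sample <- split(idx, cells$sample[idx])
      purrr::map_dbl(names(by_sample), function(sa) {
        loglik <- Reduce(`+`, run$loggrids[by_sample[[sa]]])
        .power_from_loggrid(run$grid, loglik, truth[[sa]])
      })
    })
    mean(unlist(vals))
  }

  panel <- character(0)
  curve <- tibble()
  for (step in seq_len(k)) {
    candidates <- sort(setdiff(events, panel))
    scores <- purrr::map_dbl(candidates, function(e) panel_power(c(panel, e)))
    pick <- candidates[order(-scores, candidates)[1]]
    panel <- c(panel, pick)
    curve <- bind_rows(curve, tibble(size = step, event_added = pick,
                                     mean_power = max(scores)))
  }
  structure(list(panel = panel, curve = curve, truth = truth, config = config),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("Greedy biomarker panel:\n")
  print(x$curve)
  invisible(x)
}

#' @export
autoplot.biomarker_panel <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$size, .data$mean_power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "panel size", y = "mean predictive power")
}
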