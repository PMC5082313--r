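test_that("cohort splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("s%02d", 1:10)
  cfg <- crossval_config(train_frac = 0.7, n_trials = 3, seed = 5)
  sp <- split_cohort(ids, cfg, 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_cohort(ids, cfg, 1))
  expect_false(identical(sp, split_cohort(ids, cfg, 2)))
  expect_error(split_cohort("only_one", cfg), class = "mbnldose_invalid_argument")
})

test_that("severity strata reproduce the published boundaries", {
  expect_equal(as.character(severity_group(c(0.20, 0.50, 0.90))),
               c("severe", "moderate", "mild"))
  # boundary convention: lower-inclusive into the opening stratum
  expect_equal(as.character(severity_group(c(0, 0.33, 0.66, 1))),
               c("severe", "moderate", "mild", "mild"))
  expect_equal(as.character(severity_group(0.329999)), "severe")
  expect_equal(as.character(severity_group(0.659999)), "moderate")
  expect_error(severity_group(1.1), class = "mbnldose_invalid_argument")
})

# one small cross-validated cohort shared by the remaining tests: four
# informative events plus one flat (uninformative) event
cv_cohort <- local({
  sampler <- function(n) {
    c(informative_sampler(n - 1), list(sigmoid_params(0.5, 0.5, 0.3, 1)))
  }
  simulate_cohort(5, 16, param_sampler = sampler, sigma = 0.04, seed = 3)
})
cv_config <- crossval_config(n_trials = 3, seed = 3)
cv_eval <- evaluate_single_biomarkers(cv_cohort$psi, cv_config,
                                      grid_size = 501, mcmc = fast_mcmc(),
                                      anchor_slopes = true_anchors(cv_cohort))

test_that("a flat event scores at the uniform baseline, below informative ones", {
  overall <- dplyr::filter(cv_eval$power, stratum == "overall")
  flat <- dplyr::filter(overall, event == "event_05")
  informative <- dplyr::filter(overall, event != "event_05")
  expect_equal(flat$mean_power, 1, tolerance = 0.15)
  expect_true(all(informative$mean_power > flat$mean_power))
  expect_true(all(cv_eval$per_cell$power >= 0))
})

test_that("stratum means recombine to the overall mean", {
  by_stratum <- dplyr::filter(cv_eval$power, stratum != "overall")
  overall <- dplyr::filter(cv_eval$power, stratum == "overall")
  recombined <- by_stratum |>
    dplyr::group_by(event) |>
    dplyr::summarise(
      mean_power = sum(mean_power * n_obs) / sum(n_obs),
      n = sum(n_obs), .groups = "drop")
  merged <- dplyr::left_join(overall, recombined, by = "event")
  expect_equal(merged$mean_power.x, merged$mean_power.y, tolerance = 1e-12)
  expect_equal(merged$n_obs, merged$n)
})

test_that("cross-validation is reproducible under a fixed seed", {
  again <- evaluate_single_biomarkers(cv_cohort$psi, cv_config,
                                      grid_size = 501, mcmc = fast_mcmc(),
                                      anchor_slopes = true_anchors(cv_cohort))
  expect_identical(cv_eval$power, again$power)
})

test_that("greedy panel growth starts from the best single biomarker", {
  panel <- greedy_select(cv_cohort$psi, 2, cv_config, truth = cv_eval$truth,
                         grid_size = 501, mcmc = fast_mcmc(),
                         anchor_slopes = true_anchors(cv_cohort))
  overall <- dplyr::filter(cv_eval$power, stratum == "overall")
  best_single <- overall$event[which.max(overall$mean_power)]
  expect_equal(panel$panel[1], best_single)
  expect_equal(panel$curve$mean_power[1], max(overall$mean_power),
               tolerance = 1e-9)
  expect_length(unique(panel$panel), 2)
  expect_error(greedy_select(cv_cohort$psi, 0, cv_config),
               class = "mbnldose_invalid_argument")
  expect_error(greedy_select(cv_cohort$psi, 9, cv_config),
               class = "mbnldose_invalid_argument")
})

test_that("greedy pair matches the exhaustive best pair on a small cohort", {
  cohort <- simulate_cohort(4, 14, param_sampler = informative_sampler,
                            sigma = 0.04, seed = 19)
  cfg <- crossval_config(n_trials = 2, seed = 19)
  anchors <- true_anchors(cohort)
  truth <- cohort$truth$mbnl_true
  panel <- greedy_select(cohort$psi, 2, cfg, truth = truth, grid_size = 501,
                         mcmc = fast_mcmc(), anchor_slopes = anchors)
  # exhaustive oracle over all pairs, reusing the same engine internals
  runs <- mbnldose:::.cv_engine(cohort$psi, cfg, truth, 501, fast_mcmc(),
                                anchors)
  pair_power <- function(pair) {
    mean(unlist(lapply(runs, function(run) {
      idx <- which(run$cells$event %in% pair)
      if (length(idx) == 0) return(numeric(0))
      vapply(split(idx, run$cells$sample[idx]), function(ii) {
        mbnldose:::.power_from_loggrid(run$grid,
                                       Reduce(`+`, run$loggrids[ii]),
                                       truth[[run$cells$sample[ii[1]]]])
      }, numeric(1))
    })))
  }
  events <- sort(unique(cohort$psi$event))
  pairs <- combn(events, 2, simplify = FALSE)
  scores <- vapply(pairs, pair_power, numeric(1))
  best_pair <- sort(pairs[[which.max(scores)]])
  expect_equal(sort(panel$panel), best_pair)
  expect_equal(max(scores), panel$curve$mean_power[2], tolerance = 1e-9)
})

test_that("an event is the better biomarker in the stratum where it switches", {
  # one event switching near the top of the concentration range, one near
  # the bottom: within each severity stratum, the event whose transition
  # falls in that range should outrank the other
  sampler <- function(n) list(
    sigmoid_params(0.1, 0.9, ec50 = 0.80, slope = 4),
    sigmoid_params(0.1, 0.9, ec50 = 0.12, slope = 4)
  )[seq_len(n)]
  mb_sampler <- function(n) seq(0.02, 0.98, length.out = n)
  cohort <- simulate_cohort(2, 24, param_sampler = sampler, sigma = 0.05,
                            seed = 1, mbnl_sampler = mb_sampler)
  ev <- evaluate_single_biomarkers(
    cohort$psi, crossval_config(n_trials = 6, seed = 1), grid_size = 501,
    mcmc = fast_mcmc(), truth = cohort$truth$mbnl_true,
    anchor_slopes = true_anchors(cohort))
  power_of <- function(event, stratum) {
    dplyr::filter(ev$power, event == !!event,
                  stratum == !!stratum)$mean_power
  }
  expect_gt(power_of("event_01", "mild"), power_of("event_02", "mild"))
  expect_gt(power_of("event_02", "severe"), power_of("event_01", "severe"))
})
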