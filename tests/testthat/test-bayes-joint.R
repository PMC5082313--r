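# Joint inference runs here use reduced MCMC (hundreds of iterations, 2
# chains) so the whole file stays fast; the full acceptance-scale run lives
# in test-acceptance.R.

test_that("with no data the posterior reproduces the priors", {
  psi <- tidyr::expand_grid(event = c("e1", "e2"),
                            sample = c("s1", "s2", "s3"))
  psi$psi <- NA_real_
  post <- infer_joint(psi, iterations = 1000, warmup = 0, chains = 2, seed = 4)
  expect_equal(mean(post$mbnl$mean), 0.5, tolerance = 0.05)
  lec <- dplyr::filter(post$event_params, parameter == "log_ec50")
  expect_equal(mean(lec$mean), 0.5, tolerance = 0.15)
  slp <- dplyr::filter(post$event_params, parameter == "slope")
  expect_equal(mean(slp$mean), 0, tolerance = 0.15)
  # marginal of [MBNL] indistinguishable from Uniform(0,1)
  ks <- suppressWarnings(
    stats::ks.test(post$draws[, "mbnl[1]"], "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("latent concentrations are recovered on an informative cohort", {
  cohort <- simulate_cohort(6, 20, param_sampler = informative_sampler,
                            sigma = 0.03, seed = 31)
  post <- infer_joint(cohort$psi, iterations = 600, warmup = 600, chains = 2,
                      seed = 8, anchor_slopes = true_anchors(cohort))
  truth <- cohort$truth$mbnl_true[post$mbnl$sample]
  expect_gt(cor(post$mbnl$mean, truth, method = "spearman"), 0.9)
  expect_gt(cor(post$mbnl$mean, truth)^2, 0.85)
  expect_true(all(post$mbnl$mean >= 0 & post$mbnl$mean <= 1))
  expect_true(all(post$mbnl$q05 <= post$mbnl$mean &
                    post$mbnl$mean <= post$mbnl$q95))
})

test_that("identical seeds reproduce summaries exactly", {
  cohort <- simulate_cohort(4, 10, param_sampler = informative_sampler,
                            sigma = 0.04, seed = 17)
  a <- infer_joint(cohort$psi, iterations = 200, warmup = 200, chains = 2,
                   seed = 12)
  b <- infer_joint(cohort$psi, iterations = 200, warmup = 200, chains = 2,
                   seed = 12)
  expect_identical(a$mbnl, b$mbnl)
  expect_identical(a$event_params, b$event_params)
})

test_that("duplicated samples get matching posteriors", {
  cohort <- simulate_cohort(5, 8, param_sampler = informative_sampler,
                            sigma = 0.03, seed = 23)
  dup <- cohort$psi
  extra <- dplyr::filter(dup, sample == "sample_01") |>
    dplyr::mutate(sample = "sample_01b")
  post <- infer_joint(dplyr::bind_rows(dup, extra), iterations = 600,
                      warmup = 600, chains = 2, seed = 3)
  m <- setNames(post$mbnl$mean, post$mbnl$sample)
  expect_equal(unname(m["sample_01b"]), unname(m["sample_01"]),
               tolerance = 0.05)
})

test_that("posterior summaries match an independent quantile computation", {
  set.seed(9)
  draws <- cbind(a = rnorm(500), b = runif(500))
  s <- posterior_summaries(draws)
  manual_q <- function(x, p) {
    # piecewise-linear interpolation of the order statistics, written out
    xs <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[pmin(lo + 1, length(x))] - xs[lo])
  }
  for (nm in c("a", "b")) {
    row <- s[s$parameter == nm, ]
    expect_equal(row$mean, mean(draws[, nm]))
    expect_equal(row$q05, manual_q(draws[, nm], 0.05))
    expect_equal(row$q95, manual_q(draws[, nm], 0.95))
  }
  expect_equal(posterior_summaries(matrix(2, 100, 1))$mean, 2)
  expect_equal(posterior_summaries(matrix(2, 100, 1))$q05, 2)
  grid <- matrix(seq_len(1000) / 1000, ncol = 1)
  expect_equal(posterior_summaries(grid)$q05, 0.05, tolerance = 0.05)
  expect_equal(posterior_summaries(grid)$q95, 0.95, tolerance = 0.005)
  expect_error(posterior_summaries(matrix(1, 50, 2)),
               class = "mbnldose_insufficient_draws")
})

test_that("invalid priors and malformed matrices are rejected", {
  expect_error(prior_spec(log_ec50_sd = 0), class = "mbnldose_invalid_argument")
  expect_error(infer_joint(tibble::tibble(event = "e", sample = "s", psi = 1.4)),
               class = "mbnldose_invalid_argument")
  psi <- tidyr::expand_grid(event = c("e1", "e2"), sample = c("s1", "s2", "s3"))
  psi$psi <- runif(6)
  expect_error(infer_joint(psi, priors = list(a = 1)),
               class = "mbnldose_invalid_argument")
})

test_that("trained curves carry a positive data-derived noise scale", {
  cohort <- simulate_cohort(4, 12, param_sampler = informative_sampler,
                            sigma = 0.05, seed = 41)
  post <- infer_joint(cohort$psi, iterations = 400, warmup = 400, chains = 2,
                      seed = 2)
  curves <- trained_curves(post, cohort$psi)
  expect_equal(nrow(curves), 4)
  expect_true(all(curves$sigma >= 0.01))
  expect_true(all(curves$ec50 > 0))
  # residual-based sigma should be near the generating noise
  expect_lt(median(curves$sigma), 0.2)
})
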