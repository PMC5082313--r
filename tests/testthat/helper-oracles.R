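# Independent oracles and small fixture builders used across the suite.

# Brute-force grid search minimizer of the 4PL least-squares objective over
# the (psi_min, psi_max, log10 ec50, slope) box. Independent of the package's
# optimizer: plain nested grids, no derivatives.
grid_search_fit <- function(log_conc, psi, n = 21) {
  grid <- expand.grid(
    lo = seq(0, 1, length.out = n),
    hi = seq(0, 1, length.out = n),
    lec = seq(min(log_conc) - 1, max(log_conc) + 1, length.out = n),
    slope = seq(-8, 8, length.out = n)
  )
  sse <- apply(grid, 1, function(g) {
    mu <- g[1] + (g[2] - g[1]) / (1 + 10^((g[3] - log_conc) * g[4]))
    sum((psi - mu)^2)
  })
  i <- which.min(sse)
  list(par = as.numeric(grid[i, ]), sse = sse[i],
       cell = c(1 / (n - 1), 1 / (n - 1),
                diff(range(log_conc)) / (n - 1), 16 / (n - 1)))
}

# Regex-based YGCY scanner (overlapping matches via lookahead), the oracle
# for the Biostrings-backed implementation.
regex_scan_ygcy <- function(s) {
  s <- toupper(chartr("uU", "tT", s))
  m <- gregexpr("(?=[CT]GC[CT])", s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Loop-based reimplementation of the mis-splicing filter, one criterion at a
# time, used as the oracle for filter_events().
brute_filter <- function(cells, bf, min_cov = 0.7, min_reads = 20,
                         min_dpsi = 0.2, bf_thr = 5, min_case_frac = 0.25) {
  out <- list()
  for (e in sort(unique(cells$event))) {
    ec <- cells[cells$event == e, ]
    covered <- !is.na(ec$reads) & ec$reads >= min_reads & !is.na(ec$psi)
    ctrl <- ec$group == "control"
    pass_cov <- sum(covered & ctrl) / sum(ctrl) >= min_cov &&
      sum(covered & !ctrl) / sum(!ctrl) >= min_cov &&
      sum(covered & ctrl) > 0 && sum(covered & !ctrl) > 0
    mc <- mean(ec$psi[covered & !ctrl])
    mk <- mean(ec$psi[covered & ctrl])
    pass_dpsi <- is.finite(mc - mk) && abs(mc - mk) >= min_dpsi
    eb <- bf[bf$event == e, ]
    frac_bf <- if (nrow(eb) == 0) 0 else {
      med <- tapply(eb$bf, eb$case_sample, median)
      mean(med >= bf_thr)
    }
    pass_bf <- frac_bf >= min_case_frac
    out[[e]] <- data.frame(event = e, pass_coverage = pass_cov,
                           pass_dpsi = pass_dpsi, pass_bf = pass_bf,
                           pass = pass_cov && pass_dpsi && pass_bf)
  }
  do.call(rbind, out)
}

# Random toy case/control event tables for filter property tests.
random_event_tables <- function(n_events, n_control = 6, n_case = 8) {
  cells <- expand.grid(
    event = sprintf("ev%04d", seq_len(n_events)),
    sample = c(sprintf("ctrl%02d", seq_len(n_control)),
               sprintf("case%02d", seq_len(n_case))),
    stringsAsFactors = FALSE
  )
  cells$group <- ifelse(grepl("^ctrl", cells$sample), "control", "case")
  cells$reads <- rpois(nrow(cells), 25)
  cells$psi <- round(runif(nrow(cells)), 3)
  cells$psi[runif(nrow(cells)) < 0.1] <- NA
  bf <- expand.grid(
    event = sprintf("ev%04d", seq_len(n_events)),
    case_sample = sprintf("case%02d", seq_len(n_case)),
    control_sample = sprintf("ctrl%02d", seq_len(n_control)),
    stringsAsFactors = FALSE
  )
  bf$bf <- rexp(nrow(bf), 1 / 4)
  list(cells = cells, bf = bf)
}

# Event curves with well-separated plateaus and moderate slopes: the regime
# of experimentally validated MBNL-responsive exons, used where tests need
# informative events.
informative_sampler <- function(n) {
  purrr::map(seq_len(n), function(i) {
    lo <- runif(1, 0, 0.35)
    sigmoid_params(lo, runif(1, 0.6, 1), 10^runif(1, -1, 0),
                   sample(c(-1, 1), 1) * runif(1, 1, 4))
  })
}

true_anchors <- function(cohort) {
  sign(vapply(cohort$truth$event_params, `[[`, numeric(1), "slope"))
}

fast_mcmc <- function() cv_mcmc_control(iterations = 400, warmup = 400,
                                        chains = 2)
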