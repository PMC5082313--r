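test_that("zero-noise cohorts reproduce the curve values exactly", {
  cohort <- simulate_cohort(4, 10, sigma = 0, missing_frac = 0, seed = 3)
  wide <- tidyr::pivot_wider(cohort$psi, names_from = "sample",
                             values_from = "psi")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$event
  expect_equal(mat[rownames(cohort$truth$psi_noiseless),
                   colnames(cohort$truth$psi_noiseless)],
               cohort$truth$psi_noiseless)
})

test_that("the same seed regenerates the cohort bit-for-bit", {
  a <- simulate_cohort(8, 30, sigma = 0.05, missing_frac = 0.1, seed = 7)
  b <- simulate_cohort(8, 30, sigma = 0.05, missing_frac = 0.1, seed = 7)
  expect_identical(a$psi, b$psi)
  expect_identical(a$truth$mbnl_true, b$truth$mbnl_true)
  c <- simulate_cohort(8, 30, sigma = 0.05, missing_frac = 0.1, seed = 8)
  expect_false(identical(a$psi$psi, c$psi$psi))
})

test_that("empirical residual noise matches the generating sigma", {
  cohort <- simulate_cohort(40, 50, sigma = 0.03, seed = 5)
  resid <- cohort$truth$psi_preclip - cohort$truth$psi_noiseless
  expect_gt(length(resid), 1000)
  expect_equal(sd(resid), 0.03, tolerance = 0.2)
})

test_that("generated values respect bounds, masks and sampler support", {
  cohort <- simulate_cohort(30, 20, sigma = 0.1, missing_frac = 0.25, seed = 9)
  present <- cohort$psi$psi[!is.na(cohort$psi$psi)]
  expect_true(all(present >= 0 & present <= 1))
  expect_equal(sum(is.na(cohort$psi$psi)),
               round(0.25 * 30 * 20))
  for (p in cohort$truth$event_params) {
    expect_true(p$ec50 >= 0.01 && p$ec50 <= 10)
    expect_true(abs(p$slope) >= 0.5 && abs(p$slope) <= 6)
    expect_true(p$psi_min <= p$psi_max)
  }
  expect_true(all(cohort$truth$mbnl_true >= 0 & cohort$truth$mbnl_true <= 1))
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_cohort(0, 5), class = "mbnldose_invalid_argument")
  expect_error(simulate_cohort(2, 5, sigma = -1),
               class = "mbnldose_invalid_argument")
  expect_error(simulate_cohort(2, 5, missing_frac = 1),
               class = "mbnldose_invalid_argument")
  expect_error(simulate_dose_series(c(-1, 10), sigmoid_params(0, 1, 100, 2),
                                    list(sigmoid_params(0.2, 0.8, 0.3, -2))),
               class = "mbnldose_invalid_argument")
})

test_that("noiseless dose series are monotone and hit the midpoint at EC50", {
  induction <- sigmoid_params(0.05, 1, ec50 = 100, slope = 1.5)
  wt <- sigmoid_params(0.41, 0.98, ec50 = 0.19, slope = -1.8)
  doses <- 10^seq(0, 4, length.out = 15)
  ser <- simulate_dose_series(doses, induction, list(wt = wt), sigma = 0)
  expect_true(all(diff(ser$mbnl_rel) >= 0))
  expect_true(all(diff(ser$psi) <= 0))  # repressed event: psi falls with dose
  # dose at which induced concentration equals the event's EC50
  d_mid <- invert_logistic(0.19, induction)
  mid <- simulate_dose_series(d_mid, induction, list(wt = wt), sigma = 0)
  expect_equal(nrow(mid), 1)
  expect_equal(mid$psi, (0.41 + 0.98) / 2, tolerance = 1e-9)
})

test_that("planted motifs are recovered exactly on motif-free background", {
  regions <- simulate_exon_regions(6, flank_len = 200, planted_motif_rate = 15,
                                   seed = 11, background = "motif_free")
  expect_equal(nrow(regions), 12)
  for (i in seq_len(nrow(regions))) {
    expect_identical(scan_ygcy(regions$seq[i]),
                     as.integer(regions$planted[[i]]))
  }
  none <- simulate_exon_regions(4, flank_len = 150, planted_motif_rate = 0,
                                seed = 2, background = "motif_free")
  expect_true(all(lengths(lapply(none$seq, scan_ygcy)) == 0))
})

test_that("planted motif counts track the requested rate", {
  rate <- 8  # per kb
  regions <- simulate_exon_regions(100, flank_len = 400,
                                   planted_motif_rate = rate, seed = 13,
                                   background = "motif_free")
  planted_per_kb <- sum(lengths(regions$planted)) /
    (nrow(regions) * 400 / 1000)
  expect_equal(planted_per_kb, rate, tolerance = 0.15)
})

test_that("tabular and FASTA round trips preserve values", {
  cohort <- simulate_cohort(5, 8, sigma = 0.04, missing_frac = 0.15, seed = 21)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psi_table(cohort$psi, f)
  back <- read_psi_table(f)
  key <- function(d) dplyr::arrange(d, event, sample)
  expect_equal(key(back), key(cohort$psi), tolerance = 1e-9)

  regions <- simulate_exon_regions(4, flank_len = 120, planted_motif_rate = 10,
                                   seed = 3)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_flanks_fasta(regions, fa)
  back_fa <- read_flanks_fasta(fa)
  expect_equal(back_fa$seq, regions$seq)
  expect_equal(back_fa$planted, lapply(regions$planted, as.integer))
})
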