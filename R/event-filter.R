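#' Filtering thresholds for calling mis-spliced exons
#'
#' Defaults reproduce the published high-confidence criteria for cassette
#' exons mis-spliced in DM1 muscle: at least 70% of control samples and 70%
#' of case samples covered (>= 20 inclusion+exclusion reads over the event),
#' an absolute group-mean inclusion difference of at least 0.20, and at
#' least 25% of case samples showing per-patient evidence of differential
#' splicing (median Bayes factor across that patient's control comparisons
#' >= 5).
#'
#' @param min_coverage_frac Minimum covered fraction per group (default 0.70).
#' @param min_reads Minimum reads for a cell to count as covered (default 20).
#' @param min_abs_mean_dpsi Minimum `|mean case psi - mean control psi|`
#'   (default 0.20).
#' @param bf_threshold Bayes-factor threshold per patient median (default 5).
#' @param min_case_frac_dysregulated Minimum fraction of case samples passing
#'   the Bayes-factor test (default 0.25).
#' @return List with class `"filter_criteria"`.
#' @export
filter_criteria <- function(min_coverage_frac = 0.70, min_reads = 20,
                            min_abs_mean_dpsi = 0.20, bf_threshold = 5,
                            min_case_frac_dysregulated = 0.25) {
  vals <- c(min_coverage_frac, min_reads, min_abs_mean_dpsi, bf_threshold,
            min_case_frac_dysregulated)
  if (any(!is.finite(vals) | vals < 0) || min_coverage_frac > 1 ||
      min_case_frac_dysregulated > 1) {
    abort("thresholds must be nonnegative (fractions at most 1)",
          class = "mbnldose_invalid_argument")
  }
  structure(list(min_coverage_frac = min_coverage_frac, min_reads = min_reads,
                 min_abs_mean_dpsi = min_abs_mean_dpsi,
                 bf_threshold = bf_threshold,
                 min_case_frac_dysregulated = min_case_frac_dysregulated),
            class = "filter_criteria")
}

#' Call mis-spliced cassette exons in a case/control cohort
#'
#' Applies the three-part filter to per-cell inclusion and read-support data
#' plus per-comparison Bayes factors. A cell is "covered" when its total
#' (inclusion + exclusion) reads meet `min_reads`; group means use covered
#' cells only. An event with zero covered samples in either group fails the
#' coverage criterion outright.
#'
#' @param cells Data frame with one row per (event, sample): columns
#'   `event`, `sample`, `group` (`"control"` or `"case"`), `psi`, `reads`.
#' @param bayes_factors Data frame with one row per (event, case sample,
#'   control sample) comparison: columns `event`, `case_sample`, `bf`.
#' @param criteria A [filter_criteria()].
#' @return Tibble of class `"event_filter_audit"`, one row per event:
#'   coverage fractions, mean inclusion per group, `delta_psi`, fraction of
#'   cases with qualifying median Bayes factor, per-criterion logicals
#'   (`pass_coverage`, `pass_dpsi`, `pass_bf`) and overall `pass`.
#' @export
filter_events <- function(cells, bayes_factors,
                          criteria = filter_criteria()) {
  cells <- as_tibble(cells)
  stopifnot(all(c("event", "sample", "group", "psi", "reads") %in% names(cells)),
            all(cells$group %in% c("control", "case")))
  cov <- cells |>
    mutate(covered = !is.na(.data$reads) & .data$reads >= criteria$min_reads &
             !is.na(.data$psi)) |>
    group_by(.data$event, .data$group) |>
    summarise(
      n = n(),
      n_covered = sum(.data$covered),
      mean_psi = if (any(.data$covered))
        mean(.data$psi[.data$covered]) else NA_real_,
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "n_covered", "mean_psi"))

  bf <- as_tibble(bayes_factors) |>
    group_by(.data$event, .data$case_sample) |>
    summarise(median_bf = median(.data$bf), .groups = "drop") |>
    group_by(.data$event) |>
    summarise(
      frac_cases_bf = mean(.data$median_bf >= criteria$bf_threshold),
      .groups = "drop")

  audit <- cov |>
    left_join(bf, by = "event") |>
    mutate(
      frac_cases_bf = dplyr::coalesce(.data$frac_cases_bf, 0),
      coverage_control = .data$n_covered_control / .data$n_control,
      coverage_case = .data$n_covered_case / .data$n_case,
      delta_psi = .data$mean_psi_case - .data$mean_psi_control,
      pass_coverage = dplyr::coalesce(
        .data$coverage_control >= criteria$min_coverage_frac &
          .data$coverage_case >= criteria$min_coverage_frac &
          .data$n_covered_control > 0 & .data$n_covered_case > 0, FALSE),
      pass_dpsi = !is.na(.data$delta_psi) &
        abs(.data$delta_psi) >= criteria$min_abs_mean_dpsi,
      pass_bf = .data$frac_cases_bf >= criteria$min_case_frac_dysregulated,
      pass = .data$pass_coverage & .data$pass_dpsi & .data$pass_bf
    ) |>
    select("event", "coverage_control", "coverage_case",
           "mean_psi_control", "mean_psi_case", "delta_psi",
           "frac_cases_bf", "pass_coverage", "pass_dpsi", "pass_bf", "pass") |>
    arrange(.data$event)
  class(audit) <- c("event_filter_audit", class(audit))
  audit
}

#' Fraction of case samples with dysregulated splicing for one event
#'
#' Per covered case sample, the inclusion shift is
#' `|psi - reference_mean|`; a sample counts as dysregulated when its shift
#' exceeds half the maximum shift seen for the event (a per-event normalized
#' threshold, so events with different dynamic ranges are comparable).
#'
#' @param psi_case Numeric vector of case-sample inclusion (NA = not covered).
#' @param reference_mean Control-group mean inclusion for the event.
#' @return Fraction in `[0, 1]` of covered case samples.
#' @examples
#' dysregulation_fraction(c(0.8, 0.7, 0.5, 0.5), reference_mean = 0.4)
#' @export
dysregulation_fraction <- function(psi_case, reference_mean) {
  d <- abs(psi_case - reference_mean)
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    abort("no covered case samples", class = "mbnldose_undefined_statistic")
  }
  mean(d > 0.5 * max(d))
}
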