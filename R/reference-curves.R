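#' Reference dose-response parameters for MBNL1 exon 5 minigene constructs
#'
#' Published fitted four-parameter logistic constants for the human MBNL1
#' exon 5 minigene and a series of deletion/point mutants of its downstream
#' intronic splicing silencer (ISS), measured in a dox-inducible HEK293
#' MBNL1 titration system. Concentrations are relative MBNL1 units; slopes
#' are negative because MBNL1 promotes skipping of its own exon 5.
#'
#' These constants are useful as realistic generating curves for synthetic
#' dose series and for round-trip fitting checks: inclusion levels generated
#' noiselessly from a row and refit with [fit_dose_response()] recover the
#' row's EC50 and slope.
#'
#' @return A tibble with columns `construct`, `ec50`, `slope`, `r_squared`,
#'   `psi_min`, `psi_max`.
#' @examples
#' mbnl1_minigene_curves()
#' @export
mbnl1_minigene_curves <- function() {
  # plateaus reported above 1 are clamped to the model's [0,1] support
  tibble::tribble(
    ~construct, ~ec50, ~slope, ~r_squared, ~psi_min, ~psi_max,
    "WT",   0.19, -1.80, 0.9244, 0.41, 0.98,
    "del1", 0.48, -0.60, 0.9167, 0.38, 1.00,
    "del2", 1.20, -0.33, 0.8163, 0.26, 1.00,
    "del3", 1.60, -0.56, 0.8500, 0.54, 1.00,
    "del4", 0.15, -2.00, 0.8075, 0.39, 0.96,
    "del5", 0.29, -0.67, 0.7983, 0.49, 0.95,
    "3M",   1.70, -0.45, 0.9126, 0.32, 1.00
  )
}
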