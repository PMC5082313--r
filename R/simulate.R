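#' Default sampler of per-event sigmoid parameters
#'
#' Draws generating curves spanning the range seen for MBNL-responsive exons:
#' plateaus uniform on `[0,1]` then ordered, log10 EC50 normal with mean -0.5
#' and SD 0.5 truncated so EC50 lies in `[0.01, 10]`, and absolute slope
#' uniform on `[0.5, 6]` with random sign (steep repressed events through
#' shallow activated ones).
#'
#' @param n_events Number of curves to draw.
#' @return A list of [sigmoid_params()] objects (without sigma).
#' @export
default_param_sampler <- function(n_events) {
  purrr::map(seq_len(n_events), function(i) {
    plateaus <- sort(runif(2))
    lec <- rnorm(1, -0.5, 0.5)
    while (lec < log10(0.01) || lec > log10(10)) lec <- rnorm(1, -0.5, 0.5)
    sigmoid_params(
      psi_min = plateaus[1], psi_max = plateaus[2],
      ec50 = 10^lec,
      slope = sample(c(-1, 1), 1) * runif(1, 0.5, 6)
    )
  })
}

#' Simulate a patient cohort's inclusion matrix
#'
#' Generates the data structure the joint Bayesian model assumes: each sample
#' carries a latent functional MBNL concentration on `[0,1]`; each event has a
#' four-parameter logistic curve; observed inclusion is the curve value at the
#' sample's log10 concentration plus Normal noise, clipped to `[0,1]`; a
#' fraction of cells is missing uniformly at random (mimicking events without
#' sufficient read coverage in a sample).
#'
#' @param n_events,n_samples Cohort dimensions (both >= 1).
#' @param param_sampler Function `n -> list of sigmoid_params`; defaults to
#'   [default_param_sampler()].
#' @param sigma Observation noise SD on the psi scale (>= 0).
#' @param missing_frac Fraction of cells masked, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param mbnl_sampler Function `n -> numeric in [0,1]` drawing the latent
#'   concentrations; defaults to `Uniform(0, 1)`.
#' @return A list with class `"mbnl_cohort"`:
#'   \describe{
#'     \item{psi}{long tibble `(event, sample, psi)` with `NA` psi for masked
#'       cells; attribute-free, ready for [infer_joint()].}
#'     \item{truth}{list with `mbnl_true` (named per sample), `event_params`
#'       (list of generating curves), `psi_noiseless` and `psi_preclip`
#'       matrices, `missing_mask`, `sigma`, `seed`.}
#'   }
#' @examples
#' cohort <- simulate_cohort(n_events = 4, n_samples = 6, sigma = 0.02, seed = 1)
#' head(cohort$psi)
#' @export
simulate_cohort <- function(n_events, n_samples,
                            param_sampler = default_param_sampler,
                            sigma = 0.03, missing_frac = 0, seed = 1L,
                            mbnl_sampler = function(n) runif(n)) {
  if (n_events < 1 || n_samples < 1) {
    abort("need at least one event and one sample",
          class = "mbnldose_invalid_argument")
  }
  if (!is.finite(sigma) || sigma < 0) {
    abort("sigma must be finite and >= 0", class = "mbnldose_invalid_argument")
  }
  if (!is.finite(missing_frac) || missing_frac < 0 || missing_frac >= 1) {
    abort("missing_frac must lie in [0, 1)", class = "mbnldose_invalid_argument")
  }
  set.seed(seed)
  event_ids <- sprintf("event_%02d", seq_len(n_events))
  sample_ids <- sprintf("sample_%02d", seq_len(n_samples))
  mbnl_true <- setNames(mbnl_sampler(n_samples), sample_ids)
  params <- param_sampler(n_events)
  names(params) <- event_ids

  noiseless <- t(vapply(params, function(p) logistic_psi(log10(mbnl_true), p),
                        numeric(n_samples)))
  dimnames(noiseless) <- list(event_ids, sample_ids)
  preclip <- noiseless + matrix(rnorm(n_events * n_samples, 0, sigma),
                                n_events, n_samples)
  psi <- pmin(1, pmax(0, preclip))

  mask <- matrix(FALSE, n_events, n_samples, dimnames = dimnames(noiseless))
  if (missing_frac > 0) {
    n_mask <- round(missing_frac * n_events * n_samples)
    mask[sample(length(mask), n_mask)] <- TRUE
  }
  psi_obs <- psi
  psi_obs[mask] <- NA_real_

  psi_long <- tibble(
    event = rep(event_ids, times = n_samples),
    sample = rep(sample_ids, each = n_events),
    psi = as.vector(psi_obs)
  )
  structure(
    list(
      psi = psi_long,
      truth = list(mbnl_true = mbnl_true, event_params = params,
                   psi_noiseless = noiseless, psi_preclip = preclip,
                   missing_mask = mask, sigma = sigma, seed = seed)
    ),
    class = "mbnl_cohort"
  )
}

#' @export
print.mbnl_cohort <- function(x, ...) {
  n_e <- length(x$truth$event_params)
  n_s <- length(x$truth$mbnl_true)
  cat(sprintf(
    "Synthetic splicing cohort: %d events x %d samples, sigma=%.3g, %d masked cells (seed %d)\n",
    n_e, n_s, x$truth$sigma, sum(x$truth$missing_mask), x$truth$seed))
  invisible(x)
}

#' Simulate a dox-titration dose series
#'
#' Emulates an inducible-expression titration: doxycycline dose induces the
#' splicing factor along a sigmoid induction curve (relative MBNL vs log10
#' dose), and each event's inclusion responds to the induced concentration
#' through its own four-parameter logistic. Zero dose is treated as the
#' uninduced baseline (the induction curve's lower plateau).
#'
#' @param dox_grid Numeric vector of doses (ng/ml), all >= 0.
#' @param induction_params [sigmoid_params()] mapping log10 dose to relative
#'   MBNL. Plateaus here are relative-concentration units (still within
#'   `[0,1]` after normalization to the maximal induction).
#' @param event_params List of [sigmoid_params()], one per event.
#' @param sigma Observation noise SD on the psi scale.
#' @param seed Integer seed.
#' @return Tibble with columns `dose`, `mbnl_rel`, `event`, `psi`.
#' @export
simulate_dose_series <- function(dox_grid, induction_params, event_params,
                                 sigma = 0, seed = 1L) {
  if (any(!is.finite(dox_grid)) || any(dox_grid < 0)) {
    abort("doses must be finite and >= 0", class = "mbnldose_invalid_argument")
  }
  if (!is.finite(sigma) || sigma < 0) {
    abort("sigma must be finite and >= 0", class = "mbnldose_invalid_argument")
  }
  set.seed(seed)
  if (is.null(names(event_params))) {
    names(event_params) <- sprintf("event_%02d", seq_along(event_params))
  }
  mbnl_rel <- logistic_psi(log10(dox_grid), induction_params)
  grid <- tidyr::expand_grid(
    tibble(dose = dox_grid, mbnl_rel = mbnl_rel),
    event = names(event_params)
  )
  mu <- purrr::map2_dbl(grid$mbnl_rel, grid$event, function(m, e) {
    logistic_psi(log10(m), event_params[[e]])
  })
  grid$psi <- pmin(1, pmax(0, mu + rnorm(nrow(grid), 0, sigma)))
  grid
}

.YGCY_VARIANTS <- c("TGCT", "TGCC", "CGCT", "CGCC")

#' Simulate exon-flanking sequences with planted YGCY motifs
#'
#' Builds FASTA-ready flank sequences for motif-enrichment testing. The
#' background can be fully random ACGT or "motif_free" (drawn from A/C/T only,
#' so the YGCY class — which requires a G — cannot arise by chance). Motifs
#' are planted at non-overlapping positions at the requested rate, and the
#' planted offsets are recorded so scans can be checked against a known
#' truth.
#'
#' @param n_events Number of events (each gets an upstream and a downstream
#'   flank).
#' @param flank_len Flank length in nt (>= 20; default 400).
#' @param planted_motif_rate Expected planted motifs per kilobase.
#' @param seed Integer seed.
#' @param background `"random"` (uniform ACGT) or `"motif_free"`.
#' @return Tibble with columns `event`, `region` (`upstream`/`downstream`),
#'   `seq`, and `planted` (list column of 0-based planted start offsets).
#' @export
simulate_exon_regions <- function(n_events, flank_len = 400,
                                  planted_motif_rate = 2, seed = 1L,
                                  background = c("random", "motif_free")) {
  background <- match.arg(background)
  if (flank_len < 20) {
    abort("flank_len must be >= 20", class = "mbnldose_invalid_argument")
  }
  if (planted_motif_rate < 0) {
    abort("planted_motif_rate must be >= 0", class = "mbnldose_invalid_argument")
  }
  set.seed(seed)
  alphabet <- if (background == "motif_free") c("A", "C", "T") else c("A", "C", "G", "T")
  one_flank <- function() {
    s <- sample(alphabet, flank_len, replace = TRUE)
    n_plant <- rpois(1, planted_motif_rate * flank_len / 1000)
    planted <- integer(0)
    if (n_plant > 0) {
      # greedy non-overlapping placement on a coarse lattice of 4-nt slots
      slots <- sample(seq(1, flank_len - 3, by = 4))
      for (pos in head(slots, n_plant)) {
        s[pos:(pos + 3)] <- strsplit(sample(.YGCY_VARIANTS, 1), "")[[1]]
        planted <- c(planted, pos - 1L)  # report 0-based
      }
    }
    list(seq = paste(s, collapse = ""), planted = sort(planted))
  }
  grid <- tidyr::expand_grid(
    event = sprintf("event_%03d", seq_len(n_events)),
    region = c("upstream", "downstream")
  )
  flanks <- purrr::map(seq_len(nrow(grid)), function(i) one_flank())
  grid$seq <- purrr::map_chr(flanks, "seq")
  grid$planted <- purrr::map(flanks, "planted")
  grid
}
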