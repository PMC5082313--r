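# mbnldose

Estimating functional MBNL splicing-factor concentration from alternative
splicing.

In myotonic dystrophy (DM1), expanded CUG-repeat RNA sequesters the MBNL
splicing factors, and the *free* (functional) MBNL concentration in a
patient's tissue — the quantity therapies aim to restore — cannot be measured
directly. What can be measured, from RNA-seq alone, is the inclusion level Ψ
of MBNL-responsive cassette exons. Each such exon responds to MBNL along a
characteristic sigmoid, so a panel of exons acts as a multiplexed biosensor
of the factor's concentration. `mbnldose` implements that idea end to end
for analysts working with Ψ matrices from patient cohorts or titration
experiments.

## The model

Inclusion of event *e* in a sample with relative functional concentration
*m* follows the four-parameter variable-slope logistic in log concentration
(`x = log10 m`):

    Ψ_e(x) = Ψmin_e + (Ψmax_e − Ψmin_e) / (1 + 10^((log10 EC50_e − x) · h_e))

with plateaus `Ψmin ≤ Ψmax` in [0,1], half-maximal concentration `EC50`,
and Hill-type slope `h` whose sign encodes whether MBNL promotes skipping
(negative) or inclusion (positive). Observed Ψ is the curve value plus
Normal(0, σ_e) noise.

The package provides:

- **Constrained curve fitting** (`fit_dose_response`): least squares with
  plateaus bounded in [0,1], multi-start optimization, curvature-based 95%
  intervals, broom-style `tidy()`/`glance()` and `autoplot()`.
- **Joint Bayesian inference** (`infer_joint`): given only an events ×
  samples Ψ matrix, MCMC over all curve parameters *and* every sample's
  latent concentration `[MBNL] ∈ [0,1]`, with the priors
  Ψmin, Ψmax ~ U(0,1), log EC50 ~ N(0.5, 1), slope ~ N(0, 1),
  [MBNL] ~ U(0,1), σ ~ U(0,1).
- **Grid posteriors for new samples** (`mbnl_posterior_density`,
  `combine_posteriors`, `predictive_power`): the probability of [MBNL]
  across its whole range given trained event curves, and the predictive
  power of a biomarker — its posterior density evaluated at the sample's
  full-data [MBNL] estimate (uniform baseline = 1).
- **Biomarker cross-validation** (`evaluate_single_biomarkers`,
  `greedy_select`): repeated 70%/30% train/test divisions, per-event power
  overall and within severity strata ([MBNL] < 0.33 severe, < 0.66 moderate,
  else mild), and greedy construction of biomarker panels.
- **Mis-splicing filters** (`filter_events`): the coverage / |ΔΨ̄| ≥ 0.20 /
  Bayes-factor criteria for calling dysregulated cassette exons in
  case/control cohorts.
- **YGCY motif analysis** (`scan_ygcy`, `window_profile`,
  `enrichment_test`): MBNL-binding motif scanning in exon flanks and a
  resampled-background enrichment t-test.
- **A synthetic-cohort generator** (`simulate_cohort`,
  `simulate_dose_series`, `simulate_exon_regions`) so the whole pipeline is
  testable without patient data.

All user-facing functions take and return tibbles and chain with the pipe;
a thin command-line wrapper lives in `inst/cli/mbnldose`.

## Worked example

Fit the dose-response of the human MBNL1 exon 5 minigene from a noiseless
series generated by its published curve, then infer a synthetic cohort's
concentrations:

```r
library(mbnldose)

wt <- sigmoid_params(psi_min = 0.41, psi_max = 0.98, ec50 = 0.19, slope = -1.8)
x  <- seq(log10(0.01), log10(10), length.out = 12)
fit <- fit_dose_response(tibble::tibble(log_conc = x, psi = logistic_psi(x, wt)))
fit
#> 4PL fit (n=12): EC50=0.19 slope=-1.8 psi_min=0.41 psi_max=0.98 R^2=1.0000
```

The fit recovers the generating constants exactly: EC50 0.19 relative MBNL1
units, slope −1.8 (MBNL promotes skipping of this exon), plateaus 0.41–0.98.

```r
cohort <- simulate_cohort(n_events = 8, n_samples = 30, sigma = 0.03, seed = 1)
post <- infer_joint(cohort$psi, iterations = 1000, warmup = 1000, chains = 4,
                    seed = 1,
                    anchor_slopes = sign(sapply(cohort$truth$event_params,
                                                `[[`, "slope")))
head(post$mbnl, 4)
#> # A tibble: 4 × 4
#>   sample     mean    q05   q95
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 sample_01 0.134 0.0733 0.210
#> 2 sample_02 0.273 0.194  0.370
#> 3 sample_03 0.483 0.389  0.596
#> 4 sample_04 0.828 0.699  0.947

cor(post$mbnl$mean, cohort$truth$mbnl_true[post$mbnl$sample])^2
#> [1] 0.985
```

Each row is one sample's inferred functional [MBNL] (posterior mean with
5%/95% bounds) on the relative [0,1] scale; against the generator's hidden
truth the squared correlation is 0.985. `anchor_slopes` passes the known
regulatory direction of each event — without it the direction of the
concentration axis is not identifiable from Ψ alone (see the methods
vignette).

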