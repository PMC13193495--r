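---
title: "Modelling growth-mark counts across fish body areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth-mark counts across fish body areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalemarks)
```

## The problem

Age determination in fishes often relies on counting annual growth marks
(annuli) on scales. Scales are cheap and non-lethal to collect, but they are
not interchangeable: scales from different body areas grow differently, get
damaged or regenerated at different rates, and may record different numbers
of visible marks. For two Gulf-of-Mexico mullets (*Mugil cephalus* and
*Mugil curema*), the question is whether the number of marks depends on the
body area the scale came from — and hence which area should be sampled for
age studies. `scalemarks` implements the full analysis pipeline for this
question: per-scale data management, screening statistics, a hierarchical
Bayesian count model, convergence diagnostics, and effect summaries, plus a
synthetic-data generator so that every stage can be validated against a
known truth.

The body surface is coded as a 3 x 3 grid: horizontal position Anterior /
Central / Posterior crossed with vertical position Dorsal / Middle /
Ventral, giving the nine area codes AD ... PV. Three to four scales are
collected per area per specimen, so mark counts are repeated measures
within individuals.

## The model

Counts of marks on readable (non-damaged, non-regenerated) scales are
modelled per species with a non-centred hierarchical Poisson regression:

* Shared (species-level) priors: `alpha ~ Normal(0, 10)` for the intercept,
  `beta_f ~ Normal(0, 10)` for each factor, and
  `sigma_alpha, sigma_beta_f ~ HalfCauchy(5)` for the individual-effect
  scales.
* Individual level, non-centred: `delta_alpha_i ~ Normal(0, 1)` with
  `alpha_i = alpha + delta_alpha_i * sigma_alpha`, and analogously
  `beta_{i,f} = beta_f + delta_beta_{i,f} * sigma_beta_f` for factors that
  vary within an individual.
* Likelihood: `marks ~ Poisson(lambda)` with
  `lambda = exp(alpha_i + X . beta_i)`, or a zero-inflated Poisson
  `ZIP(pi, lambda)` with `pi ~ Beta(1, 1)` when `likelihood = "zip"`.

The covariates are a male indicator, scale length centred at the sample
mean (a scale-level control for the size-growth correlation), horizontal
and vertical area dummies, and their interactions. Effects are reported
after inverting the log link, i.e. as multiplicative changes `exp(beta_f)`
with 95% highest-density intervals and the direction probability
`P(effect != 1)` (the larger of the two directional posterior fractions;
draws exactly at 1 count toward neither side).

### Design choices in the covariate coding

The reference cell is a female scale of average length from the
central-middle (CM) area: vertical effects are read against the middle
band (the natural baseline, since the ventral areas are reported relative
to it) and horizontal effects against the central band (the area
recommended for sampling). The coding is configurable through
`build_design()`; changing the reference only relabels contrasts.

Individual-level slopes are attached to every factor that varies within an
individual — scale length and the area terms — but not to sex: a
per-individual sex slope is not identifiable when sex is constant within a
specimen (it would be absorbed into `alpha_i`). The prior for the
slope-shrinkage scales is not separately documented anywhere we could
anchor it, so it mirrors the intercept shrinkage prior, HalfCauchy(5), by
symmetry. Whether the likelihood should be plain Poisson or zero-inflated
is genuinely ambiguous in the source material (both are named); the
package defaults to Poisson and exposes `likelihood = "zip"` so both
readings are runnable, with the ZIP weight given an uninformative
Beta(1, 1) prior.

## The sampler

No Hamiltonian-Monte-Carlo engine was available as a dependency, so the
package ships its own: a multinomial No-U-Turn sampler (recursive doubling,
biased progressive sampling, divergence flag at a Hamiltonian error of
1000) with Stan-style warmup — dual averaging of the step size toward a
0.9 target acceptance statistic and windowed estimation of a diagonal
inverse mass matrix (75-iteration initial buffer, doubling windows, 50
iterations of final step-size refinement; mass adaptation is skipped when
warmup is shorter than 200 iterations). Gradients of the log posterior are
analytic, written in C++.

Each NUTS iteration is followed by interweaving updates in the spirit of
the ancillarity-sufficiency interweaving strategy: the non-centred
coordinates place every shared location on a long ridge with its
standardized offsets (raising `alpha` while lowering all `delta_alpha_i`
leaves the likelihood unchanged), which gradient steps cross only slowly.
Holding the centred individual effects fixed — the likelihood depends on
the state only through them — the full conditional of each shared
location (`alpha`, each random-slope mean, and the coefficient of any
covariate constant within individuals, such as sex) is conjugate Normal
and is resampled exactly; each half-Cauchy scale is likewise refreshed by
a one-dimensional slice-sampling update of its sampling coordinate with
the centred deviations held fixed. These are valid Gibbs moves composed
with the NUTS kernel, so the posterior is untouched; they roughly double
the effective sample size of the shared parameters at negligible cost.

Two further numerical choices matter:

* **Scale-parameter geometry.** The half-Cauchy scales are sampled through
  a standard-normal coordinate, `sigma = scale * cot((pi/2) * Phi(-z))`
  with `z ~ Normal(0, 1)` — an exact reparameterization of the HalfCauchy
  prior. On the log scale these parameters otherwise perform a slow random
  walk through the flat region near zero; the normal-CDF map keeps the
  unconstrained tails Gaussian and roughly doubles the effective sample
  size of the shrinkage scales.
* **Overflow.** The linear predictor is evaluated in log space and any
  `eta > 60` (an expected count above e^60) marks the point as
  off-support, which surfaces as a divergent transition rather than an
  overflow.

All randomness flows through R's RNG, so `set.seed()` plus the
configuration fully determines a fit; chains run sequentially.

"Run until convergence" is made executable as: fit at the configured
length; if max split R-hat > 1.01, minimum total ESS falls below the
threshold (default 2000), or any divergence occurs, double both warmup and
draws and refit once (`max_retries`); report the final state honestly via
`glance()` and `diagnose()` either way. The package's internal criterion
monitors the species-level parameters *and* the shrinkage scales; the
shrinkage scales are the slowest-mixing quantities, so this is the
conservative reading of "all parameters" (a `strict` mode extends
monitoring to every individual offset).

## Diagnostics

`diagnose()` reports split R-hat (half-chains; the stricter modern variant
of the potential scale reduction factor), bulk ESS (combined-chain
autocorrelations, Geyer paired sums with initial-positive and
initial-monotone truncation, capped at twice the total draw count),
divergence counts, per-chain E-BFMI (`mean(diff(E)^2) / var(E)`; about 2
for white-noise energies, small values flag poor energy exploration), and
optionally posterior-predictive Bayesian p-values. The PPC simulates
replicate datasets at each retained draw — individual effects included —
and compares a test statistic with its observed value, one-sided
(`P(T_rep >= T_obs)`), reporting `p` with `1 - p` implied; the `mean`
statistic checks location calibration and the `dispersion`
(variance/mean) statistic is the standard detector of overdispersion a
Poisson model cannot absorb. ESS thresholds are totals across chains; the
per-chain reading is obtainable by dividing by the chain count.

The HDI is the sorted-window estimator: the shortest contiguous window of
the sorted draws containing `ceiling(prob * n)` of them, ties broken by
the earliest window. It is deterministic and exactly testable against a
brute-force scan of all windows, at the price of assuming a unimodal
posterior — appropriate for all the marginals this model produces.

## The synthetic-data generator

Because the study's raw data is not deposited, the generator *is* the
test bed: `truth_preset()` encodes the two species' published summaries as
generative truths and `simulate_scales()` draws full datasets from the
model's own generative process. The presets use:

* Headline effects: for *M. curema*, `exp(alpha) = 3.37`, a +7% male
  effect, +6% per unit scale length, +7% ventral effect, and a +3%
  dorsal-by-horizontal interaction; for *M. cephalus*, `exp(alpha) = 5.75`,
  a 0.98 sex effect, and area effects within 5-10% arranged so counts fall
  anterior-to-posterior along the middle band and rise along the dorsal
  and ventral bands.
* Specimen structure: locality mixtures, standard-length means and SDs and
  sex ratios from the study's sampling tables (e.g. 200 *M. curema* across
  four localities, male fraction 47/200).
* Scale length as a linear map of standard length (0.35 mm per cm, a
  plausible scale for mullet scales; units are a dataset-level convention)
  plus Gaussian noise calibrated so the scale-length/standard-length
  Pearson correlation matches the reported 0.83 (*cephalus*) / 0.6
  (*curema*).
* Damage/regeneration probabilities per area matching the observed
  percentage table (roughly 10-37%, elevated anterior and ventral cells),
  split evenly between the "damaged" and "regenerated" labels (the split
  is not documented; the analysis only uses the good/not-good dichotomy).
* Individual heterogeneity `sigma_alpha = 0.25` and slope heterogeneity
  0.05 — moderate values typical of repeated-measures count data; the
  magnitudes are not published, so they are fixed package defaults rather
  than estimates.
* Zero inflation `pi = 0` in the presets (the Poisson reading); a positive
  `pi` can be injected to exercise the ZIP path, and its magnitude is
  likewise undocumented in the source.

What the generator does *not* emulate: reader error in mark counting,
scale geometry (circuli), between-reader variation, and any
model-misspecification structure (the data really are Poisson given the
effects). Passing recovery tests therefore demonstrates that the pipeline
is a correct implementation of its own model — not that the model is true
of real scales.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles:
Kruskal-Wallis against a brute-force rank-table computation and
`stats::kruskal.test`; the HDI against exhaustive window search; ESS
against a direct-sum reimplementation, an iid oracle and the closed-form
AR(1) value `N(1-rho)/(1+rho)`; the C++ gradients against numerical
differentiation; the prior against a no-data fit; and the full pipeline
through parameter recovery. The headline end-to-end checks run a
curema-preset fit at 80 individuals (4 chains at defaults, one retry
permitted) against the convergence standards — split R-hat at most 1.01,
total ESS at least 2000 for the species-level parameters, zero
divergences — and 10 replicate fits at 150 individuals in which the 95%
HDIs must cover the true sex and length effects at least 8 times each.
These sizes keep a complete run in the tens of minutes on a single core
while leaving the Monte-Carlo error well below the tolerances tested.

## Screening stage

Before modelling, `status_table()` reproduces the damage/regeneration
percentage table (cells exact to the ratio, presentation-rounded half-up
to one decimal; locality summaries are means and sample SDs over the area
percentages), `kw_locality_screen()` applies the tie-corrected
Kruskal-Wallis test to mark counts by locality, and
`length_correlation()` checks the scale-length/standard-length
correlation. The Kruskal-Wallis unit of analysis defaults to the
per-specimen mean count — repeated measures within a specimen violate the
test's independence assumption — with `per_scale = TRUE` available for
the literal per-scale reading. Localities are excluded from the model's
design on the strength of this screen, mirroring the original analysis
flow. All-tied data make the tie correction zero and the statistic
undefined; this raises an explicit error rather than returning `NaN`.

## Known limitations

* One model per species; no joint or comparative model, and no model
  comparison criteria.
* The HDI estimator assumes unimodality; multimodal posteriors would need
  a different summary.
* The sampler is single-threaded and sequential over chains.
* E-BFMI and the energy plot are descriptive; no automatic remediation is
  attempted beyond the doubled retry.
* Real-data features outside the generative model (reader error,
  overdispersion beyond individual heterogeneity) will surface as PPC
  misfit, not as parameter bias corrections.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_scales(truth_preset("curema"), seed = 1, n_individuals = 80)
fit <- fit_scales(sim$data, seed = 2)
diagnose(fit, ppc = TRUE)
effect_summary(fit)
recovery_report(sim$truth, effect_summary(fit))
autoplot(interaction_surface(fit))
```

`run_scale_pipeline()` wires the same stages together with on-disk
artifacts and a manifest; see the README for a worked example with real
output.
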