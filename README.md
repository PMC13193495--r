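# scalemarks

Hierarchical Bayesian analysis of growth-mark (annulus) counts on fish
scales sampled from the nine body areas of a specimen.

## The problem

Fish age is commonly read from the annual growth marks on scales, but
scales from different body areas are damaged or regenerated at different
rates and may record different numbers of visible marks. For the mullets
*Mugil cephalus* and *M. curema* the practical question is which body area
(anterior/central/posterior × dorsal/middle/ventral, codes AD … PV)
yields the most reliable scales for ageing. `scalemarks` implements the
complete analysis for per-scale count data of this design:

- **Data layer** — validated CSV I/O for per-scale records
  (`read_scale_table()`, `write_scale_table()`, `filter_readable()`).
- **Screening** — damage/regeneration percentage tables by area ×
  locality (`status_table()`), a tie-corrected Kruskal–Wallis locality
  screen (`kw_locality_screen()`), and the scale-length/standard-length
  Pearson correlation (`length_correlation()`).
- **Model** — a non-centred hierarchical Poisson (or zero-inflated
  Poisson) regression per species, fitted with a built-in multinomial
  No-U-Turn sampler with analytic C++ gradients (`fit_scales()`,
  `fit_model()`):

  ```
  alpha ~ Normal(0, 10)        sigma_alpha ~ HalfCauchy(5)
  beta_f ~ Normal(0, 10)       sigma_beta_f ~ HalfCauchy(5)
  delta_alpha_i ~ Normal(0,1)  alpha_i = alpha + delta_alpha_i * sigma_alpha
  delta_beta_if ~ Normal(0,1)  beta_if = beta_f + delta_beta_if * sigma_beta_f
  marks ~ Poisson(lambda)      lambda = exp(alpha_i + X . beta_i)
  ```

  with covariates sex, centred scale length, area dummies (reference CM)
  and horizontal × vertical interactions.
- **Diagnostics** — split R-hat, bulk ESS, divergence counts, E-BFMI and
  posterior-predictive Bayesian p-values (`diagnose()`, `split_rhat()`,
  `ess_bulk()`, `ebfmi()`, `ppc_pvalue()`).
- **Effect summaries** — exp-scale effects with 95% highest-density
  intervals and direction probabilities P(β≠1) (`effect_summary()`,
  `hdi()`, `prob_direction()`), 3 × 3 interaction surfaces
  (`interaction_surface()`), broom-style `tidy()`/`glance()` methods and
  `autoplot()` figures.
- **Synthetic data** — a seeded generator with known ground truth
  (`truth_preset()`, `simulate_scales()`) emulating the study design
  (9 areas × 3–4 scales per specimen, locality-structured body sizes,
  area-dependent damage rates), plus truth-recovery reports
  (`recovery_report()`) and an end-to-end orchestrator
  (`run_scale_pipeline()`).

## Worked example

Simulate a *M. curema*-preset dataset (40 specimens), screen it, fit the
model and check recovery of the generating truth:

```r
library(scalemarks)

sim <- simulate_scales(truth_preset("curema"), seed = 1, n_individuals = 40)
nrow(sim$data)
#> [1] 1253

kw_locality_screen(sim$data)
#> Kruskal-Wallis: H = 1.8826, df = 3, p = 0.5971 (tie correction 1.0000, n = 40)

round(length_correlation(sim$data), 3)
#> [1] 0.532

fit <- fit_scales(sim$data, chains = 2, tune = 600, draws = 600, seed = 2,
                  max_retries = 0)
glance(fit)[, c("nobs", "divergences", "max_rhat")]
#> # A tibble: 1 × 3
#>    nobs divergences max_rhat
#>   <int>       <int>    <dbl>
#> 1   993           0     1.01

effect_summary(fit)
#> # A tibble: 10 × 5
#>    factor   mean_effect hdi_low hdi_high prob_direction
#>    <chr>          <dbl>   <dbl>    <dbl>          <dbl>
#>  1 sex_M          1.34    1.02      1.68          0.982
#>  2 length_c       1.06    1.03      1.10          0.999
#>  3 H_A            1.14    0.977     1.31          0.961
#>  4 H_P            1.15    0.980     1.33          0.964
#>  5 V_D            1.09    0.940     1.25          0.878
#>  6 V_V            1.16    0.999     1.32          0.982
#>  7 HxV_AD         0.972   0.774     1.17          0.636
#>  8 HxV_AV         1.05    0.844     1.25          0.67
#>  9 HxV_PD         0.915   0.729     1.10          0.803
#> 10 HxV_PV         0.881   0.708     1.08          0.887

recovery_report(sim$truth, effect_summary(fit))
#> Truth recovery: 100% of factors covered by their HDI
```

Reading the output: the locality screen finds no locality effect (p =
0.60), matching the generator, which does not link localities to mark
counts. `effect_summary()` reports multiplicative effects on the expected
mark count — here the +6% per-unit scale-length effect used by the
generator is recovered as 1.06 with a tight interval, and every
generating effect lies inside its 95% HDI. At 40 specimens the sex
effect's posterior mean (1.34) is still noisy around its true 1.07;
coverage, not the point estimate, is the calibrated quantity. The
Kruskal–Wallis screen uses per-specimen mean counts (hence n = 40), a
deliberate guard against pseudo-replication from repeated measures.

`autoplot(effect_summary(fit))`, `autoplot(interaction_surface(fit))` and
`plot_energy(fit)` give ridge-style effect, interaction-surface and
energy-diagnostic figures; `run_scale_pipeline()` runs
simulate → screen → fit → diagnose → summarize → recover end to end and
writes every artifact plus a run manifest to a directory.

## Method details

The methods vignette (`vignettes/scale-mark-modelling.Rmd`) documents the
model and its assumptions, the sampler (Stan-style warmup, divergence and
energy accounting, the half-Cauchy reparameterization), every tunable
parameter with its default and rationale, what the synthetic-data
generator does and does not emulate, and known limitations.
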