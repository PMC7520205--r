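# siteuse

Detection-corrected daily site-use occupancy and criterion-sensitive
diversity estimates from abundant, opportunistic, presence-only species
records.

## The problem

Citizen-science portals accumulate enormous numbers of presence-only records
at popular sites. With dozens of visits per site and day, nearly every
mobile species is eventually seen nearly everywhere at least once, so the
"observed at least once" seasonal species list mixes residents with
day-visiting vagrants. Local species richness (α-diversity) and between-site
dissimilarity (β-diversity) then depend strongly on the **inclusion
criterion** — how many days of presence, in a row or not, a species needs
before it counts as part of the local community — and on whether raw counts
are corrected for detection.

`siteuse` is for ecologists who want to (i) estimate daily occupancy from
such data while correcting for uneven effort, and (ii) quantify how
sensitive their diversity estimates are to the inclusion criterion.

## The model

For each species separately, visits `j` on day `d`, year `t`, site `i`:

```
y_jdti ~ Bernoulli(u_dti × p_jdti)                      observation model
u_1ti  ~ Bernoulli(ψ₁)                                  initial occupancy
u_d+1  ~ Bernoulli(u_d φ_dti + (1 − u_d) γ_dti)         daily dynamics
```

Detection rises with the visit's species-list length (SLL, the effort proxy)
and saturates at a species ceiling:
`p = pmax (1 − e^{−λ·SLL})`, `log λ = α_i + η_half + δ·PLL_t`,
with site random steepness `α_i`, a season-half offset and a slope on the
annual proportion of long lists (PLL). Persistence `φ` and colonization `γ`
are quadratic in the standardized day with site and year random effects on
the logit scale. Fitting is Bayesian: adaptive Metropolis on the marginal
posterior (latent trajectories summed out by the two-state forward
algorithm) plus exact forward-filtering backward-sampling (FFBS) draws of
the daily occupancy trajectories.

From trajectory draws the package computes, per site and criterion
(k days, nonconsecutive or consecutive): posterior inclusion probabilities,
expected richness `S = Σ_species P(included)` with credible intervals, raw
observed richness, and the pairwise β-diversity partition
`β_SOR = (b+c)/(2a+b+c)`, `β_SIM = min(b,c)/(a+min(b,c))`,
`β_NES = β_SOR − β_SIM` on lists binarized at posterior inclusion
probability > 0.5.

A synthetic-data generator (`simulate_dataset()`) reproduces the assumed
data structure — daily colonization–extinction dynamics, skewed list
lengths (60% singleton target lists), seasonally declining effort, at most
40 visits/site/day, presence-only reporting, and a background community of
unmodelled species that carries realistic list lengths — with full ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(siteuse)

cfg <- sim_config(n_species = 4, n_sites = 6, n_days = 40, visit_mean = 4)
sim <- simulate_dataset(cfg, seed = 42)
sim
#> <siteuse_simulation> 4 species x 6 sites x 1 year(s), D = 40
#>   2368 observation records from 1051 scheduled visits (seed 42)

visits    <- cap_visits(assemble_visits(sim$observations))
effort    <- compute_effort_covariates(visits, n_days = cfg$n_days)
histories <- build_detection_histories(
  visits, species_pool = sort(unique(c(unlist(visits$species),
                                       sim$focal_species))))
fit <- fit_siteuse(histories, effort, species = sim$focal_species,
                   mcmc = mcmc_config(chains = 2, warmup = 400, samples = 400),
                   seed = 1)

crit <- inclusion_criteria(k = c(1, 5, 10, 20))
rich <- richness_table(fit, crit)
incl <- inclusion_probability(fit, crit)
cmp  <- criterion_sensitivity_summary(rich, beta_by_criterion(incl))
dplyr::select(cmp, k, mode, S_mean, S_pct_change, beta_sor_mean,
              beta_sor_pct_change)
#> # A tibble: 7 × 6
#>       k mode           S_mean S_pct_change beta_sor_mean beta_sor_pct_change
#>   <int> <chr>           <dbl>        <dbl>         <dbl>               <dbl>
#> 1     5 consecutive      2.87        -22.6        0.251                 229.
#> 2    10 consecutive      2.04        -45.1        0.324                 326.
#> 3    20 consecutive      1.23        -66.7        0.733                 862.
#> 4     1 nonconsecutive   3.71          0          0.0762                  0
#> 5     5 nonconsecutive   3.15        -15.1        0.251                 230
#> 6    10 nonconsecutive   2.60        -29.8        0.271                 256.
#> 7    20 nonconsecutive   1.37        -63.1        0.647                 749.
```

Reading the output: with the loosest criterion (any day, `k = 1`), almost
all four simulated species qualify everywhere (`S_mean = 3.71` of 4) and
sites look nearly identical (`β_SOR = 0.08`). Requiring 20 days of presence
drops mean richness by 63% (nonconsecutive) and 67% (consecutive) and
multiplies between-site dissimilarity severalfold — the transient species
fall out of the lists at different sites. The consecutive variant of each
criterion is always stricter than the nonconsecutive one.

Other entry points: `tidy(fit)` / `glance(fit)` for posterior summaries and
diagnostics, `convergence_diagnostics()`, `posterior_predictive_check()`,
`daily_richness()` and `plot_daily_richness()`, `autoplot(fit)`,
`plot_richness_sensitivity()`, `plot_beta_sensitivity()`, and
`run_site_use_pipeline()` to drive simulate → ingest → fit → richness →
beta → compare as one reproducible, file-backed run.

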