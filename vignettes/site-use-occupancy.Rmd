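---
title: "Daily site-use occupancy and inclusion-criteria diversity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily site-use occupancy and inclusion-criteria diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(siteuse)
```

## The problem

Opportunistic citizen-science records from heavily visited sites (popular
birding wetlands being the canonical example) are presence-only: observers
report the species they saw, and nothing else. When such data are abundant —
dozens of visits per site and day — almost every mobile species is eventually
recorded almost everywhere at least once. A seasonal species list built from
"observed at least once" then mixes residents and breeders with vagrants that
touched the site for a day, and both local richness (α-diversity) and
between-site dissimilarity (β-diversity) become artefacts of the *inclusion
criterion* — the rule deciding how much presence qualifies a species for the
local list.

`siteuse` implements the full chain needed to study this sensitivity:

1. turn raw records into *visits* and detection histories with
   pseudo-nondetections;
2. fit, per species, a Bayesian daily colonization–extinction occupancy model
   with detection probability driven by list length;
3. evaluate inclusion criteria of the form "present on ≥ k days
   (nonconsecutive or consecutive)" on posterior trajectory draws;
4. derive richness and the pairwise Sørensen/Simpson/nestedness partition per
   criterion, and summarise how both respond as the criterion tightens.

A synthetic-data generator with known ground truth makes every stage testable
without any external download.

## Data model

A **visit** is everything one observer (or group) reported at one site on one
day of one year. Its species list length (**SLL**) is the effort proxy. Two
derived covariates describe effort beyond the visit itself: **PLL**, the
annual proportion of visits with SLL ≥ 10, and the half of the season the
visit falls in (days 1..⌈D/2⌉ are "first"). Per site and day at most 40
visits are retained, keeping the longest lists (ties broken by input order so
results are reproducible); PLL is computed after capping so it describes the
data actually modelled. A **pseudo-nondetection** is the inferred `y = 0` for
a species when a visit reported other species but not that one; site-days
with no visits contribute nothing, rather than zeros.

The season window is configurable as (start date, D days); the default is
April 1 with D = 90 days, the breeding season the workflow was designed
around. Day indexing is 1-based and inclusive.

## The site-use model

For species-, day-, year- and site-indexed occupancy `u` and per-visit
detections `y`,

```
y_jdti ~ Bernoulli(u_dti * p_jdti)                (observation model)
u_1ti  ~ Bernoulli(psi1)
u_(d+1)ti | u_dti ~ Bernoulli(u * phi_dti + (1 - u) * gamma_dti)
```

Detection saturates with list length,

```
p = pmax * (1 - exp(-lambda * SLL)),    log lambda = alpha_i + eta_h + delta * PLL_t
```

where `pmax` is the species-level ceiling ("maximum expected detection
probability"), `alpha_i` a site-level random steepness
(`alpha_i ~ N(mu_alpha, sigma_alpha)`), `eta_h` a second-season-half offset
(first half is the baseline), and `delta` the PLL slope. This form is
increasing in SLL, bounded by `pmax`, and exposes "steepness" exactly where
the covariates act. Persistence and colonization are quadratic in the
standardized day with site and year random effects on the logit scale:

```
logit(phi_d) = b0 + b1 z_d + b2 z_d^2 + eps_site + eps_year,
z_d = (d - (D+1)/2) / (D/4)
```

(so `z` spans roughly [-2, 2]), and analogously `c0, c1, c2` for `gamma`,
with independent random effects. The quadratic lets either rate rise, fall
or peak within the season, accommodating different phenologies. Multiple
years enter only through the year random effects and PLL.

### Priors

Weakly informative defaults, all overridable via `siteuse_priors()`:
Normal(0, 1.5) on every logit/log-scale intercept and slope, half-Normal(1)
on random-effect SDs, Beta(2, 2) on `pmax`, Beta(1, 1) on `psi1`. Random
effects are parameterized non-centred (`effect = sigma * raw`,
`raw ~ N(0, 1)`), which keeps the hierarchy well-behaved when data are thin.

### Inference

Each species is fitted separately. The latent daily trajectories are *summed
out* of the likelihood with the two-state forward algorithm (per site-year:
per-day emission = product of the visit Bernoullis; a detection day is
incompatible with absence; empty days are uninformative), so parameter
updates target the marginal posterior — componentwise adaptive random-walk
Metropolis, each coordinate adapting towards a 0.44 acceptance rate during
warmup. At every kept iteration the trajectories for the target year are
drawn exactly by forward-filtering backward-sampling (FFBS). This pairing is
deliberate: consecutive-day criteria are functionals of whole trajectories,
not of daily marginals, so trajectory draws are required downstream, while
marginalization keeps the parameter chain free of data-augmentation
stickiness. Defaults: 3 chains × (1000 warmup + 1000 kept), split R-hat
flagged above 1.1. Everything is seeded; refits are bit-identical.

Goodness of fit is assessed by posterior predictive checks on per-site
detection totals, per-day naive occupancy (sites with ≥ 1 detection) and
detection totals per SLL class (1, 2–4, 5+), the last being the statistic
sensitive to a misspecified list-length relationship. P-values are mid-p
(`P(rep > obs) + 0.5 P(rep = obs)`) so sparse count statistics remain
calibrated; values near 0 or 1 flag misfit. Replication uses the stored
target-year trajectory draws, so the check covers the target year (draws for
other years are not retained, to bound memory).

## Inclusion criteria, richness, and the β partition

For a criterion (k, mode), a species' inclusion probability at a site is the
fraction of posterior trajectory draws with total presence days ≥ k
(nonconsecutive) or a presence run ≥ k (consecutive). Evaluating on draws
accounts for within-season dependence; an exact dynamic-programming oracle
over the two-state chain (`exact_inclusion_probability()`) validates the
estimator in the no-data limit. By construction inclusion probabilities are
nonincreasing in k, the consecutive probability never exceeds the
nonconsecutive one, and the modes coincide at k = 1.

Expected richness is the sum of inclusion probabilities across the species
pool; credible intervals come from the per-draw richness distribution (count
of qualifying species per draw), whose mean equals the probability sum
exactly. Daily richness sums the posterior mean occupancy per day. The
raw-data counterpart counts species observed on ≥ k *distinct days*
(nonconsecutive only — raw detection days say nothing about the days in
between, so the consecutive mode is rejected for observed data).

The default criterion set is k ∈ {1, 5, 10, 20, 30} × {nonconsecutive,
consecutive}, with the k = 1 duplicate collapsed; the stricter
{1, 10, 20, 30} set is available by argument. Richness and dissimilarity are
reported for a single configured target year.

For β-diversity, a species enters a site's seasonal list when its inclusion
probability is strictly above 0.5. The pairwise partition is computed from
the incidence components (a shared, b only-A, c only-B):

```
beta_SOR = (b + c) / (2a + b + c)        total dissimilarity
beta_SIM = min(b, c) / (a + min(b, c))   turnover
beta_NES = beta_SOR - beta_SIM           nestedness component
```

Degenerate pairs are given finite values by convention: two empty lists →
all indices 0; one empty list against a non-empty one → pure nestedness
(`sor = 1, sim = 0, nes = 1`), with a log message whenever triggered. These
conventions keep the partition identity and bounds exact in every case.
Per-site summaries are unweighted means over all other sites.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
every ground-truth quantity retained:

* **Occupancy**: per species/site/year, day-1 presence `Bernoulli(psi1)`,
  then the daily colonization–extinction chain with the species' full
  transition structure (quadratic day effects, site and year random
  effects).
* **Effort**: visit counts per site-day are negative binomial (dispersion
  1.5) truncated at 40, with a log-linear seasonal trend (default −1: effort
  roughly e-fold lower by the season's end), mean 5 visits/site-day at
  mid-season.
* **Observer thoroughness**: each visit draws a target list length from a
  skewed distribution with P(1) = 0.6 (matching the dominance of
  single-species reports in opportunistic data) and a shifted
  negative-binomial tail, capped at 45.
* **Detection**: each focal species present at the site-day is detected with
  the model's saturating probability evaluated at the visit's thoroughness;
  detected species form the visit list. Visits that detect nothing leave no
  record — presence-only reporting is emergent, not imposed.
* **Background community**: by default 35 unmodelled background species are
  reported alongside the focal ones, each with probability
  `min(1, (s* - 1)/35)` for thoroughness `s*`. This embeds the focal pool in
  a richer reported community, which is precisely the situation that makes
  list length usable as an effort covariate: in a small closed pool the
  focal species' own detections dominate the realized list length, the
  apparent detection–SLL curve then saturates near 1 at list lengths close
  to the pool size, and the detection ceiling `pmax` is unrecoverable. With
  the background community, realized lists span 1–45 and the fitted
  saturation matches the generating one. Setting `n_background = 0` gives
  the closed community, used in tests of the degenerate limits.

Default parameter ranges were chosen once as ecologically plausible for a
mixed pool of residents and transients: `pmax` ∈ [0.4, 0.95], `psi1` ∈
[0.1, 0.6], persistence intercepts `b0` ∈ [0.5, 3.5] (daily persistence
0.62–0.97, i.e. mean occupancy runs of ~2.5 days up to a month),
colonization intercepts `c0` ∈ [−4, −1] (daily colonization 0.02–0.27),
moderate day-of-season curvature, site/year random-effect SDs 0.5/0.2 and
detection-steepness SD 0.3. The wide `b0` range is what produces the
transient-vs-resident contrast the inclusion criteria are designed to
separate. Every operation uses its own RNG stream derived from the master
seed, so regeneration is reproducible and order-independent.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: observer identity and heterogeneity beyond list
length, misidentification, spatial structure among sites, taxonomic
reporting biases, and any feedback between species presence and visitation
rates.

## Numerical choices and problem sizes

* Forward recursion in scaled (normalized) space with a log-sum accumulator;
  `-Inf` signals data impossible under the parameters (used for rejection in
  the sampler), `NaN` is an error.
* The sampler initializes all unconstrained coordinates near weakly
  informative centres with N(0, 0.1) jitter per chain.
* Split R-hat and a Geyer initial-monotone-sequence ESS are computed per
  parameter; identical constant chains report R-hat 1 by convention.
* Exact DP criteria state spaces are O(D·k); enumeration oracles in the test
  suite are used only for D ≤ 10–12.
* Test and example problem sizes were chosen to exercise the full method at
  realistic density while staying desk-sized: the standard recovery fixture
  is 10 focal species × 15 sites × 1 year × 90 days at mean 5 visits/site-day
  (≈ 5,000–7,000 retained visits), fitted with 3 chains × (1000 + 1000);
  unit tests use 3–5 species, 20–30 days and shorter chains.

## Known limitations

* Componentwise random-walk Metropolis mixes slowly for weakly identified
  detection parameters; R-hat for `mu_alpha`/`sigma_alpha` can exceed 1.1 on
  thin data even when occupancy quantities are stable. Diagnostics are
  reported per parameter so this is visible, and chains/iterations are
  configurable.
* With a single year, the year random effects and the PLL slope are
  confounded with intercepts; they are retained for structural fidelity, and
  the widened intercept posteriors are the honest consequence.
* Latent trajectories are stored for the target year only; inclusion
  criteria and PPC therefore address that year. Refit with another
  `target_year` for other years.
* The β partition is pairwise; no multi-site decomposition, and no
  abundance-based indices (the partition requires binary lists).
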