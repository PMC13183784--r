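---
title: "harvestlab: models, estimators, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{harvestlab: models, estimators, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestlab)
```

`harvestlab` packages two things: an individual-based model (IBM) of a
size-structured, iteroparous fish population under size-dependent harvest,
and the estimators a selection-experiment analysis needs (maturity ogives,
mortality, generation time, biphasic growth, haldane rates, elasticities).
This vignette explains the model and its assumptions, the defaults and why
they were chosen, the numerical decisions, and what the validation suite
does — and does not — establish.

## The simulated system

Each replicate population lives on a weekly clock. One call to `step_week()`
applies, in fixed order:

1. **Natural mortality.** Every fish survives the week with probability
   $e^{-\mu}$, $\mu$ in week$^{-1}$. Cannibalism, disease and senescence are
   not modelled mechanistically; they are subsumed into $\mu$, because the
   downstream estimators only ever see the resulting mortality. An optional
   density exponent scales $\mu$ by relative biomass (off by default).
2. **Growth.** Weight follows the biphasic recursion
   $w \leftarrow w + c\,w^{\alpha} f$ before maturation and
   $w \leftarrow w + c\,w^{\alpha} f/(1+r)$ after, where
   $f = \min(f_{\max}, (\mathrm{ration}/\mathrm{biomass})^{\gamma})$ is the
   food factor that makes growth density-dependent. Length follows from the
   log-log weight–length allometry
   $\log w = a_{wl} + b_{wl}\log(L/16\,\mathrm{mm})$, so lengths never
   shrink and weight–length consistency is an invariant, not a hope.
3. **Maturation.** Immature fish face a weekly Bernoulli trial with
   probability $\mathrm{logit}^{-1}(s\,(L - L_{p50}))$ — a probabilistic
   maturation reaction norm in length. A deterministic mode (mature at the
   first crossing of $L_{p50}$) exists purely so estimator tests have a
   sharp oracle; it produces complete separation in ogive fits by design.
4. **Reproduction.** Mature females release a brood every
   `brood_interval_weeks` (default 6); brood size is
   $\max(0, \mathrm{round}(b_0 + b_1 (L - 13\,\mathrm{mm})))$ above the
   13 mm fecundity threshold. Newborns enter at 7 mm with an even sex ratio.

Harvest happens on cycle boundaries (default every 6 weeks), *after* the
census and the cohort bookkeeping, so recorded cohort counts are
pre-harvest and each track row carries the realized harvest survival
$P_{hs}$ of the event that immediately follows it — exactly the quantities
the mark-recapture estimator consumes.

### Harvest regimes

With per-size-class intensity $P$ and a 16 mm SL threshold:

| regime   | eligible fish  | removed               |
|----------|----------------|-----------------------|
| positive | $L > 16$ mm    | round$(P\,n_{above})$ |
| negative | $L \le 16$ mm  | round$(P\,n_{below})$ |
| random   | all            | round$((P/2)\,n)$     |

"Larger than 16 mm" is read strictly; the boundary set $\{L = 16.000\}$ has
measure zero under continuous lengths and is assigned to the negative
regime so the two size-dependent regimes partition the population
exhaustively. Counts are rounded half-up (base R's round-half-even would
make expected takes parity-dependent); removal is simple random sampling
without replacement among the eligible. With equal abundance above and
below the threshold all three regimes remove $P/2$ of the population —
the identity the acceptance suite checks at $P = 0.60$ (30%) and
$P = 0.25$ (12.5%).

### The default experiment plan

`experiment_plan()` encodes the reference design: a 28-week establishment
period, harvest phase 1 (167 weeks, 6-week cycles, cohorts marked), a
recovery phase in which *every* population gets random harvest every
12 weeks (154 weeks) followed by a 46-week break with no harvest, and
harvest phase 2 (153 weeks, with the last six events at 12-week intervals
at doubled intensity to keep the time-averaged exploitation comparable).
Censuses sample 25% of the population at every cycle boundary, harvest or
not — the cadence during the break is not pinned down by the design, and
continuing at 12-week intervals was chosen so every phase contributes
baseline-normalizable data. `scale` shrinks phase durations (rounded to
whole cycles, minimum one cycle) so tests can run a 10×-shorter plan.

Trait "evolution" is phenomenological, not genetic: `default_drift()`
applies a linear drift of $L_{p50}$ (mm/week) during size-dependent harvest
phases, by default only in positively harvested lines. This is a
validation construct — it gives estimator pipelines a known trajectory to
recover — and deliberately not a model of inheritance.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_initial` | 140 | fish | founding design (even sex ratio) |
| `size_threshold_mm` | 16 | mm SL | maturation onset in the founders |
| `cycle_weeks` | 6 | weeks | harvest cadence |
| `harvest_proportion_P` | 0.40 | – | long-run mean intensity (range 0.25–0.60) |
| `census_fraction` | 0.25 | – | phenotypic census design |
| `mu_nat_week` | 0.0424 | week⁻¹ | observed non-positive-regime total natural mortality |
| `c`, `r`, `alpha` | 0.03, 0.5, 2/3 | g$^{1-\alpha}$wk⁻¹, –, – | juveniles reach ~16 mm in 4–5 months; surplus-power exponent 2/3 |
| `a_wl`, `b_wl` | log 0.041, 3 | log g, – | near-isometric cube law; 0.041 g at 16 mm |
| `lp50_mm`, `slope` | 16, 1.5 | mm, mm⁻¹ | maturation centred on the threshold |
| `b0`, `b1` | 0.5, 0.4 | fish, fish/mm | see below |
| `food_ration` | 60 | g | equilibrium biomass scale |

The fecundity coefficients and ration are the one place the defaults were
*calibrated* rather than taken from the stated design: the source system
reports abundances (mean 506 ± 190, range 100–1384) but no brood-size rule.
`b0 = 0.5`, `b1 = 0.4` and a 60 g ration were chosen once so that default
populations fluctuate on the hundreds scale with the negative lines
smallest, and were not revisited. Two honest caveats: positively harvested
lines, whose juveniles are never harvested, can overshoot the observed
maximum abundance severalfold during low-harvest phases; and per-fish
fecundity is lower than real guppy broods because it absorbs
newborn-to-census survival that the IBM does not model separately. Neither
affects any validated quantity.

## Estimators

**Ogives.** `fit_ogive()` is maximum-likelihood logistic regression of
maturity on length; quantile lengths come from the closed form
$L_p = (\mathrm{logit}(p) - \beta_0)/\beta_1$. The logit link is the field
standard and the reason $L_{50}$ has a closed form. Complete separation
(every immature fish shorter than every mature one) is *reported*, not
failed — flagged fit, infinite slope, quantiles at the separating midpoint —
because deterministic-maturation oracles produce it by design. Group
contrasts (`odds_ratio_contrast()`) are Wald intervals on coefficient
differences from a fixed-effects fit. The reference analysis used GLMMs
with population random effects; this package instead fits per replicate and
aggregates (mean ± SE across replicates), a deliberate simplification that
preserves the contrast structure without re-implementing a mixed-model
solver.

**Mortality.** `observed_mortality()` is the death count over starting
abundance per 6-week interval. `total_mortality_mark_recapture()` inverts
$N_{t+1} = e^{-\mu\Delta t} P_{hs} N_t$: a single interval gives the closed
form $\mu = \log(P_{hs} N_t / N_{t+1})/\Delta t$; several intervals give
$-\mu$ as the least-squares slope of harvest-adjusted log counts
($\log N_t - \sum_{s<t}\log P_{hs,s}$) against cumulative weeks. Pooling by
regression, rather than averaging per-interval estimates, keeps noisy
late-series intervals (small counts) from dominating. Negative pooled
estimates (possible on growing tracks) are floored at zero with a warning.
CIs are a seeded nonparametric bootstrap over the per-interval decrements
(1000 resamples, percentile interval) — the reference analysis does not
state its CI method, so one had to be chosen.

**Generation time.** `generation_time()` implements the life-table formula
$T = \sum x\,l_x m_x / \sum l_x m_x$ in cycles, converted to days. It is
invariant to rescaling $m_x$, so total brood counts work as well as
daughters-only. The pipeline builds $l_x$ from marked-cohort survivorship
(raw counts, i.e. including harvest, as a cohort actually experiences it)
and $m_x$ from the configured length–fecundity schedule along the growth
curve, with 1 mm-scale resolution irrelevant because the schedule is linear
in length.

**Biphasic growth.** `predict_biphasic()` is the canonical forward map
above (the published analyses delegate the exact equations to the growth
literature; the discrete weekly weight recursion with the adult increment
divided by $1+r$ realizes the stated semantics — larger $c$: faster
acquisition; larger $r$: slower adult growth — with the fewest free
parameters, and any published variant can be swapped in behind the same
interface). `fit_biphasic()` estimates $(c, r)$ only: $\alpha$ and the
allometry are fixed inputs estimated separately (`fit_weight_length()`),
and each individual's age at maturation comes from observed maturation
records. The optimizer is bounded L-BFGS-B polished from the best of a
5×5 log-spaced multi-start grid, with tight tolerances
(`factr = 1`, finite-difference steps $10^{-7}$) because the acceptance
suite demands $10^{-4}$ relative recovery on noiseless data. Trajectories
are anchored at each fish's first observation, so $w_0$ is data, not a
parameter.

**Haldanes.** `haldane_rate()` computes
$h = (\bar x_2 - \bar x_1)/(s_p\,g)$ with $s_p$ the pooled SD and
$g = 7\,\mathrm{weeks}/T_{days}$ generations. CI and $p$ come from a
bootstrap over individuals (2000 resamples, percentile interval; $p$ is
twice the smaller tail around zero, floored at $1/B$) — chosen over normal
theory because trait variances need not be equal across samples. Exact
algebraic identities (scale invariance, antisymmetry, $g \propto 1/T$)
are tested as such. The generation time supplied can be regime-specific or
one shared constant (the "equal generation time" convention).

**Elasticity.** `elasticity()` is the proportional trait change divided by
the proportional biomass change across a phase transition; a zero biomass
change yields a flagged undefined result rather than an infinity.

## Determinism and seeds

Every replicate population derives its seed from the master seed by a fixed
offset (`master_seed + 1000·index`), and all stochastic events draw from
the per-replicate stream in a fixed order, so a master seed determines the
entire event log bit-for-bit — the suite asserts byte-identical CSVs. All
bootstrap estimators accept an explicit seed.

## What a green suite establishes — and what it does not

The synthetic world has, by construction, the statistical structure the
estimators assume: exponential natural survival, binomial harvest given the
regime rule, logistic maturation in length, growth that follows the
biphasic map exactly. Recovery tests therefore establish *estimator
correctness* (no bias beyond sampling noise at the stated sizes, exactness
on noiseless input), not *model adequacy* for real data. Features of real
populations deliberately not emulated: genetic inheritance (drift is
phenomenological), individual behaviour and spatial structure,
size-dependent natural mortality (available via the density exponent but
off by default), measurement error in length, tag loss in marked cohorts,
and the husbandry adjustments of a real ration schedule. Real-data
ingestion is schema-compatible (`read_experiment_csv()`), but analyses of
real data inherit none of the guarantees above.

## Known limitations

- The fixed-effects-then-aggregate replacement for mixed models
  understates uncertainty when replicate populations share systematic
  deviations; with three replicates per regime the SE across replicates is
  itself noisy.
- The bootstrap over cohort-track intervals treats decrements as
  exchangeable; with very few intervals (2–3) its SE is unstable, which is
  why the pipeline requires at least three positive counts per cohort.
- `fit_biphasic()` assumes ages at maturation are known exactly; errors in
  `t_mature` propagate into $r$.
- Elasticities are point ratios of means; no uncertainty is propagated.
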