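# harvestlab

Size-selective harvest — fishing that preferentially removes large
individuals — is an evolutionary force: it favours fish that mature earlier
and smaller, invest more in reproduction, and grow more slowly. Decade-long
selection experiments on guppies (*Poecilia reticulata*) probe this by
keeping replicate populations under contrasting harvest regimes and tracking
their life histories. `harvestlab` re-creates the computational core of such
an experiment for simulation studies and estimator validation:

- an **individual-based simulator** of size-structured, iteroparous
  populations with overlapping generations under three regimes applied every
  6-week cycle at a 16 mm standard-length (SL) threshold:
  *positive* harvest removes a proportion `P` of fish with `SL > 16 mm`,
  *negative* harvest removes `P` of fish with `SL ≤ 16 mm`, and *random*
  harvest removes `P/2` irrespective of size — so with balanced abundance
  across the threshold every regime removes about `P/2` of the population;
- the **estimation pipeline** used to analyse such experiments:
  - maturity ogives (logistic regression of maturity on length; `L50`) and
    probabilistic maturation reaction norms (`Lp50`), with odds-ratio
    contrasts,
  - directly observed natural mortality (deaths per 6-week interval over
    starting abundance) and **total natural mortality** from marked-cohort
    decay, `N(t+1) = e^(−μΔt) · P_hs · N(t)`, with `μ` in week⁻¹ and `P_hs`
    the realized harvest survival,
  - life-table generation time `T = Σ x·l_x·m_x / Σ l_x·m_x`,
  - a biphasic growth model — weekly weight recursion `w ← w + c·wᵅ`
    before maturation and `w ← w + c·wᵅ/(1+r)` after, with `c` the
    energy-acquisition coefficient and `r` the relative reproductive
    investment — fitted by multi-start nonlinear least squares,
  - the log-log weight–length allometry standardised to 16 mm,
  - phenotypic rates of change in **haldanes**
    `h = (x̄₂ − x̄₁)/(s_p · g)` with bootstrap intervals,
  - elasticity of traits to biomass change.

Everything is validated by parameter recovery on synthetic data; no external
data are required.

## Worked example

Simulate a 3-regime, 3-replicate experiment through a scaled version of the
default phase plan (establishment → harvest phase 1 → recovery → break →
harvest phase 2), with the faster-life-history drift applied to the
positively harvested lines, then estimate maturation and mortality:

```r
library(harvestlab)

plan <- experiment_plan(replicates = 3, master_seed = 42, scale = 0.25)
logs <- run_experiment(plan, sim_config(), drift = default_drift(-0.02))
summ <- summarize_experiment(logs,
                             metrics = c("biomass", "l50",
                                         "total_mortality"))
subset(summ$l50, phase %in% c("baseline", "harvest2"))
#>      regime    phase estimate      se n normalized
#> 1  negative baseline    15.37 0.19161 3     1.0000
#> 2  negative harvest2    15.10 0.02399 3     0.9828
#> 6  positive baseline    15.15 0.26118 3     1.0000
#> 7  positive harvest2    13.87 0.01720 3     0.9160
#> 11   random baseline    15.52 0.15079 3     1.0000
#> 12   random harvest2    15.02 0.02536 3     0.9677
```

`L50` (the length at which half the fish are mature) drops by ~8% in the
positive lines while barely moving elsewhere — the classic
harvest-induced-maturation signature, here recovered by the ogive estimator
from 25% censuses of the simulated populations.

Total natural mortality, re-estimated from the marked cohorts the simulator
tracks through harvest phase 1 (the generator used μ = 0.0424 week⁻¹):

```r
summ$total_mortality
#>     regime    phase estimate      se n
#> 1 negative harvest1   0.0432 0.00320 3
#> 2 positive harvest1   0.0445 0.00118 3
#> 3   random harvest1   0.0461 0.00100 3

tr <- subset(logs$cohorts, regime == "positive" & replicate == 1 &
             cohort == "c002")
total_mortality_mark_recapture(tr, seed = 1)
#> <mortality_estimate:mark_recapture> mu = 0.04636 week^-1 [0.03758, 0.05703], 6 intervals
```

## Command line

```sh
Rscript inst/cli/harvestlab.R all --out runs/demo --seed 7 --scale 0.25
```

writes `census.csv`, `deaths.csv`, `harvests.csv`, `cohorts.csv`,
`popsize.csv`, a JSON run manifest, and per-metric report tables under
`runs/demo/report/`. `simulate`, `estimate` and `report` run the stages
separately; `--config file.yaml` overrides simulator settings.

## Vignette

`vignettes/harvestlab-methods.Rmd` documents the model, the estimators, the
synthetic world's parameter choices, and what the validation suite does and
does not establish.
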