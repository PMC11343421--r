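# hfcea

A Markov cohort cost-utility engine for evaluating empagliflozin added to
standard of care (SoC) in chronic heart failure with ejection fraction
above 40 percent, from the Malaysian healthcare payer perspective.

Heart failure with preserved or mildly reduced ejection fraction has had few
disease-modifying options; SGLT2 inhibition lowers the risk of heart-failure
hospitalisation (hHF) and shows a trend toward lower cardiovascular (CV)
mortality. Whether paying roughly RM 111/month extra per patient is good
value depends on lifetime extrapolation of those effects. `hfcea` implements
the standard health-technology-assessment machinery for that question and is
aimed at health economists and HTA analysts who want a scriptable, tested
engine rather than a spreadsheet.

## The model

A cohort enters at age 64.6 split equally across four alive health states —
the quartiles of the Kansas City Cardiomyopathy Questionnaire clinical
summary score (KCCQ-CSS; Q1 worst, Q4 best, cut points 55.73 / 73.96 /
88.02) — and is propagated in monthly cycles to age 100. Each cycle:

1. **Death.** CV death follows a Weibull AFT risk equation (treatment and
   current health state as covariates); non-CV death is the all-cause minus
   CV risk-equation difference, floored at zero, and never below the age-
   and sex-matched general-population non-CV rate from a life table
   (`max` blending).
2. **Discontinuation.** On-treatment patients stop empagliflozin at a
   generalised-gamma hazard; once off, they face SoC risks, costs and
   utilities for good.
3. **Transitions.** Survivors move between quartiles via treatment-specific
   row-stochastic matrices, different for months 1–3, 4–8 and 9+.
4. **Transient events.** Expected hHF counts accrue from a Poisson
   log-linear rate model; eight adverse events accrue at arm-specific rates.

Life-years, state utilities and drug/management costs are half-cycle
corrected; events cost and hurt in their cycle (one hHF event = RM 5,276
and a 0.335 QALY loss, i.e. a −0.335 decrement held for 12 months). Costs
and benefits are discounted at 3 %/year. Results are summarised as the
incremental cost-effectiveness ratio ICER = ΔC/ΔQ against a
cost-effectiveness threshold of RM 47,439 per QALY, with one-way (tornado),
probabilistic (1,000-iteration Monte Carlo, CEAC) and scenario/subgroup
analyses, plus prevalence-weighted pooling with reduced-EF results
(0.67/0.33, PSA resampled 670/330).

The coefficient tables behind the original analysis are not public, so the
package ships a synthetic-data module that generates internally consistent
bundles and calibrates them by root-finding to the published arm-level
targets (SoC hHF 8.45 and CV death 5.12 per 100 patient-years,
intervention 7.31 and 4.84, mean 3.34 years on treatment). A 200,000-walker
microsimulation oracle validates the cohort engine.

## Worked example

```r
library(hfcea)
cfg <- system.file("extdata", "basecase", "config.json", package = "hfcea")
p <- load_parameters(cfg)     # packaged calibrated synthetic bundle
res <- run_base_case(p)
res$epg_soc
#> <outcome_summary> arm EPG_SOC (425 cycles)
#>   discounted: LY 4.577, QALY 3.276, total cost RM 15,900
#>   event rates /100 PY: hHF 7.31, CV death 4.84, non-CV death 14.23
#>   mean time on treatment: 3.34 years
res$soc
#> <outcome_summary> arm SOC (425 cycles)
#>   discounted: LY 4.526, QALY 3.188, total cost RM 12,030
#>   event rates /100 PY: hHF 8.45, CV death 5.12, non-CV death 14.19
res$incremental
#> <incremental_result>
#>   delta cost RM 3870 | delta LY 0.0518 | delta QALY 0.0881
#>   ICER: RM 43913 per QALY gained (RM 74659 per LY)
```

Read: adding empagliflozin costs RM 3,870 more per patient over a lifetime,
buys 0.088 QALYs, and so costs RM 43,913 per QALY gained — under the
RM 47,439 threshold, i.e. cost-effective in this synthetic world (net
monetary benefit +RM 311). The hHF and CV-death rates reproduce the
calibration targets.

Sensitivity machinery:

```r
run_dsa(p)                                   # tornado table
run_psa(p, n = 1000, seed = 1)               # PSA samples
run_scenarios(p, scenario_default_specs(p))  # discount/horizon/family swaps, subgroups
```

File-based pipeline entry points (`cmd_run`, `cmd_dsa`, `cmd_psa`,
`cmd_scenarios`, `cmd_combine`) write delimited-text tables, JSON summaries
and run manifests.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic bundle from scratch, calibrates it to the published
event-rate targets, runs both arms and the deterministic ICER, then a
seed-deterministic 200-iteration PSA with the CEAC probability at the
threshold, logging each quantity as it is computed.

See `vignettes/cost-utility-model.Rmd` for modelling assumptions, parameter
choices and limitations.
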