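---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hfcea` is a Markov cohort state-transition engine for the cost-utility
question "is adding empagliflozin to standard of care (SoC) good value in
heart failure with ejection fraction above 40 percent?". This vignette
records the modelling assumptions, the choices made where the design was
genuinely open, and what the test suite does and does not establish.

## State space and cycle ordering

Alive states are the four KCCQ-CSS quartiles (Q1 worst to Q4 best, cut
points 55.73/73.96/88.02 on the 0–100 score), crossed with on/off-treatment
status in the intervention arm; death is split by cause (cardiovascular
vs other). The cycle is one month; both arms start 25 % per quartile.

Within a cycle, events are resolved in a fixed order: death first (CV, then
non-CV applied to the CV survivors), then treatment discontinuation, then
health-state transitions among survivors, then transient events (hHF,
adverse events) on the end-of-cycle alive occupancy. The source analysis
does not state an ordering; this one was chosen so that patients cannot die
out of a state they left mid-cycle, competing mortality risks resolve
cause-specifically, and transient events accrue to survivors. The
individual-level validation oracle (`microsimulate_cohort()`) implements
the identical ordering by sampling, so the equivalence test validates the
cohort propagation and accrual, not the ordering itself.

Patients who stop treatment immediately adopt SoC transition matrices,
event risks, utilities and the SoC drug price — no washout. Expected hHF
counts are Poisson expectations (`occupancy × rate`), with no per-patient
cap on events per cycle.

## Time-to-event processes

Six parametric families are supported. Weibull, lognormal, log-logistic and
generalised gamma use accelerated-failure-time (AFT) location-scale forms
(covariates shift the log-time location); exponential and Gompertz use
proportional-hazards forms (covariates shift the log hazard). These match
the conventions of common survival-regression software so externally fitted
coefficients can be transcribed without algebra; the family implies the
convention, avoiding silent mismatches. Covariates are the treatment
indicator and indicators for Q1–Q3 relative to Q4. Q4 is the declared
reference state: the source is silent on the coding, the choice is recorded
in the config, and supplied coefficient sets can override it.

The health state is time-varying: the state at cycle start selects the
hazard for that whole cycle (piecewise-constant approximation — a cohort
model cannot track within-cycle switching). Per-cycle probabilities are
`1 − S(t+1)/S(t)`; a telescoping test verifies the products reconstruct
`S(T)` to 1e-10 for every family, and reduction identities (Weibull with
shape 1 ≡ exponential; generalised gamma at Q = 1 ≡ Weibull, at Q = 0 ≡
lognormal) are checked numerically.

Non-CV mortality is the all-cause minus CV risk-equation difference,
floored at zero (extrapolated curves can cross; a warning is emitted), and
blended each cycle with the general-population non-CV rate — annual
all-cause probability × (1 − CV share of deaths), sex-mix weighted,
converted monthly as `1 − (1−p)^(1/12)` — taking the maximum. The cohort
ages continuously (`age(t) = 64.6 + t/12`), life-table lookups use the
integer age floor.

Base-case families follow the text of the source analysis: Weibull for CV
and all-cause death, generalised gamma for discontinuation. (Its input
table lists Weibull for discontinuation, contradicting its own methods
text; the methods text wins here, and Weibull discontinuation is available
as a scenario.)

## Accrual, discounting, reporting

State-based quantities (life-years, state utilities, drug and
disease-management cost) use half-cycle-corrected occupancy — the mean of
cycle-start and cycle-end occupancy. Event-based quantities apply in full
at their cycle: an hHF event costs RM 5,276 and 0.335 QALYs (a −0.335
decrement held twelve months; the only reading consistent with the
published per-patient hHF QALY-loss figures given the event rates), an
adverse event costs its unit cost and |disutility|/12 QALYs (decrement held
one month). Whether the original model half-cycle-corrected event counts as
well is unknowable from the text; here the correction applies to occupancy
only. Mean time on treatment is likewise a half-cycle-corrected occupancy
sum, reported undiscounted.

Discount factors are `(1+r)^(−cycle/12)` with 0-based cycles, 3 %/year for
both costs and benefits. Event rates per 100 patient-years divide
cumulative undiscounted expected events by undiscounted alive person-years.
A "lifetime" horizon means age 100, or total alive occupancy below 1e-6,
whichever comes first; the horizon is clamped (with a warning) to the life
table's coverage. Internals run in full double precision; only reporting
helpers round (costs to whole RM, rates to 2 dp, scenario percent change to
whole percent).

## The synthetic world

The risk-equation coefficients, transition matrices and AE incidence tables
behind the original analysis are unpublished. `generate_bundle()` therefore
builds a stated stand-in world:

* **Transition matrices**: Dirichlet-drawn rows (concentration 200) centred
  on mean reversion toward adjacent quartiles, with stay probabilities
  0.55/0.65/0.75 across the three periods (early dynamics settle after
  month 8). Intervention matrices are the SoC matrices tilted by a
  log-odds shift toward better states — 0.20/0.12/0.08 per period, largest
  early, mimicking the early health-status response seen in the trial.
* **Mortality**: Weibull AFT with mildly increasing hazard (σ = 0.90 CV,
  0.95 all-cause), worse states dying sooner; the all-cause equation has no
  treatment effect (the source assumed a CV-only survival benefit).
* **Discontinuation**: generalised gamma (σ = 1.2, Q = 0.7), slightly
  faster in worse states.
* **Adverse events**: monthly rates set from the published arm-level rates
  per 100 PY; disutilities and unit costs verbatim from the published input
  table. Ketoacidosis (below the 1/100 PY inclusion cut) is generated but
  excluded by default; its rate (0.6/0.2 per 100 PY), disutility (−0.05)
  and cost (RM 2,500) are synthetic stand-ins, chosen once as plausible,
  and marked as such.
* **Life table**: Gompertz-type hazard doubling roughly every 7.3 years
  (male q(65) ≈ 0.018, female ≈ 0.012 — plausible for the setting), CV
  share of deaths declining from 0.42 toward 0.22 inside the 0.2–0.5 band,
  cohort sex mix 55 % male.
* **Costs and utilities**: the published values verbatim (utilities
  0.613/0.707/0.778/0.832; drug RM 212 vs 101/month; hHF RM 5,276; CV
  death RM 2,573; management RM 28/month).

`calibrate_bundle()` then root-finds the event-model intercepts so the full
engine reproduces the published arm-level targets (SoC hHF 8.45/100 PY and
CV death 5.12/100 PY; intervention 7.31 and 4.84; 3.34 years mean
treatment duration) within 0.5 %. Comparator-arm quantities depend only on
comparator parameters, so SoC CV death is solved first, then SoC hHF (its
person-years depend on survival). The intervention-arm treatment
coefficients and the discontinuation intercept are mutually dependent
(off-treatment patients revert to SoC risks), so those three are cycled to
joint convergence — for the comparator the intercept is the free location
parameter, for the intervention arm the treatment log-ratio is. Brackets
start at ±1.5 on the coefficient scale and double up to four times;
no root is a hard calibration error reporting the bracket.

What a green suite establishes: the engine's propagation and accrual are
consistent with an independent individual-level simulation of the same
stated world, closed-form limits hold, and calibration recovers its
targets. What it does not establish: that this world's coefficients equal
the unpublished ones — so headline numbers (ICER, CEAC probabilities) are
properties of the synthetic world, expected to be near, not equal to, the
published results. Parameters are not correlated across the bundle, and
patient-level heterogeneity beyond the four states is not emulated.

## Sensitivity analyses

* **One-way (tornado)**: printed interval bounds where available — hHF rate
  ratio to its published upper 95 % bound 0.83, CV-death hazard ratio to 1
  (benefit removed) — otherwise ±20 % for costs and ±10 % for utilities
  (Q1 capped below Q2 to keep ordering). Bars are sorted by ICER width;
  rows crossing the threshold are flagged; invalid overrides are marked
  failed without aborting the table.
* **Probabilistic**: beta for utilities and disutility magnitudes
  (moment-matched, SE = 10 % of mean), gamma for event/management costs
  (SE = 20 % of mean), lognormal for the two treatment ratios (spread from
  the published composite 0.69–0.90 interval), Dirichlet on every
  transition row (concentration 100 × base row). Drug acquisition prices
  are administered prices, treated as known and held fixed. Draws that
  violate hard constraints (sign, range, non-finite) are redrawn, with a
  hard error after 100 retries; the base-case requirement that state
  utilities be strictly ordered is deliberately *not* imposed on draws —
  independent beta draws may cross, which is standard practice and keeps
  the sampled means unbiased. All randomness flows through the seed;
  per-iteration draws and the distribution manifest are attached to the
  returned samples.
* **Scenarios**: discount 0 %/5 %, horizons 5/10 years, starting age 71.9,
  family swaps for mortality and discontinuation, no discontinuation,
  ketoacidosis on, no CV benefit, and the diabetes subgroups (T2D: CV HR
  1.01, hHF 0.78; non-T2D: 0.83/0.77), which share the base transition
  matrices. Family swaps have no published coefficients, so the alternative
  family is refit to the base survivor curve (least squares on log S over
  months 3–120 at the reference covariate pattern) and covariate effects
  are carried over — copied between AFT families, converted via
  `−β/σ` for PH targets (exact for the Weibull base). This preserves the
  trial-period fit and varies only the extrapolation tail, which is the
  point of the scenario.

The mean PSA ICER is the ratio of mean deltas, not the mean of ratios:
it is the convention under which a zero-variance PSA reproduces the
deterministic ICER exactly (a tested property). Phenotype pooling resamples
without replacement (670/330 from the two pools), preserving the empirical
marginals at those counts; the deterministic pooled ICER uses full-precision
phenotype deltas, not rounded ones.

## Known limitations

Procurement-price scenarios cannot be reproduced (prices undisclosed).
The engine is a cohort model: history dependence (e.g. risk rising with
prior hospitalisations) is out of scope except via the health states.
Coefficient fitting from patient-level data, EQ-5D mapping, and
value-of-information analysis are out of scope. Costs are 2022 RM with no
currency conversion.
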