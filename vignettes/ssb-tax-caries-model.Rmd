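---
title: "A closed-cohort Markov model of SSB taxation and dental caries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-cohort Markov model of SSB taxation and dental caries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariestax)
```

## The decision problem

A 20% valoric (flat sales) tax on sugar-sweetened beverages (SSBs)
raises prices, reduces purchases, and thereby lowers daily free-sugar
intake. Because sugar is the primary cause of dental caries, the tax is
expected to avert caries cases, the decayed teeth and toothache they
bring, and the downstream treatment costs. `cariestax` quantifies that
chain for a national population stratified by quintiles of the Index of
Relative Socio-economic Disadvantage (IRSD; quintile 1 is the most
disadvantaged), comparing the tax against no intervention from both a
societal and a healthcare perspective.

## Model structure and assumptions

Each single-year age cohort (ages 0–100) of each sex and quintile is
simulated as a closed cohort through four states — *caries free*,
*dental caries*, *edentulism* (complete tooth loss, no longer
susceptible to caries), and *dead* (absorbing) — in annual cycles.
Cohorts enter at their prevalence: edentulism prevalence first, the
remainder split between caries and caries free by caries prevalence.
Toothache is not a separate state (its duration is weeks, not years);
it is an attribute of incident cases.

Within a cycle, competing events are applied in a fixed order:

1. background death, from every living state;
2. edentulism onset, from caries free and caries;
3. caries incidence, from caries free, scaled by the intervention
   multiplier;
4. recovery: the treated fraction of the caries state returns to caries
   free.

The ordering is a modelling choice (the source materials for models of
this family typically do not state one), and it matters at the third
decimal of the results; `transition()` documents and tests it, and the
test suite checks the engine against an independent brute-force
path-enumeration oracle. Treated means: everyone with toothache plus,
of the remainder, those who attended a dental practitioner within 12
months — both probabilities live in the epidemiological schedule, so
the recovery fraction is age- and sex-specific. Untreated cases remain
in the caries state and may be treated in a later cycle (attendance is
an annual probability).

Cohorts are simulated for `min(horizon, 101 − start age)` cycles, so no
one ages past 100; survivors at that cap simply stop accruing. This
age-cap convention makes the "lifetime" scenario a 100-cycle horizon.

## From tax to incidence

The exposure chain is multiplicative and intentionally simple:

- grams of sugar removed per day
  = population-mean cups/day × grams per cup × 11.52% (net consumption
  reduction under the tax, SD 9.62 percentage points) × effectiveness
  decay;
- incidence multiplier
  = max(0, 1 − 0.010 × Δgrams/10), where 0.010 (SD 0.028) is the annual
  DMFT change per 10 g sugar/day, and a fractional DMFT change is
  treated as the same fractional reduction in caries incidence.

Design choices worth knowing:

- **Population-mean consumption.** The consumption table's "mean daily
  cups" is read as the mean over the whole quintile population;
  the consumer share is carried for reporting but not used as a second
  exposure pathway, which would double count.
- **Ages 0–1 are exempt** (`min_ssb_age = 2`): no consumption data
  exist for infants, so the multiplier is 1 there.
- **Grams per cup defaults to 26 g**: a 250 mL cup scaled from an
  average 39 g of free sugar per 375 mL serve. The survey-derived value
  is not public; the parameter is configurable.
- **Same multiplier for deciduous and permanent teeth.** Deciduous
  teeth are in reality more caries-prone; the schedule's
  `deciduous_fraction` column (1 up to age 5, linear hand-over across
  the mixed-dentition ages 6–14, 0 from 15) documents the dentition mix
  but does not modulate the effect.
- **Effectiveness decay** is a constant retained fraction per cycle,
  not a compounding decline; the threshold analysis searches over this
  constant.

## Outcomes and costs

Each incident case carries 1.64 (SD 1.262) decayed teeth. DALYs are
years lived with disability only — dental disease is nonfatal here, so
no years-of-life-lost term exists. Symptomatic (toothache) episodes
accrue `0.010 × duration/365` DALYs with durations of 28 days for ages
2–16 and 55 days from age 17; time spent edentulous accrues a constant
disability weight of 0.067 per person-year.

Treated caries episodes cost a check-up (AUD 54.69) plus restorations
(AUD 189.61 per decayed tooth under the default `per_tooth` mode; a
`per_episode` switch exists). The societal perspective adds travel
(AUD 20.71 per visit) and time (AUD 49.22/h over 60 min travel + 60 min
treatment); children incur the same time costs via an accompanying
adult. Treated edentulous persons (those perceiving a denture need)
receive a denture pair (AUD 2798.08) at onset and replacements with
annual probability `1 − 0.41^(1/10)` ≈ 0.085 derived from 10-year
denture survival by the compounding conversion (probability↔rate
conversions are never linear). The denture visit schedule is three
visits; the stated "three appointments totaling 60 min" is ambiguous,
so the default treats 60 min as the total treatment time
(`denture_minutes_mode = "total"`), with a `per_visit` alternative.
Tax administration costs (AUD 5.8M in year 1, 4.47M thereafter) accrue
in the intervention arm under both perspectives; quintile-level runs
carry their population share of it. The 85%/15% private/public fee mix
is taken as already folded into the printed mean fees.

Rewards based on state occupancy (edentulous person-years) use
trapezoidal within-cycle weighting — the half-cycle correction — while
event flows accrue in the cycle they occur; transitions themselves are
uncorrected. Discounting applies `(1.03)^−(t−1)` from year 2 onward
(year 1 is already in present value).

## Uncertainty analysis

The probabilistic sensitivity analysis samples all uncertain parameters
per draw — moment-matched gamma for costs, durations and caries
severity, moment-matched beta for probabilities and disability weights,
and zero-truncated normal for the two effect sizes (the distribution
families are standard cost-effectiveness practice; the sources do not
state them). Each draw feeds *both* arms (common random numbers), so
increments isolate the intervention effect. Draw `i` is reproducible
from `(seed, i)` alone. Cost-effectiveness is operationalized uniformly
as positive net monetary benefit, `NMB = WTP × ΔDALY + savings`, at
AUD$50,000 per DALY averted; the acceptability curve evaluates the same
indicator over a WTP grid. Uncertainty intervals are 2.5/97.5
percentiles over draws. Dominance (cost-saving and health-promoting) is
declared on PSA means.

The threshold analysis bisects the effectiveness-decay constant on
[0, 1] to a tolerance of 1e−3, holding the PSA draws fixed across
evaluations so the criterion is monotone. The default criterion is
probability cost-effective ≥ 0.5, with ties (NMB exactly zero) counting
as acceptable so that a costless, zero-effect intervention sits at the
margin; a mean-NMB ≥ 0 alternative is available
(`criterion = "mean_nmb"`).

## The synthetic input generator

The real analysis rests on burden-of-disease extracts and national
survey tables that are not redistributable, so `synth_spec()` +
`generate_*()` produce complete, internally consistent stand-ins with
the statistical structure the model assumes:

- caries incidence: unimodal in age, peaking at age 12 with annual
  probability 0.32 (chosen so that whole-population caries episode
  counts land at a realistic a-fifth-of-the-population-per-year scale),
  log-normal shape in age;
- edentulism incidence: zero before age 40, rising exponentially after;
  entry prevalence accumulated from the incidence curve;
- mortality: infant component plus Gompertz hazard (slope 0.095/year),
  males ~25% higher, monotone beyond age 60;
- care seeking: toothache probability 0.25, 12-month attendance 0.65
  (children) / 0.55 (adults), perceived denture need 0.5 — flat in age,
  in the range of national oral-health survey estimates;
- population: a stationary age pyramid (counts ∝ survival), 25.7M
  total, rounded by largest remainder so totals are exact;
- consumption: in **fixture** mode, exactly the published survey table
  (1.41, 1.18, 0.94, 1.02, 0.72 cups/day and 44.7–29.0% consumers for
  quintiles 1–5; 1.07 cups, 37.2% for the total population) with equal
  quintile population shares; in **synthetic** mode, seeded
  perturbations of the curve-shape parameters that preserve smoothness
  and the strictly decreasing consumption gradient.

Fixture mode draws no random numbers at all and is therefore bit-stable
across runs; synthetic mode is deterministic given its seed.

What passing tests on these inputs do and do not show: they verify the
model's mechanics (conservation, monotonicity, accounting identities,
oracle agreement, reproducibility) and qualitative behaviour (the
equity gradient follows the consumption gradient; the intervention is
dominant at realistic scales). They do not validate the published
Australian burden or cost magnitudes — the synthetic schedule is shaped
like, but not calibrated to, the real extracts, and quintiles share one
epidemiological schedule, so equity ratios here reflect consumption
differences only (roughly the Q1/Q5 cups ratio of ~2), whereas analyses
with quintile-specific epidemiology report steeper gradients.

## Numerical choices and degenerate inputs

- Occupancy is validated to sum to 1 within 1e−10 each cycle; drift
  beyond 1e−8 raises an internal consistency error.
- The incidence multiplier clamps at 0, unreachable for published
  central values (it stays above 0.9 for all fixture inputs).
- Degenerate PSA (all SDs zero) returns central values exactly, so the
  Monte Carlo mean equals the deterministic run bit-for-bit.
- A sampled net consumption reduction above 1 (possible only in the
  far tail of the truncated normal) is capped at 1.
- Caries prevalence at entry is the steady state implied by incidence
  and the recovery fraction, `h/(h + r)`.
- With zero mortality, edentulous occupancy is monotone non-decreasing;
  with mortality it need not be (deaths deplete the state), which is
  why monotonicity is asserted on cumulative inflows instead.
- Serialization writes doubles at 17 significant digits, so
  write-then-load round-trips are lossless.

## Problem sizes

The headline analysis uses 2000 Monte Carlo draws (binomial standard
error on a probability near 0.7 of about 1 percentage point) over 101
ages × 2 sexes × 6 profile groups. The bundled acceptance script runs
both horizons at 2000 draws and the threshold bisection at 200
common-random-number draws per evaluation — the threshold is a
root-finding problem on a monotone function, where draw noise shifts
the located root by far less than the decision-relevant margin.
`ssb_cea()` defaults to 200 draws for interactive use.

## Known limitations

- No severe-tooth-loss sequela, no root-canal/extraction/anaesthesia
  cost pathways, and no repeat-restoration cycles: savings are
  conservative.
- No drink substitution effects, no tax-revenue modelling, no
  population growth (closed cohort), and no movement between quintiles.
- The sugar-dose slope is dimensionally loose (a DMFT increment equated
  to a fractional incidence change); the package follows that
  equivalence rather than re-deriving a severity-weighted one, and
  applies severity (1.64 teeth/case) only when counting decayed teeth,
  never inside the incidence effect.
- Equity stratification rests on area-level disadvantage, and only the
  consumption profile differs by quintile.
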