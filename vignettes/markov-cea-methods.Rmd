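---
title: "Methods: a five-state Markov cohort model for eplerenone in NYHA Class II heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-state Markov cohort model for eplerenone in NYHA Class II heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcea)
```

## The decision problem

Chronic heart failure patients with mild (NYHA Class II) symptoms can
progress to more severe functional classes, be hospitalized, and die of
cardiovascular or other causes. Adding the aldosterone antagonist
eplerenone to standard therapy reduces heart-failure hospitalization and
cardiovascular death, at the price of drug and monitoring costs. `hfcea`
models whether that trade-off is value for money for the Australian
healthcare system, in 2014 AUD, against *usual care* — a comparator in
which part of the population already takes spironolactone, a cheaper drug
of the same class assumed (conservatively) to be equally effective.

## Model structure

A discrete-time Markov cohort model with 1-year cycles and five states:
alive in NYHA Class I–IV, and dead (absorbing). Each living class has a row
of ten per-cycle outcome probabilities: for each living destination class,
a no-hospitalization and a hospitalization variant, plus cardiovascular and
non-cardiovascular death. Hospitalization here means surviving the cycle
with at least one heart-failure admission; deaths within a cycle are
mutually exclusive with non-fatal hospitalization. The cohort starts 100%
in Class II at age 68 and runs for a 10-year horizon.

The same placebo transition table drives both arms:

* **Eplerenone (EG)** rows are the placebo rows transformed by direct
  probability multiplication with the trial hazard ratios —
  hospitalization entries × 0.58, CV death × 0.76 (the all-cause variant,
  × 0.76 on total death mass with cause shares preserved, is available via
  `hr_mode = "all-cause-split"`).
* **Usual care (UCG)** rows are per-class convex combinations: a
  spironolactone fraction (0 / 0.437 / 0.937 / 0.937 for Classes I–IV)
  gets the treated row, the remainder the placebo row.
* The NYHA IV row equals the NYHA III row — the source data do not resolve
  Class IV separately.

### Where the freed probability mass goes

Multiplying selected probabilities by a hazard ratio breaks the row-sum
constraint, and the source of the transformation is silent about the
repair. `hfcea` uses two rules, chosen to preserve class dynamics:

1. hospitalization mass freed by the hospitalization HR moves to the *same
   destination's* no-hospitalization entry (the destination-class
   distribution is unchanged — the effect is fewer admissions, not
   different progression);
2. death mass freed by the death HR is spread proportionally over all
   eight living entries.

Both rules are unit-tested against frozen hand arithmetic. A consequence
worth knowing: after rule 2 the hospitalization entries are 0.58 × placebo
*times a small uniform living rescale* (≈1.01 at typical death risks), not
0.58 × placebo exactly; the two statements cannot hold simultaneously, and
rule 2 is the one this package commits to.

### Age trend

Death risks grow with age. Each cycle the two death probabilities are
multiplied by a relative mortality multiplier at the cohort's current age
(normalized to 1 at the baseline age of 68), total death mass is capped at
1, and the living entries are rescaled proportionally. One combined trend
is applied to both causes of death: separate CV and non-CV trends would
demand cause-specific life tables the parameter pack does not carry, and
with proportional repair the split has no effect on total survival.

The shipped trend is a **synthetic stand-in**: an exponential with log
growth 0.087 per year of age (risk doubling roughly every 8 years, the
textbook adult all-cause mortality gradient and a fair approximation to
Australian population life tables in the 68–90 range). A transcribed
(age, multiplier) table can be supplied in the `age_trend` config block and
is used verbatim.

### Order of operations

The age trend is applied before the treatment effect each cycle — the
trend describes background risk that treatment then modifies. A config
flag (`trend_order = "treatment-first"`) flips the order. Testing revealed
a small identity: for the eplerenone arm the two orders *commute exactly*,
because both operations are multiplicative on deaths with proportional
living repair. They differ only for the usual-care arm, where the mixture
is taken between rows of unequal death mass and the trend's rescale is
nonlinear in that mass. Both paths preserve all row invariants.

## Accrual and discounting

Occupants at the *start* of a cycle earn that full cycle's life-year,
utility-weighted QALY (utilities 0.815 / 0.720 / 0.590 / 0.508 for
Classes I–IV, no hospitalization decrement), class background cost
(AUD 151 / 175 / 226 / 242), and the arm's drug and monitoring costs. No
half-cycle correction is applied — the modelled analysis names none — so
deaths during a cycle still accrue that cycle's person-time; a
`accrual = "cycle-end"` switch exists for sensitivity checking.
Hospitalization transitions cost AUD 7136 each, capped at one costed
admission per transition (the `double_hospitalization` scenario raises the
cap to 2). Deaths cost AUD 1821 = 50% × AUD 3642, the terminal CV
admission cost times the fraction of deaths assumed to occur in hospital.

Eplerenone monitoring is AUD 35.60 in cycle 1 (two electrolyte/urea tests
in the first 3 months) and AUD 71.20 per year thereafter. Whether year 1
should carry 35.60 alone or 35.60 + 71.20 is ambiguous in the source; the
default is 35.60 alone, and `monitor_year1_combined = TRUE` selects the
other reading. The difference is ≤ AUD 71.20 per person undiscounted.

Discounting is 5%/year applied from cycle 2 ("after the first cycle"):
cycle *t* ≥ 2 is weighted by $(1.05)^{-(t-1)}$. Event counts per 1000 are
reported undiscounted; life-years, QALYs and costs both ways.

## Sensitivity analyses

* **DSA** — one parameter at a time to its 95% CI (hazard ratios) or ±50%
  of base (everything else; utilities and fractions capped at 1), full
  model rerun at each bound, table ordered by ICER-per-QALY range width.
* **PSA** — Monte Carlo over: beta-distributed utilities (method of
  moments, SE = (hi − lo)/3.92), uniform costs on ±50%, and triangular
  transition probabilities (mode = base, ±50% limits capped into [0, 1]);
  each of a row's ten entries is drawn independently and the row is then
  renormalized (no joint Dirichlet structure is claimed by the source).
  Eplerenone/spironolactone drug and monitoring costs are fixed. Per
  iteration both arms are rerun; outputs are the incremental scatter, the
  CEAC, the percent cost-effective at AUD 50,000/QALY, and percentile
  (2.5/97.5) intervals of iteration-level ICERs restricted to the
  positive-effect quadrant (with the quadrant composition reported,
  since ratio intervals are ill-defined across quadrants); net-benefit
  intervals are also emitted. Reproducibility: iteration *i* reseeds from
  `(seed + 10007·i) mod (2^31 − 1)`, so runs are bit-identical for a given
  seed and trivially parallelizable.
* **Scenarios** — pre-registered transforms: 3% discounting, 2- and 4-year
  horizons, all hazard ratios reverting to 1.0 from cycle 2 (the source
  does not say *which* HR; all three is the conservative reading, and a
  per-HR override is available through `build_arm_tables()`), two costed
  hospitalizations per transition, 100% of *CV* deaths in hospital (CV
  death unit cost 3642, non-CV unchanged), and per-year transition tables
  for cycles 1–4 (errors cleanly when the config carries none).

## The synthetic cohort as oracle

`simulate_patients()` draws patient-level trajectories with *exactly* the
generative assumption of the cohort recursion — one multinomial draw over
the ten outcomes per patient-cycle, no latent competing-risk times — so
cohort occupancies are the exact expectations of microsimulation
frequencies and agreement within binomial Monte Carlo error is a sharp
test, not an approximation. `estimate_transition_table()` recovers rows by
maximum likelihood from event logs (counts over at-risk person-cycles;
never-observed rows are flagged missing, not invented).
`parameter_recovery_suite()` closes the loop: simulate trial-like
follow-up from the *base* placebo table — deliberately without the age
trend, because the trial data the table would be estimated from precede
the model's trend extrapolation, and re-applying the trend to
trend-contaminated estimates would double-count it — re-estimate, rebuild
the config, rerun, and report relative errors. At n = 50,000 the
ICER-per-QALY recovery error is well under 5%.

What a green suite does **not** establish: the generator shares the
model's assumptions by construction, so agreement says the code is
faithful to the model, not that the model is faithful to heart-failure
epidemiology (no covariates, no enrolment waves, no censoring, no
within-cycle event ordering).

## The stand-in world

The published transition table and the life-table appendix exist only as
figures in the available text, so the shipped pack uses synthetic
stand-ins, chosen once for realism and frozen: the Class II row gives a
~14%/year hospitalization risk and 7%/year death risk (consistent with the
placebo event rates the trial reports in prose), Class I is milder, III/IV
markedly worse. All headline outputs of this package therefore describe
the stand-in world — the base-case ICER of ≈ AUD 66,000/QALY is *not* the
published figure and was never tuned toward it. Users with access to the
original table can drop it into the CSV referenced by the parameter pack;
every downstream computation then reproduces the published pipeline.

## Numerical conventions

* Row sums are validated to 1e-9 at load (1e-12 after algebra); printed
  rounding up to a 0.05 deviation is repaired by proportional
  renormalization with a warning, anything worse is rejected.
* ICERs are computed from full-precision deltas; display rounding (whole
  AUD, one decimal for LY/QALY/NNT) happens only in print methods.
* A zero effect delta yields an undefined (NA) ratio, never an exception;
  NNT is NA when no events are averted.
* Beta moment-matching falls back to uniform, with a warning, when the
  requested variance is infeasible (σ² ≥ μ(1 − μ)).
* The trend table is linearly interpolated inside its age range and
  extended flat beyond it, so no age below 110 errors.

## Known limitations

* Transition probabilities and age trend are stand-ins until transcribed.
* The usual-care mixture inherits eplerenone efficacy and utilities for
  spironolactone users — the source's own conservative assumption.
* One costed admission per hospitalization transition understates
  multiple-admission cycles (addressed as a scenario, not in base case).
* The cohort engine is deterministic and homogeneous; patient-level
  heterogeneity lives only in the microsimulator.
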