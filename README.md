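# hfcea

Markov cohort cost-effectiveness modelling of eplerenone versus usual care
in chronic heart failure with mild (NYHA Class II) symptoms, from an
Australian healthcare-system perspective in 2014 AUD.

## Who this is for

Health economists and HTA analysts who need a transparent, scriptable,
fully-tested implementation of a five-state NYHA progression model — the
kind of decision-analytic cohort model usually built in a spreadsheet —
with deterministic and probabilistic sensitivity analysis, scenario
analysis, and a patient-level microsimulator that serves as an independent
oracle for the cohort recursion.

## The model

Five health states: alive with NYHA Class I, II, III or IV, and dead
(absorbing). Each living class has ten per-cycle (1-year) transition
probabilities: eight (destination class × {no hospitalization,
hospitalization}) outcomes plus cardiovascular and non-cardiovascular
death. A cohort starts at age 68 in Class II and is propagated for 10
cycles.

- **Treatment effect** — eplerenone transition probabilities are obtained by
  direct multiplication of the placebo probabilities: hospitalization
  entries by HR 0.58 (95% CI 0.47–0.70), CV death by HR 0.76 (0.61–0.94);
  an all-cause mode (HR 0.76, 0.62–0.93) is configurable. Freed
  hospitalization mass returns to the same destination's
  no-hospitalization entry; freed death mass is spread proportionally over
  the living entries, so every row still sums to 1.
- **Usual care** — a per-class mixture: 0% / 43.7% / 93.7% / 93.7% of
  Classes I–IV take spironolactone and are assigned eplerenone efficacy;
  the rest follow placebo dynamics.
- **Age trend** — both death probabilities are scaled by a relative
  mortality multiplier as the cohort ages (normalized to 1 at 68), with the
  living entries rescaled proportionally.
- **Accrual** — cycle-start occupants earn that cycle's life-year, the
  class utility (0.815 / 0.720 / 0.590 / 0.508) as a QALY weight, the class
  background cost (AUD 151 / 175 / 226 / 242), and arm drug + monitoring
  costs (eplerenone 1374 + 35.60 first cycle / 71.20 thereafter;
  spironolactone 45.29 + 71.20 for the treated fraction). Hospitalization
  transitions cost 7136 each (one per transition in the base case); deaths
  cost 1821 (= 50% × the 3642 terminal CV admission). Costs and effects are
  discounted at 5%/year after the first cycle.
- **Outcomes** — incremental cost-effectiveness ratios (AUD per year of
  life saved and per QALY gained), events averted per 1000 and the number
  needed to treat, one-way DSA (95% CIs, else ±50%), PSA (beta utilities,
  uniform costs, triangular transition probabilities; CEAC and percentile
  intervals), and seven pre-registered scenarios.

**Stand-in inputs.** The published usual-care transition table and the
life-table appendix behind the age trend are available only as figures, so
the shipped parameter pack (`inst/extdata/parameter_pack.yaml`) carries
clearly flagged synthetic stand-ins with realistic magnitudes. All other
inputs are the published values. Replace the stand-ins with transcribed
values to reproduce the published analysis; results below are for the
stand-in world.

## Worked example

```r
library(hfcea)
config <- default_parameters()           # or load_config("my_pack.yaml")
arms <- run_arms(config)
print(arms$EG)
#> Arm EG over 10 cycles
#>   life-years (disc/undisc):  5.866 / 6.956
#>   QALYs      (disc/undisc):  4.140 / 4.905
#>   cost AUD   (disc/undisc):  14030 / 16686
#>   events per 1000: 585 hospitalizations, 674 deaths
icer(arms$UCG, arms$EG)
#> Incremental analysis (intervention - reference)
#>   delta cost:  AUD 7121
#>   delta LY:    0.151   delta QALY: 0.108
#>   ICER: AUD 47063 per YoLS, AUD 66136 per QALY
#>   dominance: none
event_diff(arms$UCG, arms$EG)
#> Events averted per 1000 over the horizon
#>   hospitalizations: 158 (NNT 6.3)
#>   deaths:           30 (NNT 33.1)
```

Eplerenone adds AUD 7121 per person over ten years (drug, monitoring, and
longer survival accruing background costs) and buys 0.151 discounted
life-years / 0.108 QALYs, i.e. AUD 47,063 per YoLS and AUD 66,136 per QALY
under the stand-in transition table. One hospitalization is averted for
every 6.3 patients treated for the decade.

Sensitivity, scenarios, microsimulation:

```r
run_dsa(config)                              # tornado table
run_psa(config, n_iter = 10000, seed = 1)    # scatter, CEAC, intervals
run_scenario("horizon_4y", config)
log <- simulate_patients(build_arm_tables(config, "UCG"), n = 50000, seed = 1)
estimate_transition_table(log)               # ML recovery from event logs
```

A command-line driver ships at `inst/cli/hfcea`
(`hfcea run --config pack.yaml --out results/`, plus `dsa`, `psa`,
`scenario`, `simulate`, `validate` subcommands).

## Acceptance script

`scripts/acceptance.R` reruns the whole pipeline from scratch against the
installed package — base case, DSA, a 2000-iteration PSA, all runnable
scenarios, and a microsimulation parameter-recovery cross-check — and
writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
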