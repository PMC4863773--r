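# Default parameter pack: eplerenone vs usual care, NYHA Class II chronic
# heart failure, Australian healthcare system perspective, 2014 AUD.
#
# The transition table (CSV-referenced below) and the age trend are SYNTHETIC
# STAND-INS: the published usual-care transition table and life-table appendix
# are available only as figures, so plausible magnitudes were chosen once and
# frozen. Replace the CSV and the age_trend block with transcribed values for
# exact reproduction of the published analysis.
model:
  horizon: 10
  start_state: II
  cohort_size: 1000
  hr_mode: cv-only
  accrual: cycle-start
  trend_order: trend-first
  monitor_year1_combined: false
transition_table:
  provenance: weighted-average
  csv: transitions_usual_care_synthetic.csv
hazard_ratios:          # point, 95% CI lo, hi (eplerenone vs placebo)
  hf_hosp: [0.58, 0.47, 0.70]
  cv_death: [0.76, 0.61, 0.94]
  all_cause_death: [0.76, 0.62, 0.93]
mixture:                # fraction of usual care on spironolactone, per class
  I: 0.0
  II: 0.437
  III: 0.937
  IV: 0.937
utilities:
  I: 0.815
  II: 0.720
  III: 0.590
  IV: 0.508
costs:                  # 2014 AUD
  background_annual: {I: 151.0, II: 175.0, III: 226.0, IV: 242.0}
  hf_hosp_event: 7136.0
  cvd_death_admission: 3642.0
  death_in_hospital_fraction: 0.5
  eplerenone_annual: 1374.0
  epl_monitor_first_cycle: 35.60
  epl_monitor_annual: 71.20
  spiro_annual: 45.29
  spiro_monitor_annual: 71.20
  hosp_events_per_cycle_cap: 1
discount:
  rate: 0.05
  start_cycle: 2        # "after the first cycle"
age_trend:              # synthetic stand-in: exponential growth of death risk
  baseline_age: 68
  growth: 0.087         # per year of age; risk doubles roughly every 8 years
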