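# Default configuration for the DDH ultrasound screening scenario experiment.
# All values are the study defaults (2006 euros); any key may be overridden.

population:
  cohort_size: 2300          # children invited over the programme horizon
  horizon_months: 18
  prevalence: 0.038          # treatable DDH among screened children (TP 3.2% + missed 0.6%)
  graf_mix:                  # renormalized to the prevalence (printed rows sum to 3.4%)
    TYPE_2BC: 0.014
    TYPE_D: 0.015
    TYPE_34: 0.005
  urban_share: 0.6666666666666666  # two of three participating organizations urban/suburban
  attendance: {URBAN: 0.85, RURAL: 0.90}
  reattendance: {URBAN: 0.80, RURAL: 0.90}   # after one reminder
  prescreen_referral: 0.0061 # referred at the first consultation
  prescreen_treated: 0.0031  # treated before ultrasound screening; leave the cohort
  distance_km_range: [4, 7]  # travel to the IHC, km (external locations: 10)

costs:
  wage_physician: 75         # EUR per hour
  wage_nurse: 42
  wage_rt: 70
  wage_specialist: 106
  hospital_us_per_hour: 61   # ultrasound use at hospital, per hour
  parent_time_per_hour: 36   # parents' productivity loss
  km_rate: 0.20
  external_distance_km: 10
  machine_price: 32725
  machine_insurance_per_year: 1000
  maintenance_fraction: 0.08 # of the purchase price, per year
  machine_life_years: 5
  interest_rate: 0.05
  exam_minutes: 10
  training_hours: 16
  training_wage: 73
  training_materials: 130
  training_cost_per_screener: 1300  # rounded 16 h x 73 + 130 = 1298
  evening_uplift: 0.35       # wage uplift for evening sessions
  evening_flat_fee: false    # charge a flat fee per child instead of the uplift
  evening_flat_per_child: 5
  treat_first_consult: 571   # treatment after early first consultation
  treat_2bc: 897
  treat_D: 717
  treat_34: 2043
  missed_case_cost: 1217
  fp_visit_cost: 97          # one hospital visit (61) + parent absence (36)
  rent_per_child_external: 5 # not printed in the source tables; configurable

n_reps: 100
seed: 1
n_sites: 7                   # IHC sites served when machines = MANY
mode: SIMULATE               # or EXPECTED (deterministic closed form)

# One-way sensitivity sweeps (run in EXPECTED mode), e.g.:
# sensitivity:
#   - param: rent_per_child_external
#     values: [0, 5, 20]
sensitivity: []
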