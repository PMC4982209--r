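# Illustrative unit-cost table, 2012 GBP. The national reference-cost,
# formulary and PSSRU sources behind the original analysis are not
# redistributable, so these values are stand-ins with a realistic scale:
# organ-support day costs follow the tiered critical-care schedule shape,
# and the post-ICU ward day (297) is anchored to the published daily
# quartile. Replace freely via default_unit_costs(file=).
base_year: 2012
hchs_index:
  "2010": 267.5
  "2011": 273.9
  "2012": 280.3
cost_per_organ_day:
  "0": 856
  "1": 1325
  "2": 1710
  "3": 2106
  "4": 2521
  "5": 3041
  "6": 3560
rrt_cost: 185
xray_cost: 28
chest_drain_cost: 116
drug_costs:
  antibiotic: 12.5
  sedative: 6.4
  muscle_relaxant: 9.8
vent_machine_price: 18250
vent_machine_life_years: 5
vent_annual_maintenance: 1250
vent_utilisation_days: 365
vent_circuit_cost: 14.5
stepdown_cost_per_day:
  ward: 297
  hdu: 1476
  icu: 1738
transfer_cost: 296
sae_costs:
  pneumothorax: 1890
  other: 450
visit_costs:
  gp: 45
  outpatient: 135
  community: 52
inpatient_cost_per_day: 305
aids_costs:
  wheelchair: 220
  walking_frame: 40
  home_adaptation: 1200
  other: 75
petrol_rate: 0.45
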