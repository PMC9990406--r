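# Example cost book (euro, indicative prices; redefine for your situation).
# Fields per measure: implementation_cost (one-off), lifetime_years
# (straight-line depreciation), operational_cost (per year), scaling
# (fixed | per_animal | per_round | per_stable), scale_rate (euro per unit).

# Moving from multi-step to one-step depopulation carries no equipment cost;
# the yearly figure is the assumed foregone revenue from farming fewer
# broilers per round.
one_step_depopulation:
  implementation_cost: 0
  lifetime_years: 1
  operational_cost: 7000.00
  scaling: fixed

# Dedicated sealed storage and disinfection routine for incoming material.
material_supply_preventive_measures:
  implementation_cost: 2500.00
  lifetime_years: 5
  operational_cost: 700.00
  scaling: fixed

# Colour-coded clothing and boots kept per stable; charged per animal house.
stable_specific_clothing:
  implementation_cost: 0
  lifetime_years: 1
  operational_cost: 0
  scaling: per_stable
  scale_rate: 222.435

# Anteroom with bench, hand-wash station and clothing change.
hygiene_lock:
  implementation_cost: 4000.00
  lifetime_years: 10
  operational_cost: 250.00
  scaling: fixed

# Full disconnection and cleaning of the drinking-water system per round.
water_system_disconnection:
  implementation_cost: 300.00
  lifetime_years: 5
  operational_cost: 0
  scaling: per_round
  scale_rate: 35.00

# Visitor registration book and signage.
visitor_check_in:
  implementation_cost: 150.00
  lifetime_years: 5
  operational_cost: 10.00
  scaling: fixed
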