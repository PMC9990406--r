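# Expected biological direction of each measure's association with AMU:
#   protective - applying the measure should reduce usage
#   risky      - applying the measure should increase usage
#   unclear    - no defensible expectation; never proposed as intervention
# Measures whose estimated association contradicts the expectation are kept
# as predictors but excluded from intervention plans (cross-sectional data
# cannot rule out reverse causality).

hygiene_lock: protective
stable_specific_clothing: protective
material_storage_per_stable: protective
material_supply_preventive_measures: protective
water_system_disconnection: protective
hand_washing_before_entry: protective
two_plus_depopulation_steps: risky
visitor_check_in: unclear
vaccination_protocol_non_official: unclear
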