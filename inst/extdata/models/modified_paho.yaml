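# Modified PAHO model: the PAHO nutrient criteria (identical thresholds,
# including the NNS presence criterion) with the Chilean added-ingredient
# eligibility rule (added sugar, salt or fat keywords) in place of the
# NOVA processing requirement.
name: modified_paho
eligibility: added_critical_ingredient
energy_conversion:
  sugar_kcal_per_g: 4
  fat_kcal_per_g: 9
criteria:
  - id: free_sugars
    nutrient: free_sugars
    metric: energy_ratio
    kcal_per_g: 4
    threshold: 0.10
    applies_to: both
  - id: total_fat
    nutrient: total_fat_g
    metric: energy_ratio
    kcal_per_g: 9
    threshold: 0.30
    applies_to: both
  - id: sat_fat
    nutrient: sat_fat_g
    metric: energy_ratio
    kcal_per_g: 9
    threshold: 0.10
    applies_to: both
  - id: trans_fat
    nutrient: trans_fat_g
    metric: energy_ratio
    kcal_per_g: 9
    threshold: 0.01
    applies_to: both
  - id: sodium
    nutrient: sodium_mg
    metric: per_energy
    threshold: 1.0
    applies_to: both
  - id: nns
    nutrient: nns
    metric: presence
    applies_to: both
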