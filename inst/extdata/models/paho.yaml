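# PAHO nutrient profiling model.
#
# Eligibility: NOVA processed (3) or ultra-processed (4) products only.
# Criteria are nutrient-to-energy ratios (WHO population nutrient goals):
# energy from free sugars >= 10 % of total energy, from total fats >= 30 %,
# from saturated fats >= 10 %, from trans fats >= 1 %; sodium >= 1 mg per
# kcal; and presence of non-nutritive sweeteners in the ingredient list.
# Energy conversion: 4 kcal/g for sugars, 9 kcal/g for fats (Atwater).
name: paho
eligibility: nova_processed_or_ultraprocessed
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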