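# Chilean FOP warning-label model (Law 20.606, final-phase limits).
#
# Eligibility: only products with ADDED sugar, salt or fat (ingredient-list
# keywords) can receive warnings, however high their intrinsic content.
# Criteria are absolute contents per 100 g (solids) / 100 ml (liquids).
# Culinary ingredients (sugar, salt, oils, butter, milk creams) are
# eligible only when a critical nutrient OTHER than their defining one has
# been added, and never receive a warning for the defining nutrient.
name: chile
eligibility: added_critical_ingredient
criteria:
  - id: energy
    nutrient: energy_kcal
    metric: per_100
    threshold_solid: 275
    threshold_liquid: 70
    applies_to: both
  - id: sugars
    nutrient: total_sugars_g
    metric: per_100
    threshold_solid: 10
    threshold_liquid: 5
    applies_to: both
  - id: sat_fat
    nutrient: sat_fat_g
    metric: per_100
    threshold_solid: 4
    threshold_liquid: 3
    applies_to: both
  - id: sodium
    nutrient: sodium_mg
    metric: per_100
    threshold_solid: 400
    threshold_liquid: 100
    applies_to: both
culinary:
  - category: table_sugar
    defining: added_sugar
    masks: [sugars, energy]
  - category: table_salt
    defining: added_salt
    masks: [sodium]
  - category: oils_fats
    defining: added_fat
    masks: [sat_fat, energy]
  - category: butter_cream
    defining: added_fat
    masks: [sat_fat, energy]
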