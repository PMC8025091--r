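# Nutrient profiling model proposed by Anvisa (2018 preliminary proposal
# for the Brazilian FOP labelling regulation).
#
# Eligibility: all products except the listed categories (sugars, salts,
# vinegars, herbs, coffees, frozen fruits and vegetables, frozen/chilled
# meats, baby foods, foods for special dietary uses).
# Criteria: free sugars, saturated fat and sodium per 100 g / 100 ml.
name: anvisa
eligibility: category_exclusion_list
category_exclusions:
  - table_sugar
  - table_salt
  - vinegars
  - herbs_spices
  - coffees
  - frozen_fruits_vegetables
  - frozen_chilled_meats
  - baby_foods
  - special_dietary_foods
criteria:
  - id: free_sugars
    nutrient: free_sugars
    metric: per_100
    threshold_solid: 10
    threshold_liquid: 5
    applies_to: both
  - id: sat_fat
    nutrient: sat_fat_g
    metric: per_100
    threshold_solid: 4
    threshold_liquid: 2
    applies_to: both
  - id: sodium
    nutrient: sodium_mg
    metric: per_100
    threshold_solid: 400
    threshold_liquid: 200
    applies_to: both
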