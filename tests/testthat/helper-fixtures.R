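# In-code fixtures: single products and small tables built per test.

make_product <- function(product_id = "p1",
                         category = "cookies",
                         basis = "solid",
                         energy_kj = NA_real_,
                         energy_kcal = 400,
                         total_sugars_g = NA_real_,
                         added_sugars_g = NA_real_,
                         total_fat_g = 15,
                         sat_fat_g = 6,
                         trans_fat_g = 0,
                         sodium_mg = 300,
                         fibre_g = NA_real_,
                         ingredient_text = "farinha de trigo, acucar, oleo de soja, sal",
                         serving_size = 30,
                         reconstitution_factor = NA_real_,
                         nova_class = 4L,
                         defects = list(character(0)),
                         as_consumed = FALSE) {
  tibble::tibble(
    product_id = product_id, category = category, basis = basis,
    energy_kj = energy_kj, energy_kcal = energy_kcal,
    total_sugars_g = total_sugars_g, added_sugars_g = added_sugars_g,
    total_fat_g = total_fat_g, sat_fat_g = sat_fat_g,
    trans_fat_g = trans_fat_g, sodium_mg = sodium_mg, fibre_g = fibre_g,
    ingredient_text = ingredient_text, serving_size = serving_size,
    reconstitution_factor = reconstitution_factor, nova_class = nova_class,
    defects = defects, as_consumed = as_consumed
  )
}

# The reduced-sugar beverage discussed with the models: 4.5 g sugars and
# 75 kJ (18 kcal) per 100 ml, ultra-processed, sweetened with sugar.
make_reduced_sugar_beverage <- function() {
  make_product(
    product_id = "bev", category = "sweetened_beverages", basis = "liquid",
    energy_kj = 75, energy_kcal = NA_real_, total_sugars_g = 4.5,
    total_fat_g = 0, sat_fat_g = 0, trans_fat_g = 0, sodium_mg = 10,
    ingredient_text = "água, açúcar, aroma natural",
    serving_size = 350, nova_class = 4L
  )
}

# Brute-force Cohen's kappa from raw outcome vectors (independent of the
# 2x2 closed form): observed agreement minus chance agreement from the
# empirical margins.
kappa_oracle <- function(a, b) {
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

classify_with <- function(products, model) {
  findings <- scan_products(products)
  fs <- estimate_free_sugars(products, findings)
  classify_products(products, npm_config(model), findings, fs)
}
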