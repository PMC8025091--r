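# The four warning-label classifiers: eligibility, criteria, edge rules.

test_that("low-energy sugary beverage: flagged by the energy-ratio model, not by per-100 cutoffs", {
  bev <- make_reduced_sugar_beverage()
  findings <- scan_products(bev)
  fs <- estimate_free_sugars(bev, findings)
  expect_equal(fs, 4.5)  # minimal natural sugars: all declared sugars free

  paho <- classify_paho(bev, findings, fs)
  # 4.5 g x 4 kcal/g = 18 kcal of sugar against ~18 kcal total: 100 % >= 10 %
  expect_equal(paho$crit_free_sugars, "excessive")
  expect_true(paho$any_warning)

  anvisa <- classify_anvisa(bev, findings, fs)
  # 4.5 g/100 ml is under the 5 g/100 ml liquid cutoff
  expect_equal(anvisa$crit_free_sugars, "not_excessive")
  expect_false(isTRUE(anvisa$any_warning))
})

test_that("PAHO eligibility follows the NOVA class", {
  bev <- make_reduced_sugar_beverage()
  bev$nova_class <- 1L
  res <- classify_with(bev, "paho")
  expect_false(res$eligible)
  expect_false(res$any_warning)
  expect_true(all(unlist(res[, grep("^crit_", names(res))]) == "not_applicable"))

  bev$nova_class <- NA_integer_
  res_na <- classify_with(bev, "paho")
  expect_true(is.na(res_na$eligible))
  expect_true(is.na(res_na$any_warning))
})

test_that("NNS presence alone triggers a PAHO warning", {
  p <- make_product("nns1", category = "sweetened_beverages", basis = "liquid",
                    energy_kcal = 0, total_sugars_g = 0, total_fat_g = 0,
                    sat_fat_g = 0, trans_fat_g = 0, sodium_mg = 0,
                    ingredient_text = "água, sucralose", nova_class = 4L)
  res <- classify_with(p, "paho")
  expect_equal(res$crit_nns, "excessive")
  expect_true(res$any_warning)
})

test_that("an eligible all-zero panel gets zero flags", {
  p <- make_product("z1", category = "canned_vegetables", energy_kcal = 0,
                    total_sugars_g = 0, total_fat_g = 0, sat_fat_g = 0,
                    trans_fat_g = 0, sodium_mg = 0,
                    ingredient_text = "agua, hortaliças", nova_class = 3L)
  res <- classify_with(p, "paho")
  expect_true(res$eligible)
  expect_false(res$any_warning)
  expect_true(all(unlist(res[, grep("^crit_", names(res))]) == "not_excessive"))
})

test_that("Chilean eligibility requires an added critical ingredient", {
  # high intrinsic sodium but nothing added: ineligible, no warnings
  p <- make_product("ch1", category = "cheeses", sodium_mg = 900,
                    sat_fat_g = 15, total_fat_g = 25,
                    ingredient_text = "leite, coalho, fermento")
  res <- classify_with(p, "chile")
  expect_false(res$eligible)
  expect_false(res$any_warning)
})

test_that("culinary rule: salted butter is labelled for sodium but never for fat", {
  butter <- make_product("bt1", category = "butter_cream", basis = "solid",
                         energy_kcal = 720, total_fat_g = 80, sat_fat_g = 50,
                         trans_fat_g = 0, sodium_mg = 600,
                         total_sugars_g = 0,
                         ingredient_text = "creme de leite, sal")
  res <- classify_with(butter, "chile")
  expect_true(res$eligible)          # another critical nutrient (salt) added
  expect_equal(res$crit_sodium, "excessive")
  expect_equal(res$crit_sat_fat, "not_applicable")
  expect_equal(res$crit_energy, "not_applicable")
  expect_true(res$any_warning)

  unsalted <- butter
  unsalted$ingredient_text <- "creme de leite"
  res2 <- classify_with(unsalted, "chile")
  expect_false(res2$eligible)        # only its defining nutrient
  expect_false(res2$any_warning)
})

test_that("Chilean liquid sugar cutoff applies per 100 ml", {
  p <- make_product("ch2", category = "sweetened_beverages", basis = "liquid",
                    energy_kcal = 44, total_sugars_g = 6, total_fat_g = 0,
                    sat_fat_g = 0, sodium_mg = 10,
                    ingredient_text = "água, açúcar")
  res <- classify_with(p, "chile")
  expect_equal(res$crit_sugars, "excessive")
  expect_true(res$any_warning)
})

test_that("Anvisa excludes listed categories regardless of panel", {
  p <- make_product("vn1", category = "vinegars", basis = "liquid",
                    sodium_mg = 5000, sat_fat_g = 50, total_fat_g = 60,
                    ingredient_text = "vinagre de álcool")
  res <- classify_with(p, "anvisa")
  expect_false(res$eligible)
  expect_equal(res$reason, "excluded_category")
  expect_false(res$any_warning)
})

test_that("Anvisa flags a solid above the saturated-fat cutoff", {
  p <- make_product("sf1", category = "cookies", sat_fat_g = 4.5,
                    total_fat_g = 10, total_sugars_g = 1, sodium_mg = 50,
                    ingredient_text = "farinha, gordura vegetal")
  res <- classify_with(p, "anvisa")
  expect_equal(res$crit_sat_fat, "excessive")
  expect_true(res$any_warning)
})

test_that("modified PAHO keeps PAHO flags but uses added-ingredient eligibility", {
  # eligible under both: identical per-criterion flags
  p <- make_product("mp1", category = "cookies", energy_kcal = 450,
                    total_sugars_g = 25, total_fat_g = 18, sat_fat_g = 8,
                    trans_fat_g = 0.5, sodium_mg = 400,
                    ingredient_text = "farinha, açúcar, gordura vegetal, sal",
                    nova_class = 4L)
  paho <- classify_with(p, "paho")
  modified <- classify_with(p, "modified_paho")
  crit_cols <- grep("^crit_", names(paho), value = TRUE)
  expect_equal(modified[, crit_cols], paho[, crit_cols])
  expect_equal(modified$any_warning, paho$any_warning)

  # ultra-processed but nothing added: PAHO-eligible, modified ineligible
  q <- make_product("mp2", category = "plain_dairy", basis = "liquid",
                    energy_kcal = 60, total_sugars_g = 4.8, total_fat_g = 3,
                    sat_fat_g = 2, sodium_mg = 50,
                    ingredient_text = "leite integral", nova_class = 4L)
  expect_true(classify_with(q, "paho")$eligible)
  expect_false(classify_with(q, "modified_paho")$eligible)
})

test_that("PAHO and modified PAHO agree exactly on jointly eligible products", {
  sup <- generate_supply(supply_spec(n = 1500, seed = 31))
  findings <- scan_products(sup$products)
  fs <- estimate_free_sugars(sup$products, findings)
  paho <- classify_products(sup$products, npm_config("paho"), findings, fs)
  modified <- classify_products(sup$products, npm_config("modified_paho"),
                                findings, fs)
  both <- which(paho$eligible %in% TRUE & modified$eligible %in% TRUE)
  expect_gt(length(both), 100)
  crit_cols <- grep("^crit_", names(paho), value = TRUE)
  expect_equal(modified[both, crit_cols], paho[both, crit_cols])
  expect_identical(modified$any_warning[both], paho$any_warning[both])
})

test_that("thresholds are inclusive: at the cutoff flags, a hair below does not", {
  eps <- 1e-9
  # per-100 metric (Chilean liquid sugar cutoff, 5 g/100 ml)
  at <- make_product("b1", category = "sweetened_beverages", basis = "liquid",
                     energy_kcal = 40, total_sugars_g = 5, total_fat_g = 0,
                     sat_fat_g = 0, sodium_mg = 10,
                     ingredient_text = "água, açúcar")
  below <- at
  below$total_sugars_g <- 5 - eps
  expect_equal(classify_with(at, "chile")$crit_sugars, "excessive")
  expect_equal(classify_with(below, "chile")$crit_sugars, "not_excessive")

  # energy-ratio metric (PAHO free sugars, 10 % of energy): 2.5 g x 4 / 100
  at2 <- make_product("b2", category = "sweetened_beverages", basis = "liquid",
                      energy_kcal = 100, total_sugars_g = 2.5, total_fat_g = 0,
                      sat_fat_g = 0, trans_fat_g = 0, sodium_mg = 10,
                      ingredient_text = "água, açúcar", nova_class = 4L)
  below2 <- at2
  below2$total_sugars_g <- 2.5 - eps
  expect_equal(classify_with(at2, "paho")$crit_free_sugars, "excessive")
  expect_equal(classify_with(below2, "paho")$crit_free_sugars, "not_excessive")
})

test_that("criteria are monotone in the nutrient at fixed energy", {
  set.seed(88)
  for (model in c("paho", "chile", "anvisa")) {
    sodium_grid <- sort(runif(8, 0, 1500))
    p <- make_product(sprintf("mn%02d", seq_along(sodium_grid)),
                      category = "convenience_foods", energy_kcal = 200,
                      total_sugars_g = 2, total_fat_g = 5, sat_fat_g = 2,
                      trans_fat_g = 0,
                      ingredient_text = "arroz, sal, óleo de soja",
                      nova_class = 4L)
    p$sodium_mg <- sodium_grid
    res <- classify_with(p, model)
    flagged <- res$crit_sodium == "excessive"
    expect_true(all(diff(flagged) >= 0),
                info = paste("sodium flag not monotone under", model))
  }
})

test_that("any warning implies eligibility; flag count respects the config", {
  sup <- generate_supply(supply_spec(n = 800, seed = 91))
  for (model in c("paho", "chile", "anvisa", "modified_paho")) {
    res <- classify_with(sup$products, model)
    expect_true(all(res$eligible[which(res$any_warning)]))
    expect_true(all(res$n_criteria_evaluated <=
                      length(npm_config(model)$criteria)))
  }
})

test_that("indeterminate free sugars leave other criteria untouched", {
  p <- make_product("ind1", category = "cookies", energy_kcal = 450,
                    total_sugars_g = NA_real_, total_fat_g = 18, sat_fat_g = 8,
                    trans_fat_g = 0, sodium_mg = 400,
                    ingredient_text = "farinha, açúcar, sal", nova_class = 4L)
  res <- classify_with(p, "paho")
  expect_equal(res$crit_free_sugars, "indeterminate")
  expect_equal(res$crit_total_fat, "excessive")   # 18 x 9 / 450 = 36 %
  expect_true(res$any_warning)

  # when no other criterion fires, the overall outcome is indeterminate
  q <- make_product("ind2", category = "cookies", energy_kcal = 450,
                    total_sugars_g = NA_real_, total_fat_g = 1, sat_fat_g = 0.5,
                    trans_fat_g = 0, sodium_mg = 10,
                    ingredient_text = "farinha, açúcar", nova_class = 4L)
  res_q <- classify_with(q, "paho")
  expect_equal(res_q$crit_free_sugars, "indeterminate")
  expect_true(is.na(res_q$any_warning))
})

test_that("missing basis errors for per-100 models; missing energy for PAHO", {
  p <- make_product("e1", category = "cookies", basis = NA_character_,
                    ingredient_text = "farinha, sal")
  expect_error(classify_with(p, "anvisa"), "basis")
  q <- make_product("e2", energy_kcal = NA_real_, energy_kj = NA_real_,
                    total_sugars_g = 0)
  expect_error(classify_with(q, "paho"), "energy")
})

test_that("config validation rejects malformed models", {
  cfg <- npm_config("chile")
  bad <- unclass(cfg)
  bad$criteria[[1]]$threshold_solid <- -5
  expect_error(validate_model_config(bad), "> 0")
  bad2 <- unclass(cfg)
  bad2$criteria[[2]]$id <- bad2$criteria[[1]]$id
  expect_error(validate_model_config(bad2), "duplicate")
  bad3 <- unclass(cfg)
  bad3$eligibility <- "whatever"
  expect_error(validate_model_config(bad3), "eligibility")
})
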