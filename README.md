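# npmcompare

Compare the nutrient profiling models (NPMs) behind front-of-package (FOP)
warning-label policies, applied to a packaged-food database.

Regulators in Latin America use rule systems — nutrient profiling models —
to decide which packaged foods must carry "high in" warning labels. The
models differ in three ways that matter for policy: *eligibility* (which
products can be labelled at all), *which nutrients* are assessed, and
*how thresholds are expressed* (nutrient-to-energy ratios versus absolute
content per 100 g/ml). `npmcompare` implements four such classifiers and
the statistics used to compare them across a food supply:

* **PAHO**: only NOVA processed/ultra-processed foods are eligible;
  criteria are energy ratios — energy from free sugars ≥ 10 % of total
  energy, total fats ≥ 30 %, saturated fats ≥ 10 %, trans fats ≥ 1 %,
  sodium ≥ 1 mg/kcal — plus the presence of non-nutritive sweeteners
  (NNS) in the ingredient list.
* **Chile** (Law 20.606): only products with *added* sugar, salt or fat
  (detected by ingredient-list keywords) are eligible; criteria are
  per-100 g/ml cutoffs for energy, total sugars, saturated fat and
  sodium, with a culinary-ingredient rule (butter is never labelled for
  fat, only for another nutrient added in excess).
* **Anvisa** (proposed for Brazil): everything is eligible except a list
  of excluded categories (sugars, salts, vinegars, herbs, coffees,
  frozen produce and meats, baby and special-dietary foods); criteria
  are per-100 g/ml cutoffs for free sugars, saturated fat and sodium.
* **modified PAHO**: PAHO's criteria under Chile's eligibility rule.

Around the classifiers the package provides the full working apparatus:
database cleaning filters with reconciled exclusion tallies,
reconstitution of powdered/concentrated products to their as-consumed
form, Portuguese ingredient-list keyword scanning (whole-token matching
with wildcard stems), free-sugar estimation from declared sugars by
category rules, and a synthetic food-supply generator with planted
ground truth so that the whole pipeline is testable end to end.

A model's **strictness** is the share of products it flags,
p̂ = k/n with the Wald interval p̂ ± 1.96·√(p̂(1−p̂)/n). Agreement
between two models is the 2×2 cross-classification and **Cohen's
kappa**, κ = (p₀ − pₑ)/(1 − pₑ), with the usual interpretation bands
(0.01–0.20 slight … 0.81–1.00 almost perfect) and an explicit
"undefined" sentinel when a margin of the table is empty.

## Worked example

A reduced-sugar beverage sold in Brazil: 4.5 g of sugars and 75 kJ
(18 kcal) per 100 ml, ultra-processed, sweetened with sugar.

```r
library(npmcompare)

bev <- tibble::tibble(
  product_id = "bebida-01", category = "sweetened_beverages", basis = "liquid",
  energy_kj = 75, energy_kcal = NA_real_, total_sugars_g = 4.5,
  added_sugars_g = NA_real_, total_fat_g = 0, sat_fat_g = 0, trans_fat_g = 0,
  sodium_mg = 10, fibre_g = NA_real_,
  ingredient_text = "água, açúcar, aroma natural", serving_size = 350,
  reconstitution_factor = NA_real_, nova_class = 4L,
  defects = list(character(0)), as_consumed = FALSE)

findings <- scan_products(bev)            # has_added_sugar: TRUE
fs <- estimate_free_sugars(bev, findings) # 4.5 (all declared sugars are free)

classify_paho(bev, findings, fs)[, c("eligible", "crit_free_sugars", "any_warning")]
#>   eligible crit_free_sugars any_warning
#> 1 TRUE     excessive        TRUE
classify_anvisa(bev, findings, fs)[, c("eligible", "crit_free_sugars", "any_warning")]
#>   eligible crit_free_sugars any_warning
#> 1 TRUE     not_excessive    FALSE

daily_limit_share(fs, serving_size = 350, daily_limit = 50)
#> [1] 31.5
```

The two models disagree for a reason worth seeing in numbers: under
PAHO, the sugar *energy* (4.5 g × 4 kcal/g = 18 kcal) is 100 % of the
product's energy — far above the 10 % ratio cutoff — so the beverage is
flagged; under Anvisa, 4.5 g/100 ml sits below the 5 g/100 ml volumetric
cutoff, so it is not, even though one 350 ml serving delivers 31.5 % of
a 50 g daily sugar limit.

Supply-level comparison on a generated database:

```r
sup <- generate_supply(supply_spec(n = 5000, seed = 2024))
run <- run_compare(sup$products, by_category = FALSE)
format_report(run)
#> Strictness (overall):
#>   paho            87.1% (95% CI 86.1, 88.1)  n=4315
#>   chile           86.7% (95% CI 85.7, 87.8)  n=3949
#>   anvisa          95.8% (95% CI 95.1, 96.5)  n=3047
#>   modified_paho   89.4% (95% CI 88.5, 90.3)  n=4304
#> Agreement (any warning):
#>   paho           vs chile          kappa  0.59 (moderate)
#>   paho           vs anvisa         kappa  0.08 (slight)
#>   paho           vs modified_paho  kappa  0.60 (substantial)
#>   chile          vs anvisa         kappa  0.40 (moderate)
#>   chile          vs modified_paho  kappa  0.91 (almost perfect or perfect)
#>   anvisa         vs modified_paho  kappa  0.09 (slight)
```

`n` varies by model because products whose outcome cannot be determined
(typically: eligible, nothing else in excess, and no declared sugar
information — only ~10 % of products declare sugars) are excluded from
that model's denominator and reported separately in the run manifest.

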