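---
title: "Comparing warning-label nutrient profiling models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing warning-label nutrient profiling models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmcompare)
```

# The problem

Front-of-package (FOP) warning-label policies need a rule system — a
nutrient profiling model (NPM) — that decides, product by product, which
foods are "high in" critical nutrients. Different NPMs embody different
regulatory philosophies, and the practical question for a country
designing a policy is how differently they carve up the same food
supply. `npmcompare` answers that question operationally: it applies
four classifiers to a packaged-food table and quantifies their
strictness and pairwise agreement, overall and by food category.

Every model decomposes into the same three pieces, which is how the
package represents them (one YAML `model_config` per model, read by a
single criteria engine):

1. **Eligibility** — may this product carry warnings at all?
   Four rule ids exist: `nova_processed_or_ultraprocessed` (PAHO),
   `added_critical_ingredient` (Chile and the modified PAHO model:
   added sugar, salt or fat found in the ingredient list),
   `category_exclusion_list` (Anvisa) and `always`.
2. **Criteria** — one per nutrient, each with a metric
   (`energy_ratio`, `per_energy`, `per_100`, `presence`), a threshold
   (single or solid/liquid pair) and the Atwater conversion factors
   where energy ratios are involved (4 kcal/g for sugars, 9 kcal/g for
   fats, documented in the config).
3. **Category machinery** — Anvisa's exclusion list and Chile's
   culinary-ingredient rule (a staple such as butter is eligible only
   when a critical nutrient *other* than its defining one has been
   added, and its defining nutrient's criteria are masked).

A criterion evaluates to `excessive`, `not_excessive`, `indeterminate`
(the nutrient value is missing) or `not_applicable` (product ineligible
or criterion masked). The overall outcome `any_warning` is `TRUE` iff
the product is eligible and at least one criterion is excessive;
`FALSE` for ineligible products; `NA` when the outcome genuinely cannot
be determined — an eligible product with nothing in excess but an
unresolved criterion, or eligibility itself unresolved (a missing NOVA
class under PAHO).

# Threshold provenance

The PAHO cutoffs are the model's published nutrient-to-energy limits
(free sugars ≥ 10 % of energy, total fats ≥ 30 %, saturated fats
≥ 10 %, trans fats ≥ 1 %, sodium ≥ 1 mg/kcal, NNS by presence); they
are corroborated by the worked beverage example in the README, where a
product deriving all of its 18 kcal from sugar must be flagged.

The shipped Chilean config transcribes Law 20.606's definitive
(final-phase, 2019) limits: solids 275 kcal, 10 g sugars, 4 g saturated
fat, 400 mg sodium per 100 g; liquids 70 kcal, 5 g, 3 g, 100 mg per
100 ml. The law phases in progressively looser-to-stricter cutoffs; we
chose the final phase as the policy's steady state. The law defines no
total-fat cutoff, so the default config carries the four criteria
above; the YAML schema accepts additional criteria if a user wants to
assess total fats with a cutoff of their choosing.

The Anvisa config follows the agency's 2018 preliminary proposal:
free sugars 10 g / 5 g, saturated fat 4 g / 2 g, sodium 400 mg / 200 mg
per 100 g (solids) / 100 ml (liquids). All cutoffs are configuration,
never code: `npm_config()` accepts a path to a user YAML, and
`validate_model_config()` enforces the schema (positive thresholds,
unique criterion ids, known metrics).

Comparisons are **inclusive** (≥) at every threshold: a product exactly
at a cutoff is flagged, one at cutoff − ε is not. The tests pin this at
ε = 10⁻⁹ of the unit.

# Ingredient scanning

Detection of added sugar, salt, fat and non-nutritive sweeteners is a
keyword search over the Portuguese ingredient list. Text is normalized
(lowercase, accents stripped, punctuation → spaces) and terms match
**whole tokens** — substring matching is wrong in Portuguese ("sal"
inside "salsa", "massas" vs "passas") — with an explicit `*` wildcard
for stems ("xarope*" catches plurals) and multi-word terms matched as
token sequences. The shipped vocabulary renders the usual keyword
families in Portuguese and is user-replaceable YAML; negation phrases
("sem adição de açúcar") are a hook that ships empty, because the
detection method being modelled is a plain keyword search. Every match
is reported with its keyword and character offset for audit.

# Free sugars

Brazilian labels do not declare free sugars, so they are estimated:

* declared added sugars, when present, are used directly;
* otherwise declared total sugars × a category fraction — 1.0 for
  categories with no or minimal naturally occurring sugars (sodas,
  sports drinks, candies), 0.5 for milk/yogurt *gated on* an
  added-sugar keyword (lactose is not a free sugar), and for unlisted
  categories a default of 1.0 with a keyword and 0.0 without;
* neither declared → indeterminate (`NA`).

The 50 % dairy fraction is applied to the declared total-sugars value
by default. One could argue it should apply to an added-sugars figure
instead; since labels rarely provide one, we default to the total-sugar
reading and expose `basis: "added"` in the rule YAML as the alternative.
Only about one product in ten declares sugars at all, so sugar criteria
are evaluated on that sub-sample and products indeterminate overall are
excluded from denominators (and counted in the run manifest).

# Comparison statistics

Strictness is p̂ = k/n over products with a determinable outcome, with
the Wald interval p̂ ± 1.96·√(p̂(1−p̂)/n) clipped to [0, 1]. The Wald
form with the conventional 1.96 multiplier is the estimator whose
printed intervals we reproduce in closed form in the tests (e.g.
p̂ = 0.622 at n = 11 434 → 61.3–63.1 %); a Wilson option exists behind
`method = "wilson"`. Agreement is the 2×2 cross-classification over
pairwise-determinable products and Cohen's κ = (p₀ − pₑ)/(1 − pₑ),
with pₑ from the table margins. κ is reported as undefined — not 0,
not 1 — whenever a margin of the table is empty or pₑ = 1, and the
interpretation bands (slight/fair/moderate/substantial/almost perfect,
upper bounds inclusive) label the defined values. Ineligible products
count as "no warning" in both strictness denominators and agreement
tables: supply-level percentages are over all classifiable products, so
eligibility differences between models are part of the disagreement
being measured, which is the policy-relevant comparison. No hypothesis
tests or multiplicity corrections are applied; these are descriptive
supply statistics. A large-sample kappa standard error
(`cohen_kappa_se()`) is available but unused in default reports.

# The synthetic supply

The study design this package supports uses proprietary supermarket
data, so validation rests on a generator
(`generate_supply(supply_spec(...))`) that emulates the *structure*
such data presents to the analysis:

* 12 food categories with realistic shares and per-category log-normal
  nutrient distributions (right-skewed, non-negative, truncated at
  physiological maxima: 900 kcal, 100 g fat or sugar, 4 g sodium per
  100 g), with composition constraints enforced (saturated and trans
  fat within total fat; fat and sugar energy within declared energy);
* planted keyword flags per category (e.g. nearly all cookies contain
  added sugar and fat; NNS probabilities concentrated in beverages and
  cereals so overall prevalence lands near one product in ten);
* ingredient lists built generatively — a keyword surface form
  (accented, as printed on labels) is inserted iff the planted flag is
  true, amid inert distractor ingredients — so keyword detection has
  zero planted ambiguity, plus a `noisy_vocabulary` mode that adds
  near-miss tokens ("salsa", "passas", "doce") to stress the
  whole-token matcher;
* a 10 % total-sugars declaration rate, NOVA mixes per category, and
  (for the exclusion fixture) exact planted defect counts with the
  defect materialised in the data (a `missing_panel` product really has
  no panel);
* one global seed feeding a counter-based per-product stream, so
  product *i*'s draws are independent of how many products precede it
  and generation is byte-reproducible.

The generator writes, per product and per model, the warning flag
implied by the planted values — computed by direct per-model arithmetic,
deliberately separate from the config-driven criteria engine. Because
the classifiers are deterministic rules, the scan → estimate → classify
pipeline must recover these flags **exactly**; the tests assert 100 %
recovery at n = 10 000 across five seeds. What passing proves: the
plumbing between modules (normalization, rule gating, indeterminacy
propagation, threshold logic) is faithful. What it does not prove:
performance on real labels — actual ingredient lists contain negations,
misspellings, and regional vocabulary beyond the shipped keyword sets,
and real nutrient panels contain entry errors the generator does not
emulate. Supply-level percentages from the generator characterise the
generator's conditions, not any real market.

# Numerical and degenerate-input choices

* kJ→kcal at 4.184; declared kcal wins over declared kJ (labels are
  authoritative). Missing both is an error, not a silent zero.
* Unparseable numeric cells (either decimal separator accepted) become
  missing, never zero, and propagate as indeterminate criteria.
* Zero-energy products: energy-ratio criteria are undefined as ratios,
  so the criterion flags on presence of the nutrient alone (a
  zero-energy product with measurable sugar is flagged; an all-zero
  panel is not).
* Exclusion filters evaluate defects in a fixed order (multi-size,
  multipack, missing panel, missing ingredients, missing
  portion/energy); a product counts once under its first matching
  class, making tallies deterministic and exactly reconcilable.
* Reconstitution multiplies the panel by factor/100 (factor = g of
  product per 100 g/ml prepared), switches the basis, and marks the
  product as-consumed, making the operation idempotent; nutrient-to-
  energy ratios are invariant under it. The factor is an input field —
  label instructions differ too much for per-category defaults.

# Validation problem sizes

The test suite runs the full property battery at the sizes it needs and
no larger: recovery at n = 10 000 across five seeds, kappa-oracle
equivalence on random tables up to N = 200, binomial-rate checks at
n = 10 000 against 3-standard-error bounds, and the exclusion fixture
at its canonical 12 956 rows. The whole suite completes in about a
minute on one core.

# Limitations

* Keyword vocabularies are necessarily incomplete against real-world
  ingredient spellings; the vocabulary is config so users can extend it.
* The Anvisa cutoffs implement a proposal that was still moving; users
  comparing against the final adopted regulation should supply a config
  with its values.
* Free-sugar estimation is a label-based approximation, not a
  compositional analysis; categories outside the shipped rule table get
  the keyword-gated default fraction.
* Kappa is reported unweighted and pairwise; no multi-rater or
  bootstrap machinery is included by design.
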