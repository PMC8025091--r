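# Synthetic packaged-food supply with planted ground truth.
#
# The generator emulates the statistical structure a supermarket-derived
# packaged-food database presents to the analysis: category-structured
# log-normal nutrient distributions, Portuguese ingredient lists
# assembled from the default keyword vocabulary plus distractor terms,
# a 10 % total-sugars declaration rate, NOVA-class mixes, and (for the
# exclusion fixture) planted data defects. Because keyword insertion is
# generative (a term appears iff the planted flag is true) and the
# classifiers are deterministic rules, the planted per-model warning
# flags must be recovered exactly by the scan -> estimate -> classify
# pipeline; the ground truth here is computed by direct per-model
# arithmetic, independent of the config-driven criteria engine.

# Surface forms (accented, as printed on labels) inserted when a planted
# flag is true. Each must trigger exactly its own vocabulary set.
KEYWORD_SURFACES <- list(
  added_sugar = c("açúcar", "mel", "maltodextrina", "frutose",
                  "xarope de glicose", "melaço", "doce de leite",
                  "açúcar invertido"),
  added_salt = c("sal", "cloreto de sódio", "sal refinado",
                 "queijo parmesão"),
  added_fat = c("óleo de soja", "gordura vegetal hidrogenada",
                "manteiga", "azeite de oliva", "creme de leite", "banha"),
  nns = c("sucralose", "aspartame", "acessulfame de potássio",
          "estévia", "ciclamato de sódio", "sacarina sódica")
)

# Inert filler ingredients: none matches any shipped vocabulary term.
DISTRACTOR_INGREDIENTS <- c(
  "água", "farinha de trigo", "amido de milho", "fermento químico",
  "aroma natural", "espessante goma xantana", "acidulante ácido cítrico",
  "conservante sorbato de potássio", "corante caramelo", "cacau em pó",
  "leite em pó desnatado", "proteína isolada de soja",
  "polpa de tomate", "aveia em flocos", "estabilizante lecitina"
)

# Near-miss tokens that must NOT match under whole-token matching; used
# by the noisy-vocabulary stress mode.
NEAR_MISS_INGREDIENTS <- c(
  "salsa", "melancia", "massas", "passas", "doce", "glicosamina",
  "sucralfato", "azeitada"
)

#' Default per-category generator parameters
#'
#' Twelve food categories with market shares, physical basis, log-normal
#' nutrient distributions (location = log median, per 100 g/ml of the
#' as-consumed product), saturated-fat fraction ranges, keyword
#' probabilities (added sugar / salt / fat, NNS) and NOVA-class mixes.
#' Values are chosen to be realistic for a packaged-food supply: energy-
#' dense sugary cookies and cereals, sodium-heavy processed meats and
#' convenience foods, low-energy sweetened beverages with a substantial
#' NNS share, and a mostly unprocessed plain-dairy category.
#'
#' @return Named list of per-category parameter lists.
#' @export
default_supply_categories <- function() {
  cat_par <- function(share, basis, energy, sugars, fat, sodium,
                      sat_range, p_trans, p_sugar, p_salt, p_fat, p_nns,
                      nova) {
    list(share = share, basis = basis, energy = energy, sugars = sugars,
         fat = fat, sodium = sodium, sat_range = sat_range,
         p_trans = p_trans, p_sugar = p_sugar, p_salt = p_salt,
         p_fat = p_fat, p_nns = p_nns, nova = nova)
  }
  list(
    sweetened_beverages = cat_par(0.12, "liquid",
      energy = c(log(35), 0.6), sugars = c(log(8), 0.5),
      fat = c(log(0.05), 0.5), sodium = c(log(15), 0.7),
      sat_range = c(0.1, 0.4), p_trans = 0.00,
      p_sugar = 0.95, p_salt = 0.05, p_fat = 0.02, p_nns = 0.45,
      nova = c(0.00, 0.02, 0.08, 0.90)),
    sweetened_dairy_beverages = cat_par(0.08, "liquid",
      energy = c(log(70), 0.35), sugars = c(log(10), 0.35),
      fat = c(log(2), 0.5), sodium = c(log(55), 0.4),
      sat_range = c(0.5, 0.7), p_trans = 0.02,
      p_sugar = 0.90, p_salt = 0.10, p_fat = 0.30, p_nns = 0.29,
      nova = c(0.00, 0.05, 0.10, 0.85)),
    plain_dairy = cat_par(0.08, "liquid",
      energy = c(log(55), 0.3), sugars = c(log(4.8), 0.2),
      fat = c(log(3), 0.4), sodium = c(log(50), 0.3),
      sat_range = c(0.55, 0.7), p_trans = 0.02,
      p_sugar = 0.15, p_salt = 0.03, p_fat = 0.05, p_nns = 0.02,
      nova = c(0.70, 0.15, 0.10, 0.05)),
    canned_vegetables = cat_par(0.08, "solid",
      energy = c(log(45), 0.5), sugars = c(log(2.5), 0.6),
      fat = c(log(0.4), 0.8), sodium = c(log(420), 0.5),
      sat_range = c(0.1, 0.3), p_trans = 0.00,
      p_sugar = 0.20, p_salt = 0.95, p_fat = 0.15, p_nns = 0.01,
      nova = c(0.02, 0.08, 0.60, 0.30)),
    convenience_foods = cat_par(0.10, "solid",
      energy = c(log(150), 0.5), sugars = c(log(3), 0.7),
      fat = c(log(6), 0.7), sodium = c(log(550), 0.5),
      sat_range = c(0.25, 0.5), p_trans = 0.10,
      p_sugar = 0.30, p_salt = 0.95, p_fat = 0.80, p_nns = 0.02,
      nova = c(0.00, 0.02, 0.13, 0.85)),
    breakfast_cereals_granola_bars = cat_par(0.08, "solid",
      energy = c(log(380), 0.15), sugars = c(log(22), 0.4),
      fat = c(log(6), 0.6), sodium = c(log(280), 0.6),
      sat_range = c(0.2, 0.5), p_trans = 0.05,
      p_sugar = 0.90, p_salt = 0.70, p_fat = 0.60, p_nns = 0.35,
      nova = c(0.02, 0.03, 0.10, 0.85)),
    cookies = cat_par(0.10, "solid",
      energy = c(log(450), 0.1), sugars = c(log(24), 0.3),
      fat = c(log(17), 0.3), sodium = c(log(340), 0.4),
      sat_range = c(0.35, 0.55), p_trans = 0.15,
      p_sugar = 0.97, p_salt = 0.90, p_fat = 0.95, p_nns = 0.05,
      nova = c(0.00, 0.01, 0.04, 0.95)),
    ready_to_eat_meals = cat_par(0.08, "solid",
      energy = c(log(170), 0.4), sugars = c(log(2.5), 0.7),
      fat = c(log(8), 0.5), sodium = c(log(480), 0.5),
      sat_range = c(0.25, 0.45), p_trans = 0.08,
      p_sugar = 0.25, p_salt = 0.95, p_fat = 0.85, p_nns = 0.01,
      nova = c(0.00, 0.02, 0.23, 0.75)),
    processed_meats = cat_par(0.08, "solid",
      energy = c(log(220), 0.3), sugars = c(log(1.2), 0.6),
      fat = c(log(14), 0.4), sodium = c(log(1050), 0.3),
      sat_range = c(0.3, 0.45), p_trans = 0.03,
      p_sugar = 0.30, p_salt = 0.98, p_fat = 0.50, p_nns = 0.01,
      nova = c(0.00, 0.02, 0.48, 0.50)),
    cheeses = cat_par(0.08, "solid",
      energy = c(log(330), 0.25), sugars = c(log(1.5), 0.5),
      fat = c(log(25), 0.3), sodium = c(log(650), 0.4),
      sat_range = c(0.55, 0.7), p_trans = 0.03,
      p_sugar = 0.05, p_salt = 0.95, p_fat = 0.20, p_nns = 0.01,
      nova = c(0.02, 0.08, 0.75, 0.15)),
    breads_bakery = cat_par(0.07, "solid",
      energy = c(log(270), 0.2), sugars = c(log(5), 0.5),
      fat = c(log(4), 0.6), sodium = c(log(430), 0.3),
      sat_range = c(0.2, 0.45), p_trans = 0.08,
      p_sugar = 0.70, p_salt = 0.95, p_fat = 0.60, p_nns = 0.02,
      nova = c(0.02, 0.03, 0.25, 0.70)),
    candies_sweets = cat_par(0.05, "solid",
      energy = c(log(380), 0.2), sugars = c(log(60), 0.3),
      fat = c(log(3), 1.0), sodium = c(log(50), 0.9),
      sat_range = c(0.3, 0.6), p_trans = 0.05,
      p_sugar = 0.99, p_salt = 0.30, p_fat = 0.40, p_nns = 0.05,
      nova = c(0.00, 0.02, 0.08, 0.90))
  )
}

#' Specify a synthetic food supply
#'
#' @param n Number of products.
#' @param seed Integer seed (mandatory); one global seed feeds a
#'   counter-based per-product stream, so draws for product `i` do not
#'   depend on how many products precede it.
#' @param sugar_declaration_rate Probability that a product declares
#'   total sugars on its panel (default 0.10: sugar information is
#'   present for about one product in ten).
#' @param added_declaration_rate Probability that a sugar-declaring
#'   product additionally declares added sugars.
#' @param categories Per-category parameters, see
#'   [default_supply_categories()].
#' @param noisy_vocabulary Add near-miss distractor tokens (e.g.
#'   "salsa", "passas") to stress the whole-token matcher.
#' @return A validated `supply_spec` list.
#' @export
supply_spec <- function(n = 1000, seed = NULL,
                        sugar_declaration_rate = 0.10,
                        added_declaration_rate = 0.20,
                        categories = default_supply_categories(),
                        noisy_vocabulary = FALSE) {
  if (is.null(seed)) abort("supply_spec: seed is mandatory")
  if (n < 0) abort("supply_spec: n must be non-negative")
  shares <- vapply(categories, function(p) p$share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-6) {
    abort("supply_spec: category shares must sum to 1")
  }
  probs <- c(sugar_declaration_rate, added_declaration_rate,
             unlist(lapply(categories, function(p) {
               c(p$p_trans, p$p_sugar, p$p_salt, p$p_fat, p$p_nns, p$nova)
             })))
  if (any(probs < 0 | probs > 1)) {
    abort("supply_spec: probabilities must be in [0, 1]")
  }
  for (cat in names(categories)) {
    if (abs(sum(categories[[cat]]$nova) - 1) > 1e-6) {
      abort(sprintf("supply_spec: NOVA mix for '%s' must sum to 1", cat))
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sugar_declaration_rate = sugar_declaration_rate,
                 added_declaration_rate = added_declaration_rate,
                 categories = categories,
                 noisy_vocabulary = noisy_vocabulary),
            class = "supply_spec")
}

# Counter-based per-product seed, kept below 2^31.
product_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 69621) %% 2147483647)
}

# Assemble one Portuguese ingredient list from distractors plus the
# keyword surfaces implied by the planted flags.
build_ingredient_text <- function(flags, noisy) {
  parts <- sample(DISTRACTOR_INGREDIENTS, sample(3:5, 1))
  if (noisy) parts <- c(parts, sample(NEAR_MISS_INGREDIENTS, 2))
  for (set in names(KEYWORD_SURFACES)) {
    if (isTRUE(flags[[set]])) {
      parts <- c(parts, sample(KEYWORD_SURFACES[[set]], sample(1:2, 1)))
    }
  }
  paste(sample(parts), collapse = ", ")
}

#' Generate a synthetic packaged-food supply
#'
#' Draws products per the supply specification and records, per product
#' and per model,
#' the warning flags implied by the planted nutrient values and keywords
#' (computed by direct per-model arithmetic). Nutrient panels respect
#' composition constraints: values non-negative, saturated and trans fat
#' within total fat, fat and sugar energy within total energy, and
#' everything truncated at physiologically plausible maxima. Reproducible:
#' the same spec (same seed) yields identical output.
#'
#' @param spec A `supply_spec`.
#' @return List with `products` (product tibble) and `truth` (tibble of
#'   planted keyword flags, true free sugars, and per-model `eligible_*` /
#'   `warning_*` columns keyed by `product_id`).
#' @export
generate_supply <- function(spec) {
  stopifnot(inherits(spec, "supply_spec"))
  cats <- spec$categories
  cat_names <- names(cats)
  shares <- vapply(cats, function(p) p$share, numeric(1))
  n <- spec$n
  if (n == 0) {
    return(list(products = read_products_empty(),
                truth = tibble::tibble(product_id = character(0))))
  }
  category <- basis <- text <- character(n)
  energy_v <- sugars_v <- added_v <- fat_v <- sat_v <- trans_v <-
    sodium_v <- serving_v <- numeric(n)
  nova_v <- integer(n)
  kw_sugar <- kw_salt <- kw_fat <- kw_nns <- logical(n)
  for (i in seq_len(n)) {
    set.seed(product_seed(spec$seed, i))
    cat <- sample(cat_names, 1, prob = shares)
    p <- cats[[cat]]
    energy <- min(rlnorm(1, p$energy[1], p$energy[2]), 900)
    fat <- min(rlnorm(1, p$fat[1], p$fat[2]), energy / 9, 100)
    sat <- fat * runif(1, p$sat_range[1], p$sat_range[2])
    trans <- if (runif(1) < p$p_trans) fat * runif(1, 0.02, 0.15) else 0
    sugars <- min(rlnorm(1, p$sugars[1], p$sugars[2]),
                  max(0, energy - 9 * fat) / 4, 100)
    sodium <- min(rlnorm(1, p$sodium[1], p$sodium[2]), 4000)
    flags <- list(
      added_sugar = runif(1) < p$p_sugar,
      added_salt = runif(1) < p$p_salt,
      added_fat = runif(1) < p$p_fat,
      nns = runif(1) < p$p_nns
    )
    nova <- sample(1:4, 1, prob = p$nova)
    declares_total <- runif(1) < spec$sugar_declaration_rate
    declares_added <- declares_total && runif(1) < spec$added_declaration_rate
    added <- if (declares_added) sugars * runif(1, 0.5, 1) else NA_real_

    category[[i]] <- cat
    basis[[i]] <- p$basis
    energy_v[[i]] <- round(energy, 1)
    sugars_v[[i]] <- if (declares_total) round(sugars, 2) else NA_real_
    added_v[[i]] <- if (declares_added) round(min(added, sugars), 2) else NA_real_
    fat_v[[i]] <- round(fat, 2)
    sat_v[[i]] <- round(sat, 2)
    trans_v[[i]] <- round(trans, 2)
    sodium_v[[i]] <- round(sodium, 1)
    serving_v[[i]] <- if (p$basis == "liquid") round(runif(1, 200, 350)) else
      round(runif(1, 25, 60))
    nova_v[[i]] <- nova
    kw_sugar[[i]] <- flags$added_sugar
    kw_salt[[i]] <- flags$added_salt
    kw_fat[[i]] <- flags$added_fat
    kw_nns[[i]] <- flags$nns
    text[[i]] <- build_ingredient_text(flags, spec$noisy_vocabulary)
  }
  products <- tibble::tibble(
    product_id = sprintf("P%06d", seq_len(n)),
    category = category, basis = basis,
    energy_kj = round(energy_v * KJ_PER_KCAL, 1), energy_kcal = energy_v,
    total_sugars_g = sugars_v, added_sugars_g = added_v,
    total_fat_g = fat_v, sat_fat_g = sat_v, trans_fat_g = trans_v,
    sodium_mg = sodium_v, fibre_g = NA_real_,
    ingredient_text = text, serving_size = serving_v,
    reconstitution_factor = NA_real_, nova_class = nova_v,
    defects = rep(list(character(0)), n), as_consumed = FALSE
  )
  planted <- tibble::tibble(nova = nova_v, has_added_sugar = kw_sugar,
                            has_added_salt = kw_salt, has_added_fat = kw_fat,
                            has_nns = kw_nns)
  truth <- supply_ground_truth(products, planted)
  list(products = products, truth = truth)
}

# Empty product tibble with the full column set.
read_products_empty <- function() {
  out <- tibble::tibble(product_id = character(0), category = character(0),
                        basis = character(0))
  for (f in PANEL_FIELDS) out[[f]] <- numeric(0)
  out$ingredient_text <- character(0)
  out$serving_size <- numeric(0)
  out$reconstitution_factor <- numeric(0)
  out$nova_class <- integer(0)
  out$defects <- list()
  out$as_consumed <- logical(0)
  out
}

# Planted ground truth: direct vectorized arithmetic per model, using the
# values as they appear on the emitted panels (declared sugars only) and
# the planted keyword flags. Intentionally separate from the generic
# criteria engine so that pipeline recovery is a dual-route check.
supply_ground_truth <- function(products, full,
                                rules = default_free_sugar_rules()) {
  n <- nrow(products)
  e <- products$energy_kcal
  total <- products$total_sugars_g
  added <- products$added_sugars_g
  sugar_kw <- full$has_added_sugar
  salt_kw <- full$has_added_salt
  fat_kw <- full$has_added_fat
  nns_kw <- full$has_nns

  # free sugars under the category rules (declared values only)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    rule <- rules$categories[[products$category[[i]]]]
    if (!is.null(rule)) {
      frac[[i]] <- if (isTRUE(rule$requires_added_sugar_keyword) && !sugar_kw[[i]])
        0 else rule$fraction
    } else {
      frac[[i]] <- if (sugar_kw[[i]]) rules$default$fraction_with_keyword
                   else rules$default$fraction_without_keyword
    }
  }
  fs <- ifelse(!is.na(added), added,
               ifelse(!is.na(total), total * frac, NA_real_))

  liquid <- products$basis == "liquid"
  flag <- function(value, thr) {
    ifelse(is.na(value), NA, value >= thr)
  }
  outcome <- function(eligible, flag_list) {
    m <- do.call(cbind, flag_list)
    any_true <- rowSums(m, na.rm = TRUE) > 0
    any_na <- rowSums(is.na(m)) > 0
    out <- rep(NA, n)
    out[!eligible] <- FALSE
    out[eligible & any_true] <- TRUE
    out[eligible & !any_true & !any_na] <- FALSE
    out
  }

  paho_flags <- list(
    fs = flag(fs * 4 / e, 0.10),
    fat = flag(products$total_fat_g * 9 / e, 0.30),
    sat = flag(products$sat_fat_g * 9 / e, 0.10),
    trans = flag(products$trans_fat_g * 9 / e, 0.01),
    sodium = flag(products$sodium_mg / e, 1),
    nns = nns_kw
  )
  elig_paho <- full$nova %in% c(3, 4)
  elig_added <- sugar_kw | salt_kw | fat_kw

  chile_flags <- list(
    energy = flag(e, ifelse(liquid, 70, 275)),
    sugars = flag(total, ifelse(liquid, 5, 10)),
    sat = flag(products$sat_fat_g, ifelse(liquid, 3, 4)),
    sodium = flag(products$sodium_mg, ifelse(liquid, 100, 400))
  )
  anvisa_flags <- list(
    fs = flag(fs, ifelse(liquid, 5, 10)),
    sat = flag(products$sat_fat_g, ifelse(liquid, 2, 4)),
    sodium = flag(products$sodium_mg, ifelse(liquid, 200, 400))
  )

  tibble::tibble(
    product_id = products$product_id,
    has_added_sugar = sugar_kw,
    has_added_salt = salt_kw,
    has_added_fat = fat_kw,
    has_nns = nns_kw,
    free_sugars_true = fs,
    eligible_paho = elig_paho,
    eligible_chile = elig_added,
    eligible_anvisa = rep(TRUE, n),
    eligible_modified_paho = elig_added,
    warning_paho = outcome(elig_paho, paho_flags),
    warning_chile = outcome(elig_added, chile_flags),
    warning_anvisa = outcome(rep(TRUE, n), anvisa_flags),
    warning_modified_paho = outcome(elig_added, paho_flags)
  )
}

#' Build a fixture for the exclusion filters
#'
#' Generates `n_clean + sum(counts)` products and plants exactly the
#' requested number of each data defect (in the canonical defect order),
#' blanking the corresponding fields so the defects are real (a product
#' flagged `missing_panel` has no panel, etc.); rows are then shuffled
#' deterministically by the seed.
#'
#' @param counts Integer vector of 5 defect counts, in the order
#'   multi-size duplicate, multipack, missing panel, missing ingredient
#'   list, missing portion/energy.
#' @param n_clean Number of defect-free products.
#' @param seed Integer seed.
#' @return Product tibble of `n_clean + sum(counts)` rows.
#' @export
make_exclusion_fixture <- function(counts, n_clean, seed) {
  stopifnot(length(counts) == length(DEFECT_CLASSES), all(counts >= 0),
            n_clean >= 0)
  n_total <- n_clean + sum(counts)
  products <- generate_supply(supply_spec(n = n_total, seed = seed))$products
  if (n_total == 0) return(products)
  defect_of_row <- rep(c(DEFECT_CLASSES, NA_character_),
                       times = c(counts, n_clean))
  for (i in which(!is.na(defect_of_row))) {
    d <- defect_of_row[[i]]
    products$defects[[i]] <- d
    if (d == "missing_panel") {
      products[i, PANEL_FIELDS] <- NA_real_
    } else if (d == "missing_ingredients") {
      products$ingredient_text[[i]] <- NA_character_
    } else if (d == "missing_portion_or_energy") {
      products$serving_size[[i]] <- NA_real_
      products$energy_kj[[i]] <- NA_real_
      products$energy_kcal[[i]] <- NA_real_
    }
  }
  set.seed(product_seed(seed, 0L))
  products[sample(n_total), , drop = FALSE]
}
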