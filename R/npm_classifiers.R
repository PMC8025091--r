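# The four front-of-package warning-label classifiers.
#
# Each model is a ModelConfig (YAML): an eligibility rule, a list of
# nutrient criteria (energy-ratio, per-100 g/ml, per-kcal or presence
# metrics with thresholds), and optional category machinery (Anvisa's
# exclusion list, Chile's culinary-ingredient rule). A single generic
# engine evaluates any config; `classify_paho()` etc. are thin wrappers
# over the shipped defaults.
#
# Criterion statuses: "excessive", "not_excessive", "indeterminate"
# (required nutrient value missing), "not_applicable" (product ineligible
# or criterion masked by the culinary rule). `any_warning` is TRUE iff
# the product is eligible and at least one criterion is excessive; FALSE
# for ineligible products; NA when eligibility or the outcome cannot be
# determined (e.g. an eligible product whose only unresolved criterion is
# an indeterminate sugar value).

ELIGIBILITY_RULES <- c("nova_processed_or_ultraprocessed",
                       "added_critical_ingredient",
                       "category_exclusion_list", "always")
CRITERION_METRICS <- c("energy_ratio", "per_100", "per_energy", "presence")
CRITERION_NUTRIENTS <- c("free_sugars", "total_sugars_g", "added_sugars_g",
                         "total_fat_g", "sat_fat_g", "trans_fat_g",
                         "sodium_mg", "energy_kcal", "nns")

#' Load a model configuration
#'
#' Shipped defaults: `"paho"` (nutrient-to-energy ratios, NOVA 3/4
#' eligibility, NNS presence), `"chile"` (Law 20.606 per-100 thresholds,
#' added-ingredient eligibility, culinary rule), `"anvisa"` (per-100
#' thresholds with a category exclusion list) and `"modified_paho"`
#' (PAHO criteria under Chilean eligibility). A path to a custom YAML is
#' accepted in place of a name.
#'
#' @param model Model name or path to a config YAML.
#' @return A validated `model_config` list.
#' @export
npm_config <- function(model) {
  path <- if (file.exists(model)) model else npm_extdata("models", paste0(model, ".yaml"))
  validate_model_config(yaml::read_yaml(path))
}

#' Validate a model configuration
#'
#' Checks the eligibility rule id, metric names, positivity of
#' quantitative thresholds, and that each criterion id is unique.
#'
#' @param config Model config list (parsed YAML).
#' @return The config, classed `model_config`; errors name the offending
#'   entry.
#' @export
validate_model_config <- function(config) {
  if (is.null(config$name)) abort("model config: 'name' is required")
  if (is.null(config$eligibility) || !config$eligibility %in% ELIGIBILITY_RULES) {
    abort(sprintf("model config '%s': eligibility must be one of %s",
                  config$name, paste(ELIGIBILITY_RULES, collapse = ", ")))
  }
  if (length(config$criteria) == 0) {
    abort(sprintf("model config '%s': at least one criterion required", config$name))
  }
  ids <- vapply(config$criteria, function(cr) cr$id %||% "", character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("model config '%s': duplicate criterion id '%s'",
                  config$name, ids[duplicated(ids)][[1]]))
  }
  for (cr in config$criteria) {
    where <- sprintf("model config '%s', criterion '%s'", config$name, cr$id %||% "?")
    if (is.null(cr$metric) || !cr$metric %in% CRITERION_METRICS) {
      abort(sprintf("%s: metric must be one of %s", where,
                    paste(CRITERION_METRICS, collapse = ", ")))
    }
    if (is.null(cr$nutrient) || !cr$nutrient %in% CRITERION_NUTRIENTS) {
      abort(sprintf("%s: unknown nutrient '%s'", where, cr$nutrient %||% ""))
    }
    if (cr$metric != "presence") {
      thr <- c(cr$threshold, cr$threshold_solid, cr$threshold_liquid)
      if (length(thr) == 0) abort(sprintf("%s: threshold missing", where))
      if (any(thr <= 0)) abort(sprintf("%s: thresholds must be > 0", where))
    }
  }
  structure(config, class = "model_config")
}

# Threshold vector for a criterion, resolved per product basis. A config
# may give a single `threshold` or a solid/liquid pair.
criterion_threshold <- function(cr, basis, model_name) {
  if (!is.null(cr$threshold)) return(rep(cr$threshold, length(basis)))
  if (any(is.na(basis))) {
    abort(sprintf("model '%s': basis (solid/liquid) required for criterion '%s'",
                  model_name, cr$id))
  }
  ifelse(basis == "liquid", cr$threshold_liquid, cr$threshold_solid)
}

# Evaluate one criterion -> status character vector. `energy` may be NULL
# for configs that never reference it.
evaluate_criterion <- function(cr, products, free_sugars, nns, energy, model_name) {
  n <- nrow(products)
  if (cr$metric == "presence") {
    return(unname(ifelse(nns, "excessive", "not_excessive")))
  }
  value <- switch(cr$nutrient,
    free_sugars = free_sugars,
    energy_kcal = energy,
    products[[cr$nutrient]]
  )
  thr <- criterion_threshold(cr, products$basis, model_name)
  if (cr$metric == "per_100") {
    status <- ifelse(is.na(value), "indeterminate",
                     ifelse(value >= thr, "excessive", "not_excessive"))
    return(status)
  }
  # energy_ratio / per_energy need total energy
  kcal_per_g <- if (cr$metric == "energy_ratio") cr$kcal_per_g %||% 1 else 1
  ratio <- (value * kcal_per_g) / energy
  # zero-energy edge: the ratio is undefined, but a product declaring zero
  # energy and a positive nutrient content still carries that nutrient;
  # flag on presence of the nutrient alone.
  zero_e <- !is.na(energy) & energy == 0
  status <- rep("indeterminate", n)
  det <- !is.na(value) & !zero_e
  status[det] <- ifelse(ratio[det] >= thr[det], "excessive", "not_excessive")
  status[zero_e & !is.na(value)] <-
    ifelse(value[zero_e & !is.na(value)] > 0, "excessive", "not_excessive")
  status
}

# Eligibility -> list(eligible = logical (NA allowed), reason = chr)
evaluate_eligibility <- function(config, products, findings) {
  n <- nrow(products)
  reason <- rep("eligible", n)
  eligible <- rep(TRUE, n)
  switch(config$eligibility,
    always = NULL,
    nova_processed_or_ultraprocessed = {
      nova <- products$nova_class
      eligible <- ifelse(is.na(nova), NA, nova %in% c(3, 4))
      reason[is.na(nova)] <- "nova_missing"
      reason[!is.na(nova) & !nova %in% c(3, 4)] <- "not_processed"
    },
    added_critical_ingredient = {
      eligible <- findings$has_added_sugar | findings$has_added_salt |
        findings$has_added_fat
      reason[!eligible] <- "no_added_critical_ingredient"
    },
    category_exclusion_list = {
      excl <- products$category %in% (config$category_exclusions %||% character(0))
      eligible <- !excl
      reason[excl] <- "excluded_category"
    }
  )
  # Culinary-ingredient rule: a culinary staple is eligible only when a
  # critical nutrient other than its defining one has been added.
  for (cul in config$culinary %||% list()) {
    in_cat <- products$category == cul$category
    if (!any(in_cat)) next
    kw <- list(added_sugar = findings$has_added_sugar,
               added_salt = findings$has_added_salt,
               added_fat = findings$has_added_fat)
    other <- Reduce(`|`, kw[setdiff(names(kw), cul$defining)])
    eligible[in_cat] <- other[in_cat]
    reason[in_cat & !other] <- "culinary_no_other_added"
    reason[in_cat & other] <- "eligible"
  }
  list(eligible = eligible, reason = reason)
}

#' Classify products under a nutrient profiling model
#'
#' The generic engine behind the four model wrappers: resolves
#' eligibility, evaluates every configured criterion, applies culinary
#' masking, and derives the overall warning outcome. All comparisons are
#' inclusive: a product exactly at a cutoff is flagged.
#'
#' @param products Product tibble (reconstituted, defect-free).
#' @param config A `model_config`, see [npm_config()].
#' @param findings Findings from [scan_products()]; computed on the fly
#'   when `NULL` and the config needs them.
#' @param free_sugars Free-sugar vector from [estimate_free_sugars()];
#'   computed with the default rules when `NULL` and the config needs it.
#' @return A classification tibble: `product_id`, `model`, `eligible`
#'   (logical, `NA` when indeterminate), `reason`, one status column per
#'   criterion id (prefixed `crit_`), `n_criteria_evaluated` and
#'   `any_warning`.
#' @export
classify_products <- function(products, config, findings = NULL,
                              free_sugars = NULL) {
  if (!inherits(config, "model_config")) config <- validate_model_config(config)
  n <- nrow(products)
  nutrients <- vapply(config$criteria, function(cr) cr$nutrient, character(1))
  needs_findings <- config$eligibility == "added_critical_ingredient" ||
    length(config$culinary %||% list()) > 0 || "nns" %in% nutrients
  if (needs_findings && is.null(findings)) findings <- scan_products(products)
  if ("free_sugars" %in% nutrients && is.null(free_sugars)) {
    if (is.null(findings)) findings <- scan_products(products)
    free_sugars <- estimate_free_sugars(products, findings)
  }
  metrics <- vapply(config$criteria, function(cr) cr$metric, character(1))
  energy <- NULL
  if (any(metrics %in% c("energy_ratio", "per_energy")) ||
      "energy_kcal" %in% nutrients) {
    energy <- energy_kcal(products)
  }
  nns <- if (!is.null(findings)) findings$has_nns else rep(FALSE, n)

  elig <- evaluate_eligibility(config, products, findings)
  status <- lapply(config$criteria, evaluate_criterion, products = products,
                   free_sugars = free_sugars, nns = nns, energy = energy,
                   model_name = config$name)
  names(status) <- vapply(config$criteria, function(cr) cr$id, character(1))

  # culinary masking: the defining nutrient's criteria never fire
  for (cul in config$culinary %||% list()) {
    in_cat <- products$category == cul$category
    for (id in cul$masks) {
      if (id %in% names(status)) status[[id]][in_cat] <- "not_applicable"
    }
  }
  # ineligible products carry no warnings; products whose eligibility is
  # indeterminate (e.g. missing NOVA class under PAHO) are fully
  # indeterminate and drop out of every denominator downstream
  not_elig <- !is.na(elig$eligible) & !elig$eligible
  elig_na <- is.na(elig$eligible)
  for (id in names(status)) {
    status[[id]][not_elig] <- "not_applicable"
    status[[id]][elig_na] <- "indeterminate"
  }

  smat <- do.call(cbind, status)
  any_exc <- rowSums(smat == "excessive") > 0
  any_ind <- rowSums(smat == "indeterminate") > 0
  any_warning <- rep(NA, n)
  any_warning[!is.na(elig$eligible) & !elig$eligible] <- FALSE
  ok <- !is.na(elig$eligible) & elig$eligible
  any_warning[ok & any_exc] <- TRUE
  any_warning[ok & !any_exc & !any_ind] <- FALSE

  out <- tibble::tibble(
    product_id = products$product_id,
    model = config$name,
    eligible = elig$eligible,
    reason = elig$reason
  )
  for (id in names(status)) out[[paste0("crit_", id)]] <- status[[id]]
  out$n_criteria_evaluated <-
    as.integer(rowSums(smat != "not_applicable"))
  out$any_warning <- any_warning
  out
}

#' @rdname classify_products
#' @param ... Passed to [classify_products()].
#' @export
classify_paho <- function(products, findings = NULL, free_sugars = NULL, ...) {
  classify_products(products, npm_config("paho"), findings, free_sugars, ...)
}

#' @rdname classify_products
#' @export
classify_chile <- function(products, findings = NULL, ...) {
  classify_products(products, npm_config("chile"), findings, ...)
}

#' @rdname classify_products
#' @export
classify_anvisa <- function(products, findings = NULL, free_sugars = NULL, ...) {
  classify_products(products, npm_config("anvisa"), findings, free_sugars, ...)
}

#' @rdname classify_products
#' @export
classify_modified_paho <- function(products, findings = NULL, free_sugars = NULL, ...) {
  classify_products(products, npm_config("modified_paho"), findings, free_sugars, ...)
}

#' Per-criterion warning outcome as a logical vector
#'
#' Maps a criterion's status column to the outcome used in nutrient-level
#' agreement analyses: `TRUE` for excessive, `FALSE` for not excessive or
#' not applicable (ineligible and culinary-masked products carry no
#' warning), `NA` for indeterminate.
#'
#' @param results Classification tibble from [classify_products()].
#' @param criterion Criterion id (e.g. `"sodium"`).
#' @return Logical vector aligned with `results`.
#' @export
criterion_outcome <- function(results, criterion) {
  col <- paste0("crit_", criterion)
  if (!col %in% names(results)) {
    abort(sprintf("model '%s' has no criterion '%s'",
                  results$model[[1]], criterion))
  }
  status <- results[[col]]
  ifelse(status == "indeterminate", NA, status == "excessive")
}
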