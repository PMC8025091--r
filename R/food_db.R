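# Data model, CSV I/O, exclusion filters, reconstitution and energy units
# for a packaged-food database.
#
# A product table is a tibble with one row per product. Nutrient panel
# values are on the as-sold basis, per 100 g (solids) or 100 ml (liquids),
# until `reconstitute()` rescales reconstitutable products.

# Nutrient panel columns, all per 100 g/ml.
PANEL_FIELDS <- c(
  "energy_kj", "energy_kcal", "total_sugars_g", "added_sugars_g",
  "total_fat_g", "sat_fat_g", "trans_fat_g", "sodium_mg", "fibre_g"
)

PRODUCT_FIELDS <- c(
  "product_id", "category", "basis", PANEL_FIELDS,
  "ingredient_text", "serving_size", "reconstitution_factor",
  "nova_class", "defects", "as_consumed"
)

# Defect classes, in the fixed precedence order used by the exclusion
# filters: a product is counted once, under the first class it carries.
DEFECT_CLASSES <- c(
  "multi_size_duplicate", "multipack", "missing_panel",
  "missing_ingredients", "missing_portion_or_energy"
)

# kJ per kcal (thermochemical calorie).
KJ_PER_KCAL <- 4.184

#' Default column map for product CSV files
#'
#' Maps internal field names to CSV column names. Pass a modified copy to
#' [read_products()] / [write_products()] when a file uses other headers.
#'
#' @return Named character vector, `field name -> column name`.
#' @export
product_schema <- function() {
  setNames(PRODUCT_FIELDS, PRODUCT_FIELDS)
}

# Columns that must be present in an input file. Energy is special-cased:
# at least one of energy_kj / energy_kcal.
required_product_fields <- function() {
  c("product_id", "category", "basis", "total_fat_g", "sat_fat_g",
    "trans_fat_g", "sodium_mg", "ingredient_text")
}

# Parse numbers accepting both decimal comma (Brazilian labels) and dot.
# Unparseable cells become NA (missing), never zero.
parse_number_br <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
}

# Split a "a;b;c" defect cell into a character vector.
parse_defects <- function(x) {
  lapply(as.character(x), function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  })
}

#' Read a packaged-food table from CSV
#'
#' Reads one product per row. Numeric cells that cannot be parsed (either
#' decimal separator is accepted) are recorded as missing, not zero, so
#' that downstream criteria evaluate to indeterminate rather than silently
#' passing. Row order is preserved.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Column map as returned by [product_schema()].
#' @return A product tibble (one row per [FoodProduct][product_schema]).
#' @export
read_products <- function(path, schema = product_schema()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_req <- setdiff(required_product_fields(), PRODUCT_FIELDS)
  stopifnot(length(missing_req) == 0)
  for (field in required_product_fields()) {
    col <- schema[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(sprintf("missing mandatory column: %s (field %s)",
                    col %||% field, field))
    }
  }
  if (!schema[["energy_kj"]] %in% names(raw) &&
      !schema[["energy_kcal"]] %in% names(raw)) {
    abort("missing mandatory column: at least one of energy_kj, energy_kcal")
  }
  get_col <- function(field) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  numeric_fields <- c(PANEL_FIELDS, "serving_size", "reconstitution_factor")
  products <- tibble::tibble(
    product_id = as.character(get_col("product_id")),
    category = as.character(get_col("category")),
    basis = as.character(get_col("basis"))
  )
  for (field in numeric_fields) {
    products[[field]] <- parse_number_br(get_col(field))
  }
  products$ingredient_text <- as.character(get_col("ingredient_text"))
  nova <- parse_number_br(get_col("nova_class"))
  products$nova_class <- ifelse(is.na(nova), NA_integer_, as.integer(nova))
  products$defects <- parse_defects(get_col("defects"))
  ac <- tolower(trimws(as.character(get_col("as_consumed"))))
  products$as_consumed <- !is.na(ac) & ac %in% c("true", "t", "1", "yes")
  products <- products[, PRODUCT_FIELDS]
  validate_products(products)
  products
}

#' Write a packaged-food table to CSV
#'
#' Inverse of [read_products()]: `read_products(write_products(x, path))`
#' round-trips every field of a valid table.
#'
#' @param products Product tibble.
#' @param path Output path.
#' @param schema Column map as returned by [product_schema()].
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path, schema = product_schema()) {
  out <- products
  out$defects <- vapply(products$defects, paste, "", collapse = ";")
  names(out) <- unname(schema[names(out)])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate product-table invariants
#'
#' Checks non-negativity of panel values, `added_sugars <= total_sugars`
#' and `sat_fat <= total_fat` (where both are present), and that `basis`
#' is `"solid"` or `"liquid"` when given. Violations raise an error that
#' names the offending products.
#'
#' @param products Product tibble.
#' @return `products`, invisibly.
#' @export
validate_products <- function(products) {
  bad_id <- function(mask) {
    paste(head(products$product_id[which(mask)], 5), collapse = ", ")
  }
  for (field in c(PANEL_FIELDS, "serving_size", "reconstitution_factor")) {
    neg <- !is.na(products[[field]]) & products[[field]] < 0
    if (any(neg)) {
      abort(sprintf("negative %s for product(s): %s", field, bad_id(neg)))
    }
  }
  bad_sugar <- !is.na(products$added_sugars_g) & !is.na(products$total_sugars_g) &
    products$added_sugars_g > products$total_sugars_g + 1e-9
  if (any(bad_sugar)) {
    abort(sprintf("added sugars exceed total sugars for product(s): %s",
                  bad_id(bad_sugar)))
  }
  bad_fat <- !is.na(products$sat_fat_g) & !is.na(products$total_fat_g) &
    products$sat_fat_g > products$total_fat_g + 1e-9
  if (any(bad_fat)) {
    abort(sprintf("saturated fat exceeds total fat for product(s): %s",
                  bad_id(bad_fat)))
  }
  bad_basis <- !is.na(products$basis) & !products$basis %in% c("solid", "liquid")
  if (any(bad_basis)) {
    abort(sprintf("basis must be 'solid' or 'liquid' for product(s): %s",
                  bad_id(bad_basis)))
  }
  invisible(products)
}

#' Resolve energy in kcal per 100 g/ml
#'
#' Declared kcal wins over declared kJ when both are present (the label is
#' authoritative); otherwise kJ is converted at 4.184 kJ/kcal.
#'
#' @param x Product tibble (or any data frame with `energy_kcal` /
#'   `energy_kj` columns).
#' @return Numeric vector of energies (kcal per 100 g/ml).
#' @export
energy_kcal <- function(x) {
  kcal <- x$energy_kcal
  kj <- x$energy_kj
  if (is.null(kcal)) kcal <- rep(NA_real_, nrow(x))
  if (is.null(kj)) kj <- rep(NA_real_, nrow(x))
  both_missing <- is.na(kcal) & is.na(kj)
  if (any(both_missing)) {
    ids <- if (!is.null(x$product_id)) x$product_id[both_missing] else which(both_missing)
    abort(sprintf("missing energy (neither kcal nor kJ) for product(s): %s",
                  paste(head(ids, 5), collapse = ", ")))
  }
  ifelse(is.na(kcal), kj / KJ_PER_KCAL, kcal)
}

#' Apply the database exclusion filters
#'
#' Removes products carrying data defects (duplicate package sizes,
#' mixed multipacks, missing nutrition facts panel, missing ingredient
#' list, missing portion size and/or energy). Defects are evaluated in
#' that fixed order and each product is tallied once, under the first
#' class it matches, so the tally reconciles exactly:
#' `n_retained = n_input - sum(excluded)`.
#'
#' @param products Product tibble with the `defects` list-column populated.
#' @return A list with `products` (the retained rows, defect-free) and
#'   `tally` (an `exclusion_tally`: per-class counts plus `n_input` and
#'   `n_retained`).
#' @export
apply_exclusion_filters <- function(products) {
  first_defect <- vapply(products$defects, function(d) {
    hit <- DEFECT_CLASSES[DEFECT_CLASSES %in% d]
    if (length(hit) == 0) NA_character_ else hit[[1]]
  }, character(1))
  counts <- vapply(DEFECT_CLASSES, function(cl) sum(first_defect == cl, na.rm = TRUE),
                   integer(1))
  retained <- products[is.na(first_defect), , drop = FALSE]
  tally <- structure(
    list(n_input = nrow(products), excluded = as.list(counts),
         n_retained = nrow(retained)),
    class = "exclusion_tally"
  )
  stopifnot(tally$n_retained + sum(counts) == tally$n_input)
  list(products = retained, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusion tally:", x$n_input, "products in\n")
  for (cl in names(x$excluded)) {
    cat(sprintf("  - %-26s %6d\n", cl, x$excluded[[cl]]))
  }
  cat("  retained:", x$n_retained, "\n")
  invisible(x)
}

#' Serialise an exclusion tally as JSON
#'
#' @param tally An `exclusion_tally` from [apply_exclusion_filters()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (or `path`, invisibly, when written to file).
#' @export
exclusion_tally_json <- function(tally, path = NULL) {
  obj <- c(list(n_input = tally$n_input), tally$excluded,
           list(n_retained = tally$n_retained))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  }
}

#' Load the category taxonomy
#'
#' The taxonomy (category names, default physical basis, which categories
#' are reconstitutable and to what basis) is configuration, not code; the
#' shipped file covers the categories used throughout the package and can
#' be replaced.
#'
#' @param path Path to a taxonomy YAML; default is the shipped file.
#' @return Named list of per-category entries.
#' @export
category_taxonomy <- function(path = npm_extdata("categories.yaml")) {
  yaml::read_yaml(path)$categories
}

#' Reconstitute products to their as-consumed form
#'
#' Products in reconstitutable categories (instant mixes, concentrated
#' juices, powdered milks, tea/coffee powders, instant soups) are sold
#' dry or concentrated; their panel is rescaled so values refer to 100 g
#' or ml of the prepared product: each value is multiplied by
#' `reconstitution_factor / 100`, where the factor is grams of product
#' per 100 g/ml as consumed. The basis switches to the category's
#' as-consumed basis and the product is marked `as_consumed`, which makes
#' the operation idempotent. Non-reconstitutable categories pass through
#' unchanged regardless of any factor.
#'
#' @param products Product tibble.
#' @param taxonomy Category taxonomy, see [category_taxonomy()].
#' @return The product tibble with reconstitutable rows rescaled.
#' @export
reconstitute <- function(products, taxonomy = category_taxonomy()) {
  recon_cats <- names(taxonomy)[vapply(taxonomy, function(e) {
    isTRUE(e$reconstitutable)
  }, logical(1))]
  todo <- products$category %in% recon_cats & !products$as_consumed
  if (!any(todo)) return(products)
  no_factor <- todo & is.na(products$reconstitution_factor)
  if (any(no_factor)) {
    abort(sprintf(
      "reconstitutable product(s) without a reconstitution factor: %s",
      paste(head(products$product_id[no_factor], 5), collapse = ", ")
    ))
  }
  scale <- products$reconstitution_factor[todo] / 100
  for (field in PANEL_FIELDS) {
    products[[field]][todo] <- products[[field]][todo] * scale
  }
  products$basis[todo] <- vapply(products$category[todo], function(cat) {
    taxonomy[[cat]]$as_consumed_basis %||% "liquid"
  }, character(1))
  products$as_consumed[todo] <- TRUE
  products
}

#' Share of a daily limit provided by one serving
#'
#' Converts a per-100 g/ml content and a serving size into the percentage
#' of a daily limit one serving supplies, e.g. the grams of sugar in a
#' 350 ml beverage serving against a 50 g/day free-sugar limit.
#'
#' @param value_per_100 Content per 100 g/ml.
#' @param serving_size Serving size in g or ml.
#' @param daily_limit Daily limit in the same unit as `value_per_100`
#'   (default 50, the g/day free-sugar limit for a 2000 kcal diet).
#' @return Percentage of the daily limit (0-100 scale, not clipped).
#' @export
daily_limit_share <- function(value_per_100, serving_size, daily_limit = 50) {
  100 * (value_per_100 * serving_size / 100) / daily_limit
}
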