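# Free-sugar estimation from declared sugars.
#
# Brazilian labels declare neither free nor (usually) added sugars, so
# free sugars are estimated from whatever the panel provides: a declared
# added-sugars value is used directly; a declared total-sugars value is
# multiplied by a category fraction (1.0 for products with no or minimal
# naturally occurring sugars, 0.5 for milk/yogurt gated on an added-sugar
# keyword in the ingredient list). Products declaring neither are
# indeterminate and drop out of sugar-criterion denominators.

#' Load a free-sugar rule table
#'
#' Rules map categories to the fraction of declared sugars counted as
#' free, optionally gated on the presence of an added-sugar keyword.
#' Categories without an explicit rule fall back to the `default` entry
#' (fraction 1 with a keyword, 0 without); a table without a `default`
#' raises a configuration error for unlisted categories at estimation
#' time.
#'
#' @param path Rule YAML; default is the shipped file.
#' @return A `free_sugar_rules` list.
#' @export
default_free_sugar_rules <- function(path = npm_extdata("free_sugar_rules.yaml")) {
  rules <- yaml::read_yaml(path)
  rules$basis <- rules$basis %||% "total"
  if (!rules$basis %in% c("total", "added")) {
    abort("free-sugar rule basis must be 'total' or 'added'")
  }
  for (cat in names(rules$categories)) {
    fr <- rules$categories[[cat]]$fraction
    if (is.null(fr) || fr < 0 || fr > 1) {
      abort(sprintf("free-sugar fraction for category '%s' must be in [0, 1]", cat))
    }
  }
  structure(rules, class = "free_sugar_rules")
}

#' Estimate free sugars per 100 g/ml
#'
#' Implements the category-rule method: when added sugars are declared
#' they are used directly (labels are authoritative); otherwise the
#' declared total sugars are scaled by the category fraction, applied
#' only when the rule's keyword gate is satisfied (no added-sugar keyword
#' under a gated rule means 0 g free, e.g. plain milk whose only sugars
#' are lactose). With `basis: "added"` the category fraction is instead
#' applied to declared added sugars when present. Products declaring no
#' sugar information at all return `NA` (indeterminate).
#'
#' @param products Product tibble.
#' @param findings Findings tibble from [scan_products()] (or any frame
#'   with a logical `has_added_sugar` column aligned with `products`).
#' @param rules A `free_sugar_rules` table, see [default_free_sugar_rules()].
#' @return Numeric vector of free sugars (g/100 g/ml), `NA` where
#'   indeterminate. Always within `[0, declared sugars]`.
#' @export
estimate_free_sugars <- function(products, findings,
                                 rules = default_free_sugar_rules()) {
  n <- nrow(products)
  stopifnot(nrow(findings) == n)
  has_kw <- findings$has_added_sugar
  fraction <- numeric(n)
  gated <- logical(n)
  for (i in seq_len(n)) {
    rule <- rules$categories[[products$category[[i]]]]
    if (!is.null(rule)) {
      fraction[[i]] <- rule$fraction
      gated[[i]] <- isTRUE(rule$requires_added_sugar_keyword)
    } else if (!is.null(rules$default)) {
      fraction[[i]] <- if (has_kw[[i]]) rules$default$fraction_with_keyword
                       else rules$default$fraction_without_keyword
      gated[[i]] <- FALSE
    } else {
      abort(sprintf("no free-sugar rule for category: %s",
                    products$category[[i]]))
    }
  }
  eff_fraction <- ifelse(gated & !has_kw, 0, fraction)
  added <- products$added_sugars_g
  total <- products$total_sugars_g
  if (identical(rules$basis, "added")) {
    free <- ifelse(!is.na(added), added * eff_fraction,
                   ifelse(!is.na(total), total * eff_fraction, NA_real_))
  } else {
    free <- ifelse(!is.na(added), added,
                   ifelse(!is.na(total), total * eff_fraction, NA_real_))
  }
  free
}
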