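# Strictness, cross-classification, Cohen's kappa and NNS prevalence.
#
# Strictness is the share of a food supply a model flags with at least
# one warning; agreement between two models is summarised by the 2x2
# cross-classification of their any-warning (or per-nutrient) outcomes
# and Cohen's chance-corrected kappa. Products with an indeterminate
# outcome never enter a denominator; ineligible products count as "no
# warning" (supply-level percentages are over all classifiable products).

#' Binomial proportion with a 95 % Wald confidence interval
#'
#' `p = k/n` with the Wald interval `p +/- 1.96 * sqrt(p(1-p)/n)`, clipped
#' to `[0, 1]`. The Wilson score interval is available behind `method`.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param method `"wald"` (default) or `"wilson"`.
#' @param z Critical value (default 1.96 for a 95 % interval).
#' @return A list with `p`, `ci_low`, `ci_high`.
#' @export
prop_ci <- function(k, n, method = c("wald", "wilson"), z = 1.96) {
  method <- match.arg(method)
  if (any(n <= 0)) abort("prop_ci: n must be positive")
  p <- k / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- pmax(0, p - half)
    hi <- pmin(1, p + half)
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
  }
  list(p = p, ci_low = lo, ci_high = hi)
}

#' Strictness of a model: proportion flagged, with 95 % CI
#'
#' @param flagged Logical outcome vector (`TRUE` = carries at least one
#'   warning); `NA` marks indeterminate products, which are excluded from
#'   `n` and reported in `n_indeterminate`.
#' @param by Optional stratum factor (e.g. food category) aligned with
#'   `flagged`; strata with no determinable outcome are skipped with a
#'   warning.
#' @param method CI method, see [prop_ci()].
#' @return Tibble with one row per stratum (plus `"overall"` when `by` is
#'   `NULL`): `stratum`, `n`, `k`, `p`, `ci_low`, `ci_high`,
#'   `n_indeterminate`.
#' @export
strictness <- function(flagged, by = NULL, method = "wald") {
  strata <- if (is.null(by)) rep("overall", length(flagged)) else as.character(by)
  rows <- lapply(unique(strata), function(s) {
    x <- flagged[strata == s]
    n <- sum(!is.na(x))
    if (n == 0) {
      warn(sprintf("stratum '%s' has no determinable outcome; skipped", s))
      return(NULL)
    }
    k <- sum(x, na.rm = TRUE)
    ci <- prop_ci(k, n, method = method)
    tibble::tibble(stratum = s, n = n, k = k, p = ci$p,
                   ci_low = ci$ci_low, ci_high = ci$ci_high,
                   n_indeterminate = sum(is.na(x)))
  })
  dplyr::bind_rows(rows)
}

#' Cross-classify two models' outcomes
#'
#' Builds the 2x2 agreement table over products with a determinable
#' outcome under both models (pairwise-complete); pairs with an `NA` on
#' either side are dropped and tallied in the `n_dropped` attribute.
#' Inputs may be logical vectors (aligned by position) or classification
#' tibbles from [classify_products()], which are joined on `product_id`.
#'
#' @param a_results,b_results Outcomes of the two models.
#' @return 2x2 integer matrix `[A: flag/no x B: flag/no]` with attribute
#'   `n_dropped`.
#' @export
cross_classify <- function(a_results, b_results) {
  if (is.data.frame(a_results) && is.data.frame(b_results)) {
    common <- intersect(a_results$product_id, b_results$product_id)
    if (length(common) == 0) abort("cross_classify: disjoint product sets")
    a <- a_results$any_warning[match(common, a_results$product_id)]
    b <- b_results$any_warning[match(common, b_results$product_id)]
  } else {
    a <- a_results
    b <- b_results
    if (length(a) != length(b)) {
      abort("cross_classify: outcome vectors must have equal length")
    }
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  tab <- matrix(
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
    nrow = 2, byrow = TRUE,
    dimnames = list(A = c("flag", "no"), B = c("flag", "no"))
  )
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Cohen's kappa for a 2x2 table
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (a + d)/N` and expected agreement
#' `pe = [(a+b)(a+c) + (c+d)(b+d)] / N^2`. Kappa is undefined (returned
#' as `NA` with `defined = FALSE`) when a row or column margin is zero —
#' i.e. when one of the categories has no observation — or when `pe = 1`.
#'
#' @param table 2x2 matrix (counts `a, b; c, d`) as from
#'   [cross_classify()].
#' @return List with `kappa`, `po`, `pe`, `defined` and `n`.
#' @export
cohen_kappa <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n < 1) abort("cohen_kappa: empty table")
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0) || pe >= 1) {
    return(list(kappa = NA_real_, po = po, pe = pe, defined = FALSE, n = n))
  }
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, defined = TRUE, n = n)
}

#' Interpretation band for a kappa coefficient
#'
#' Bands (boundaries inclusive on the upper end): 0.01-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00
#' almost perfect or perfect. Values at or below zero indicate poor /
#' no agreement; an undefined kappa maps to `"not computable"`.
#'
#' @param kappa Kappa value (`NA` allowed).
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return("not computable")
    if (k <= 0) return("poor")
    if (k <= 0.20) return("slight")
    if (k <= 0.40) return("fair")
    if (k <= 0.60) return("moderate")
    if (k <= 0.80) return("substantial")
    "almost perfect or perfect"
  }, character(1))
}

#' Asymptotic standard error of Cohen's kappa
#'
#' Fleiss-style large-sample standard error for a 2x2 kappa; provided as
#' an option, not used in the default reports (which give point kappas).
#'
#' @param table 2x2 count matrix.
#' @return Standard error (NA when kappa is undefined).
#' @export
cohen_kappa_se <- function(table) {
  k <- cohen_kappa(table)
  if (!k$defined) return(NA_real_)
  sqrt(k$po * (1 - k$po) / (k$n * (1 - k$pe)^2))
}

#' Prevalence of non-nutritive sweeteners
#'
#' Share of products whose ingredient list contains an NNS keyword,
#' overall or by food category.
#'
#' @param products Product tibble.
#' @param findings Findings tibble from [scan_products()].
#' @param by_category Report per category as well as overall?
#' @return Tibble with `stratum`, `n`, `k`, `p` (and a Wald 95 % CI).
#' @export
nns_prevalence <- function(products, findings, by_category = FALSE) {
  stopifnot(nrow(products) == nrow(findings))
  overall <- strictness(findings$has_nns)
  out <- overall
  if (by_category) {
    per_cat <- strictness(findings$has_nns, by = products$category)
    out <- dplyr::bind_rows(overall, per_cat)
  }
  dplyr::select(out, -"n_indeterminate")
}
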