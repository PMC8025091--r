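# End-to-end orchestration: read/generate -> exclusion filters ->
# reconstitution -> ingredient scan -> free-sugar estimation ->
# classification under the selected models -> strictness, agreement and
# NNS reports, with a run manifest whose stage counts telescope.

#' Run the full model-comparison pipeline
#'
#' @param input A product tibble, a CSV path (read with
#'   [read_products()]), or a `supply_spec` (generated on the fly).
#' @param models Character vector of model names or config paths; at
#'   least two are needed for agreement reports (with one, strictness
#'   only).
#' @param vocab Keyword vocabulary, see [default_vocabulary()].
#' @param sugar_rules Free-sugar rules, see [default_free_sugar_rules()].
#' @param taxonomy Category taxonomy for reconstitution.
#' @param agreement_criteria Named list mapping a shared-nutrient label
#'   to the per-model criterion ids used for nutrient-level agreement
#'   (default: sugars, sodium, saturated fat across the shipped models);
#'   set to `list()` to skip.
#' @param by_category Also stratify reports by food category?
#' @param out_dir Optional directory; when given, reports are written as
#'   CSV and the manifest as JSON.
#' @return A list: `manifest`, `strictness` (per model x stratum),
#'   `agreement` (per model pair x outcome x stratum, with kappa and its
#'   band), `nns` (prevalence), `results` (per-model classification
#'   tibbles), `products`, `findings`, `tally`.
#' @export
run_compare <- function(input,
                        models = c("paho", "chile", "anvisa", "modified_paho"),
                        vocab = default_vocabulary(),
                        sugar_rules = default_free_sugar_rules(),
                        taxonomy = category_taxonomy(),
                        agreement_criteria = default_agreement_criteria(),
                        by_category = TRUE,
                        out_dir = NULL) {
  if (length(models) == 0) abort("run_compare: at least one model required")
  configs <- lapply(models, npm_config)
  names(configs) <- vapply(configs, function(cf) cf$name, character(1))

  if (inherits(input, "supply_spec")) {
    input <- generate_supply(input)$products
  } else if (is.character(input) && length(input) == 1) {
    input <- read_products(input)
  }
  n_input <- nrow(input)

  filtered <- apply_exclusion_filters(input)
  products <- reconstitute(filtered$products, taxonomy)
  findings <- scan_products(products, vocab)
  free_sugars <- estimate_free_sugars(products, findings, sugar_rules)

  results <- lapply(configs, function(cf) {
    classify_products(products, cf, findings = findings,
                      free_sugars = free_sugars)
  })

  strict <- dplyr::bind_rows(lapply(names(results), function(m) {
    res <- results[[m]]
    overall <- strictness(res$any_warning)
    out <- overall
    if (by_category) {
      out <- dplyr::bind_rows(
        overall, strictness(res$any_warning, by = products$category))
    }
    dplyr::bind_cols(tibble::tibble(model = m), out)
  }))

  agreement <- NULL
  if (length(results) >= 2) {
    pairs <- utils::combn(names(results), 2, simplify = FALSE)
    agreement <- dplyr::bind_rows(lapply(pairs, function(pr) {
      dplyr::bind_rows(
        pairwise_agreement(results[[pr[1]]], results[[pr[2]]], pr,
                           products, by_category, outcome = "any_warning"),
        nutrient_agreement(results[[pr[1]]], results[[pr[2]]], pr,
                           products, by_category, agreement_criteria)
      )
    }))
  }

  nns <- nns_prevalence(products, findings, by_category = by_category)

  per_model_counts <- lapply(results, function(res) {
    list(n_determinate = sum(!is.na(res$any_warning)),
         n_indeterminate = sum(is.na(res$any_warning)))
  })
  manifest <- list(
    n_input = n_input,
    excluded = filtered$tally$excluded,
    n_retained = filtered$tally$n_retained,
    models = names(results),
    model_config_sha = vapply(configs, config_hash, character(1)),
    per_model = per_model_counts,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  # stage counts must telescope
  stopifnot(manifest$n_retained + sum(unlist(manifest$excluded)) ==
              manifest$n_input)
  for (m in names(per_model_counts)) {
    pc <- per_model_counts[[m]]
    stopifnot(pc$n_determinate + pc$n_indeterminate == manifest$n_retained)
  }

  out <- list(manifest = manifest, strictness = strict,
              agreement = agreement, nns = nns, results = results,
              products = products, findings = findings,
              tally = filtered$tally)
  if (!is.null(out_dir)) write_reports(out, out_dir)
  out
}

#' Default nutrient-level agreement map
#'
#' The shared nutrients comparable across the shipped models, mapped to
#' each model's criterion id: sugars (free or total depending on the
#' model), sodium and saturated fat.
#'
#' @return Named list `outcome label -> (model name -> criterion id)`.
#' @export
default_agreement_criteria <- function() {
  list(
    sugars = c(paho = "free_sugars", modified_paho = "free_sugars",
               anvisa = "free_sugars", chile = "sugars"),
    sodium = c(paho = "sodium", modified_paho = "sodium",
               anvisa = "sodium", chile = "sodium"),
    sat_fat = c(paho = "sat_fat", modified_paho = "sat_fat",
                anvisa = "sat_fat", chile = "sat_fat")
  )
}

# One agreement row set (overall + optional per-category) for a pair of
# aligned outcome vectors.
agreement_rows <- function(a, b, pair, outcome_label, strata, by_category) {
  one <- function(mask, label) {
    tab <- cross_classify(a[mask], b[mask])
    if (sum(tab) == 0) return(NULL)
    kp <- cohen_kappa(tab)
    tibble::tibble(
      model_a = pair[1], model_b = pair[2], outcome = outcome_label,
      stratum = label, n = kp$n,
      both = tab[1, 1], a_only = tab[1, 2], b_only = tab[2, 1],
      neither = tab[2, 2], po = kp$po, pe = kp$pe, kappa = kp$kappa,
      band = interpret_kappa(kp$kappa),
      n_dropped = attr(tab, "n_dropped")
    )
  }
  out <- one(rep(TRUE, length(a)), "overall")
  if (by_category) {
    out <- dplyr::bind_rows(
      out,
      dplyr::bind_rows(lapply(unique(strata), function(s) one(strata == s, s)))
    )
  }
  out
}

pairwise_agreement <- function(res_a, res_b, pair, products, by_category,
                               outcome) {
  agreement_rows(res_a$any_warning, res_b$any_warning, pair, outcome,
                 products$category, by_category)
}

nutrient_agreement <- function(res_a, res_b, pair, products, by_category,
                               criteria_map) {
  dplyr::bind_rows(lapply(names(criteria_map), function(label) {
    map <- criteria_map[[label]]
    if (!all(pair %in% names(map))) return(NULL)
    cols <- paste0("crit_", map[pair])
    if (!cols[1] %in% names(res_a) || !cols[2] %in% names(res_b)) return(NULL)
    a <- criterion_outcome(res_a, map[[pair[1]]])
    b <- criterion_outcome(res_b, map[[pair[2]]])
    agreement_rows(a, b, pair, label, products$category, by_category)
  }))
}

# Stable hash of a model config (so the manifest records exactly which
# rules ran). Plain serialization hash; no crypto intent.
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 4294967291)
}

write_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$strictness, file.path(out_dir, "strictness.csv"))
  if (!is.null(run$agreement)) {
    readr::write_csv(run$agreement, file.path(out_dir, "agreement.csv"))
  }
  readr::write_csv(run$nns, file.path(out_dir, "nns_prevalence.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Text report mirroring the published table layout
#'
#' Renders a strictness table (percentages to one decimal, with 95 % CIs)
#' and, when available, pairwise kappas (two decimals) per stratum, as a
#' plain-text block.
#'
#' @param run Result of [run_compare()].
#' @param stratum Stratum to print (default `"overall"`).
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
format_report <- function(run, stratum = "overall") {
  lines <- c(sprintf("Strictness (%s):", stratum))
  st <- run$strictness[run$strictness$stratum == stratum, ]
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf(
      "  %-14s %5.1f%% (95%% CI %.1f, %.1f)  n=%d",
      st$model[i], 100 * st$p[i], 100 * st$ci_low[i], 100 * st$ci_high[i],
      st$n[i]))
  }
  if (!is.null(run$agreement)) {
    ag <- run$agreement[run$agreement$stratum == stratum &
                          run$agreement$outcome == "any_warning", ]
    if (nrow(ag) > 0) {
      lines <- c(lines, "Agreement (any warning):")
      for (i in seq_len(nrow(ag))) {
        kap <- if (is.na(ag$kappa[i])) "   NA" else sprintf("%5.2f", ag$kappa[i])
        lines <- c(lines, sprintf("  %-14s vs %-14s kappa %s (%s)",
                                  ag$model_a[i], ag$model_b[i], kap, ag$band[i]))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
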