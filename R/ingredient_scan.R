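# Keyword detection of added sugar, added salt, added fat and
# non-nutritive sweeteners (NNS) in Portuguese ingredient lists.
#
# Matching is whole-token on normalized text (substring matching produces
# false positives, e.g. "sal" inside "salsa"); a trailing "*" in a
# vocabulary term marks a prefix stem, and multi-word terms are matched
# as consecutive token sequences.

VOCAB_SETS <- c("added_sugar", "added_salt", "added_fat", "nns")

#' Normalize ingredient-list text
#'
#' Lowercases, strips accents (ç→c, ã→a, ú→u, ...), replaces punctuation
#' by single spaces and collapses whitespace. All keyword matching happens
#' on this normalized form; the shipped vocabulary stores its terms
#' already normalized.
#'
#' @param text Character vector; `NA` is treated as empty.
#' @return Character vector of normalized text.
#' @export
normalize_text <- function(text) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Load a keyword vocabulary
#'
#' A vocabulary holds four term sets (`added_sugar`, `added_salt`,
#' `added_fat`, `nns`) plus optional (default empty) negation lists. The
#' shipped default renders in Portuguese the keyword families used for
#' FOP eligibility searches: sugars (açúcar, mel, xaropes, melaço,
#' maltodextrina, glicose, frutose, sucos concentrados, chocolates, doce
#' de leite), salt (sal, cloreto de sódio, queijos, embutidos), fats
#' (óleos, azeites/azeitonas, manteiga, cremes, gorduras vegetais e
#' animais) and the usual non-nutritive sweeteners. It is plain YAML and
#' user-replaceable.
#'
#' @param path Vocabulary YAML; default is the shipped file.
#' @return A `keyword_vocabulary` (named list of term/negation sets).
#' @export
default_vocabulary <- function(path = npm_extdata("vocabulary.yaml")) {
  raw <- yaml::read_yaml(path)
  missing <- setdiff(VOCAB_SETS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("vocabulary is missing set(s): %s",
                  paste(missing, collapse = ", ")))
  }
  vocab <- lapply(raw[VOCAB_SETS], function(set) {
    terms <- normalize_vocab_terms(unlist(set$terms))
    if (length(terms) == 0) abort("vocabulary term sets must be non-empty")
    list(terms = terms, negations = unlist(set$negations) %||% character(0))
  })
  structure(vocab, class = "keyword_vocabulary")
}

# Normalize terms while preserving the trailing wildcard markers.
normalize_vocab_terms <- function(terms) {
  vapply(terms, function(term) {
    tokens <- strsplit(trimws(term), " +")[[1]]
    wild <- endsWith(tokens, "*")
    tokens <- normalize_text(sub("\\*$", "", tokens))
    paste0(tokens, ifelse(wild, "*", ""), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Regex for one vocabulary term against "normalized text" with word
# boundaries emulated by spaces: token -> exact token, token* -> prefix.
term_regex <- function(term) {
  tokens <- strsplit(term, " ", fixed = TRUE)[[1]]
  pieces <- ifelse(endsWith(tokens, "*"),
                   paste0(substr(tokens, 1, nchar(tokens) - 1), "[a-z0-9]*"),
                   tokens)
  paste0("(?<=^|\\s)", paste(pieces, collapse = " "), "(?=\\s|$)")
}

#' Scan ingredient text for keyword matches
#'
#' Detects added sugar, added salt, added fat and NNS in free-text
#' ingredient lists. A flag is true iff at least one vocabulary term of
#' its set matches the normalized text; every match is reported with its
#' keyword and character offset (1-based, in the normalized text) for
#' audit. Deterministic, and monotone in the text: appending ingredients
#' can only add matches.
#'
#' @param text Character vector of ingredient lists (raw, un-normalized).
#' @param vocab A `keyword_vocabulary`, see [default_vocabulary()].
#' @return A tibble with one row per element of `text`: logical columns
#'   `has_added_sugar`, `has_added_salt`, `has_added_fat`, `has_nns` and a
#'   `matches` list-column of per-text match tables (set, keyword, offset).
#' @export
scan_ingredients <- function(text, vocab = default_vocabulary()) {
  norm <- normalize_text(text)
  n <- length(norm)
  flags <- matrix(FALSE, nrow = n, ncol = length(VOCAB_SETS),
                  dimnames = list(NULL, VOCAB_SETS))
  m_idx <- integer(0)
  m_set <- m_kw <- character(0)
  m_off <- integer(0)
  for (set in VOCAB_SETS) {
    for (term in vocab[[set]]$terms) {
      rx <- term_regex(term)
      hit_idx <- which(stringi::stri_detect_regex(norm, rx))
      if (length(hit_idx) == 0) next
      flags[hit_idx, set] <- TRUE
      locs <- stringi::stri_locate_all_regex(norm[hit_idx], rx)
      counts <- vapply(locs, nrow, integer(1))
      m_idx <- c(m_idx, rep(hit_idx, counts))
      m_set <- c(m_set, rep(set, sum(counts)))
      m_kw <- c(m_kw, rep(term, sum(counts)))
      m_off <- c(m_off, unlist(lapply(locs, function(l) as.integer(l[, 1]))))
    }
  }
  empty_match <- tibble::tibble(set = character(0), keyword = character(0),
                                offset = integer(0))
  matches <- rep(list(empty_match), n)
  if (length(m_idx) > 0) {
    long <- tibble::tibble(set = m_set, keyword = m_kw, offset = m_off)
    by_text <- split(seq_along(m_idx), m_idx)
    for (key in names(by_text)) {
      matches[[as.integer(key)]] <- long[by_text[[key]], ]
    }
  }
  tibble::tibble(
    has_added_sugar = flags[, "added_sugar"],
    has_added_salt = flags[, "added_salt"],
    has_added_fat = flags[, "added_fat"],
    has_nns = flags[, "nns"],
    matches = matches
  )
}

#' Scan a product table's ingredient lists
#'
#' Convenience wrapper around [scan_ingredients()] keyed by `product_id`.
#'
#' @param products Product tibble.
#' @param vocab A `keyword_vocabulary`.
#' @return Findings tibble with a leading `product_id` column.
#' @export
scan_products <- function(products, vocab = default_vocabulary()) {
  findings <- scan_ingredients(products$ingredient_text, vocab)
  dplyr::bind_cols(tibble::tibble(product_id = products$product_id), findings)
}
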