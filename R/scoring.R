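# Penalized transformation-based similarity scoring for bilingual
# translation pairs.

#' Scoring configuration
#'
#' Holds the penalty weights, the tokenization penalty, the
#' classification cutoff and the per-language text resources used by
#' the similarity score. Defaults are the calibrated production values:
#' character transforms cost little because they rarely change meaning
#' (`char_weight` = 0.02), word transforms cost more
#' (`word_weight` = 0.05), and moving from whole-string to word-level
#' comparison costs a flat tokenization penalty (`token_penalty` =
#' 0.15). Final averaged scores are compared against `cutoff` = 0.75.
#'
#' The configuration must leave the maximum achievable total penalty
#' below 1 so that scores can never go negative:
#' `token_penalty + 3 * word_weight + max_char * char_weight < 1`.
#'
#' @param char_weight Penalty per character-transform type applied.
#' @param word_weight Penalty per word-transform type applied.
#' @param token_penalty Flat penalty for word tokenization.
#' @param cutoff Classification threshold, strictly between 0 and 1.
#' @param stopwords Named list of per-language stopword vectors;
#'   defaults to the shipped English/Spanish lists.
#' @param transforms Character vector of enabled transform identifiers;
#'   defaults to all of them.
#' @return An object of class `score_config`.
#' @examples
#' cfg <- score_config()
#' cfg$cutoff
#' @export
score_config <- function(char_weight = 0.02, word_weight = 0.05,
                         token_penalty = 0.15, cutoff = 0.75,
                         stopwords = NULL, transforms = NULL) {
  if (char_weight < 0 || word_weight < 0 || token_penalty < 0) {
    stop("penalty weights must be non-negative", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be strictly between 0 and 1", call. = FALSE)
  }
  max_penalty <- token_penalty +
    length(WORD_TRANSFORMS) * word_weight +
    length(CHAR_TRANSFORMS) * char_weight
  if (max_penalty >= 1) {
    stop("maximum total penalty (", format(max_penalty),
         ") must be < 1 to keep scores non-negative", call. = FALSE)
  }
  if (is.null(stopwords)) stopwords <- .default_stopwords
  if (is.null(transforms)) transforms <- c(CHAR_TRANSFORMS, WORD_TRANSFORMS)
  structure(
    list(char_weight = char_weight, word_weight = word_weight,
         token_penalty = token_penalty, cutoff = cutoff,
         stopwords = stopwords, transforms = transforms,
         stemmer = c(en = "porter2", es = "snowball-spanish")),
    class = "score_config"
  )
}

#' @export
print.score_config <- function(x, ...) {
  cat("<score_config>\n",
      "  char_weight:   ", x$char_weight, "\n",
      "  word_weight:   ", x$word_weight, "\n",
      "  token_penalty: ", x$token_penalty, "\n",
      "  cutoff:        ", x$cutoff, "\n", sep = "")
  invisible(x)
}

#' Percent of matching words between two token sequences
#'
#' Order-insensitive multiset overlap: the size of the multiset
#' intersection divided by the larger of the two token counts. Two
#' empty sequences match perfectly (1); an empty against a non-empty
#' sequence scores 0. Symmetric in its arguments.
#'
#' @param tokens_a,tokens_b Character vectors of tokens.
#' @return A fraction in `[0, 1]`.
#' @examples
#' percent_word_match(c("breast", "lobular", "carcinoma"),
#'                    c("lobular", "breast", "carcinoma"))  # 1
#' percent_word_match("daltonismo", c("daltonismo", "rojo")) # 0.5
#' @export
percent_word_match <- function(tokens_a, tokens_b) {
  na <- length(tokens_a)
  nb <- length(tokens_b)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  u <- unique(c(tokens_a, tokens_b))
  ca <- tabulate(match(tokens_a, u), nbins = length(u))
  cb <- tabulate(match(tokens_b, u), nbins = length(u))
  sum(pmin(ca, cb)) / max(na, nb)
}

#' Similarity score from match fraction and penalty counts
#'
#' Implements the penalized score
#' \deqn{S = W_{pct} - W_{pct} (t \cdot 1[\mathrm{tokenized}]
#'   + W_n W_{wt} + C_n C_{wt})}
#' where \eqn{W_{pct}} is the fraction of matching words, \eqn{t} the
#' tokenization penalty, and \eqn{W_n}, \eqn{C_n} the number of word-
#' and character-transform types applied. All penalties scale with
#' \eqn{W_{pct}}, so the score can never go negative and penalties
#' shrink as the match worsens.
#'
#' @param w_pct Fraction of matching words, 0 to 1.
#' @param tokenized Was word tokenization applied?
#' @param w_n Number of word-transform types applied.
#' @param c_n Number of character-transform types applied.
#' @param config A [score_config()].
#' @return The similarity score, between 0 and `w_pct`.
#' @examples
#' score_match(1, TRUE, 1, 1, score_config())   # 0.78
#' score_match(1, FALSE, 0, 1, score_config())  # 0.98
#' @export
score_match <- function(w_pct, tokenized, w_n, c_n,
                        config = score_config()) {
  stopifnot(w_pct >= 0, w_pct <= 1, w_n >= 0, c_n >= 0)
  penalty <- config$token_penalty * as.numeric(isTRUE(tokenized)) +
    w_n * config$word_weight + c_n * config$char_weight
  w_pct - w_pct * penalty
}

# Enumerate every admissible transformation set restricted to the
# enabled transform identifiers in `config`. Untokenized: all subsets
# of the character transforms. Tokenized: all subsets of the character
# transforms except space_removal, crossed with all subsets of the word
# transforms.
.enumerate_transform_sets <- function(config = score_config()) {
  subsets <- function(ids) {
    out <- list(character())
    for (id in ids) out <- c(out, lapply(out, function(s) c(s, id)))
    out
  }
  chars <- intersect(CHAR_TRANSFORMS, config$transforms)
  words <- intersect(WORD_TRANSFORMS, config$transforms)
  res <- lapply(subsets(chars), function(cs) {
    transformation_set(cs, character(), tokenized = FALSE)
  })
  chars_tok <- setdiff(chars, "space_removal")
  for (cs in subsets(chars_tok)) {
    for (ws in subsets(words)) {
      res[[length(res) + 1L]] <-
        transformation_set(cs, ws, tokenized = TRUE)
    }
  }
  res
}

#' Best transformation match between two texts
#'
#' Exhaustively enumerates every admissible transformation set (all
#' subsets of the character transforms for whole-string comparison,
#' plus all character-by-word transform combinations under
#' tokenization), applies each identically to both texts, and returns
#' the result with the maximum penalized score. Untokenized
#' comparisons are all-or-nothing: the word match fraction is 1 when
#' the transformed strings are equal and 0 otherwise. Ties are broken
#' deterministically: fewer total transforms, then fewer word
#' transforms, then lexicographic order of the applied identifiers.
#'
#' @param text_a,text_b The two texts to compare.
#' @param language ISO 639 tag ("en" or "es") selecting stemmer and
#'   stopword list.
#' @param config A [score_config()].
#' @return A list of class `match_result` with fields `w_pct`,
#'   `tokenized`, `w_n`, `c_n`, `score` and `applied`.
#' @examples
#' best_match("Ross River fever", "ross river fever", "en")$score  # 0.98
#' @export
best_match <- function(text_a, text_b, language = "en",
                       config = score_config()) {
  stopifnot(is.character(text_a), is.character(text_b),
            length(text_a) == 1L, length(text_b) == 1L)
  a <- .nfc(text_a)
  b <- .nfc(text_b)

  identity_ts <- transformation_set()
  if (identical(a, b)) {
    # a raw exact match cannot be beaten: score 1, empty set
    return(structure(list(w_pct = 1, tokenized = FALSE, w_n = 0L,
                          c_n = 0L, score = 1, applied = identity_ts),
                     class = "match_result"))
  }

  chars_enabled <- intersect(CHAR_TRANSFORMS, config$transforms)
  words_enabled <- intersect(WORD_TRANSFORMS, config$transforms)

  # Prune transforms that are no-ops on both sides in every context: a
  # no-op only adds penalty, so the exhaustive search could never
  # select it. The one interaction to respect: a no-op `case` still
  # switches roman-numeral matching to case-insensitive, so `case` is
  # kept whenever that changes anything.
  deacc <- function(x) apply_char_transform(x, "diacritic")
  both <- c(a, b)
  if ("diacritic" %in% chars_enabled &&
      !any(stringi::stri_detect_regex(stringi::stri_trans_nfd(both),
                                      "\\p{Mn}"))) {
    chars_enabled <- setdiff(chars_enabled, "diacritic")
  }
  if ("numeral" %in% chars_enabled) {
    da <- deacc(both)
    if (identical(.replace_roman_runs(da, TRUE), da)) {
      chars_enabled <- setdiff(chars_enabled, "numeral")
    }
  }
  if ("case" %in% chars_enabled &&
      identical(stringi::stri_trans_tolower(both), both) &&
      (!("numeral" %in% chars_enabled) ||
         identical(.replace_roman_runs(both, TRUE),
                   .replace_roman_runs(both, FALSE)))) {
    chars_enabled <- setdiff(chars_enabled, "case")
  }
  has_punct <- any(stringi::stri_detect_regex(both, "\\p{P}"))
  if (!has_punct) {
    chars_enabled <- setdiff(chars_enabled, "punct_removal")
    words_enabled <- setdiff(words_enabled, "punct_split")
  }
  if (!any(stringi::stri_detect_regex(both, "\\s"))) {
    chars_enabled <- setdiff(chars_enabled, "space_removal")
  }
  # conservative token superset for the word-level no-op tests: every
  # lower-cased token under both split modes, with punctuation- and
  # diacritic-stripped variants
  tok_superset <- unique(stringi::stri_trans_tolower(
    c(tokenize(a, TRUE), tokenize(b, TRUE),
      tokenize(a, FALSE), tokenize(b, FALSE))))
  tok_superset <- unique(c(tok_superset, deacc(tok_superset),
                           apply_char_transform(tok_superset,
                                                "punct_removal")))
  tok_superset <- tok_superset[nzchar(tok_superset)]
  stopw_cfg <- config$stopwords[[language]]
  if ("stopword_removal" %in% words_enabled && !is.null(stopw_cfg) &&
      !any(deacc(tok_superset) %in% deacc(stopw_cfg))) {
    words_enabled <- setdiff(words_enabled, "stopword_removal")
  }
  if ("stemming" %in% words_enabled &&
      identical(stem(tok_superset, language), tok_superset)) {
    words_enabled <- setdiff(words_enabled, "stemming")
  }

  char_order <- intersect(
    c("case", "diacritic", "numeral", "punct_removal", "space_removal"),
    chars_enabled)

  # expand all char subsets of `ids`, applying each transform once per
  # node to the cached parent value (canonical order is preserved
  # because subsets grow in canonical id order); works on whole
  # strings and on token vectors alike
  char_variants <- function(x, ids) {
    acc <- list(list(ids = character(), value = x))
    for (id in ids) {
      grown <- lapply(acc, function(e) {
        list(ids = c(e$ids, id),
             value = apply_char_transform(
               e$value, id,
               case_insensitive_numerals = "case" %in% e$ids))
      })
      acc <- c(acc, grown)
    }
    acc
  }

  word_subsets <- local({
    out <- list(character())
    for (id in intersect(c("stemming", "stopword_removal", "punct_split"),
                         words_enabled)) {
      out <- c(out, lapply(out, function(s) c(s, id)))
    }
    out
  })
  stopw <- config$stopwords[[language]]

  # every tokenized variant of one side, keyed by signature
  side_variants <- function(text) {
    env <- new.env(parent = emptyenv())
    for (ps in unique(c(FALSE, "punct_split" %in% words_enabled))) {
      toks0 <- tokenize(text, punct_split = ps)
      for (cv in char_variants(toks0, setdiff(char_order, "space_removal"))) {
        toks1 <- cv$value[nzchar(cv$value)]
        for (sw in unique(c(FALSE, "stopword_removal" %in% words_enabled))) {
          toks2 <- if (sw) {
            if (is.null(stopw)) {
              stop("no stopword list configured for language: ", language,
                   call. = FALSE)
            }
            toks1[!(toks1 %in% stopw)]
          } else toks1
          for (st in unique(c(FALSE, "stemming" %in% words_enabled))) {
            toks3 <- if (st) stem(toks2, language) else toks2
            key <- paste(c(ps, sw, st, cv$ids), collapse = "|")
            assign(key, toks3, envir = env)
          }
        }
      }
    }
    env
  }

  results <- list()
  push <- function(ts, w_pct) {
    w_n <- length(ts$word_transforms)
    c_n <- length(ts$char_transforms)
    results[[length(results) + 1L]] <<- list(
      w_pct = w_pct, tokenized = ts$tokenized, w_n = w_n, c_n = c_n,
      score = score_match(w_pct, ts$tokenized, w_n, c_n, config),
      applied = ts)
  }

  # validation-free constructor for enumerated (known-admissible) sets
  ts_new <- function(cs, ws, tok) {
    structure(list(char_transforms = cs, word_transforms = ws,
                   tokenized = tok),
              class = "transformation_set")
  }

  # untokenized: all-or-nothing whole-string comparison
  va <- char_variants(a, char_order)
  vb <- char_variants(b, char_order)
  for (i in seq_along(va)) {
    ts <- ts_new(va[[i]]$ids, character(), FALSE)
    push(ts, as.numeric(identical(va[[i]]$value, vb[[i]]$value)))
  }

  # tokenized combinations
  ea <- side_variants(a)
  eb <- side_variants(b)
  tok_chars <- setdiff(char_order, "space_removal")
  char_sub <- local({
    out <- list(character())
    for (id in tok_chars) out <- c(out, lapply(out, function(s) c(s, id)))
    out
  })
  for (cs in char_sub) {
    for (ws in word_subsets) {
      key <- paste(c("punct_split" %in% ws, "stopword_removal" %in% ws,
                     "stemming" %in% ws, cs), collapse = "|")
      ts <- ts_new(cs, ws, TRUE)
      push(ts, percent_word_match(get(key, envir = ea),
                                  get(key, envir = eb)))
    }
  }

  # maximum score; deterministic tie-break: fewer total transforms,
  # then fewer word transforms, then lexicographic identifier order
  best <- results[[1L]]
  best_key <- NULL
  key_of <- function(r) {
    list(score = r$score,
         n_total = r$c_n + r$w_n + as.integer(r$tokenized),
         n_word = r$w_n, ids = format(r$applied))
  }
  best_key <- key_of(best)
  for (r in results[-1L]) {
    k <- key_of(r)
    better <- k$score > best_key$score + 1e-12 ||
      (abs(k$score - best_key$score) <= 1e-12 &&
         (k$n_total < best_key$n_total ||
            (k$n_total == best_key$n_total &&
               (k$n_word < best_key$n_word ||
                  (k$n_word == best_key$n_word && k$ids < best_key$ids)))))
    if (better) {
      best <- r
      best_key <- k
    }
  }
  class(best) <- "match_result"
  best
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> score=%.4f w_pct=%.4f [%s]\n",
              x$score, x$w_pct, format(x$applied)))
  invisible(x)
}

#' Classify a final (averaged) similarity score
#'
#' `exact` when the score is 1 (only possible when both language pairs
#' are raw exact matches), `passed` when strictly above the cutoff,
#' `pending` (flagged for manual review) at or below the cutoff.
#'
#' @param final_score Averaged similarity score in `[0, 1]`.
#' @param config A [score_config()].
#' @return One of `"exact"`, `"passed"`, `"pending"`.
#' @examples
#' classify(0.88)  # "passed"
#' classify(0.75)  # "pending"
#' @export
classify <- function(final_score, config = score_config()) {
  stopifnot(final_score >= 0, final_score <= 1 + 1e-12)
  if (final_score >= 1) {
    "exact"
  } else if (final_score > config$cutoff) {
    "passed"
  } else {
    "pending"
  }
}

#' Score and classify one translation unit
#'
#' A translation unit carries four texts: the source-language ontology
#' text, the professional translation, the machine forward translation
#' of the source, and the machine backtranslation of the professional
#' translation. Two language-paired comparisons are scored with
#' [best_match()]: the English pair (source text vs backtranslation)
#' and the Spanish pair (professional vs machine forward translation).
#' The two best scores are averaged and classified against the cutoff.
#'
#' @param unit A list or one-row data.frame with fields `source_text`,
#'   `professional_text`, `machine_forward_text`, `machine_back_text`,
#'   and optionally `source_lang` (default "en") and `translation_lang`
#'   (default "es").
#' @param config A [score_config()].
#' @return A list of class `classified_translation` with `en_result`,
#'   `es_result`, `final_score` and `category`.
#' @examples
#' u <- list(source_text = "Ross River fever",
#'           professional_text = "fiebre del río de Ross",
#'           machine_forward_text = "Fiebre del río Ross",
#'           machine_back_text = "ross river fever")
#' score_translation_unit(u)$final_score  # 0.88
#' @export
score_translation_unit <- function(unit, config = score_config()) {
  unit <- as.list(unit)
  needed <- c("source_text", "professional_text",
              "machine_forward_text", "machine_back_text")
  for (f in needed) {
    if (is.null(unit[[f]]) || is.na(unit[[f]])) {
      stop("incomplete translation unit: missing text field '", f, "'",
           call. = FALSE)
    }
  }
  src_lang <- if (!is.null(unit$source_lang)) unit$source_lang else "en"
  trg_lang <- if (!is.null(unit$translation_lang)) unit$translation_lang else "es"
  en_result <- best_match(unit$source_text, unit$machine_back_text,
                          language = src_lang, config = config)
  es_result <- best_match(unit$professional_text, unit$machine_forward_text,
                          language = trg_lang, config = config)
  final_score <- (en_result$score + es_result$score) / 2
  structure(
    list(subject_id = unit$subject_id, predicate_id = unit$predicate_id,
         en_result = en_result, es_result = es_result,
         final_score = final_score,
         category = classify(final_score, config)),
    class = "classified_translation"
  )
}

#' @export
print.classified_translation <- function(x, ...) {
  cat(sprintf("<classified_translation> %s en=%.2f es=%.2f final=%.2f\n",
              x$category, x$en_result$score, x$es_result$score,
              x$final_score))
  invisible(x)
}

#' Score a table of translation units
#'
#' Vectorized driver for [score_translation_unit()] over a unit table
#' (as read by [read_units()]). Appends the scoring columns used by
#' the ledger workflow.
#'
#' @param units Data frame of translation units.
#' @param config A [score_config()].
#' @return `units` with columns `en_score`, `es_score`, `final_score`,
#'   `category`, `en_transforms`, `es_transforms` appended.
#' @export
score_units <- function(units, config = score_config()) {
  n <- nrow(units)
  en_score <- es_score <- final_score <- numeric(n)
  category <- en_transforms <- es_transforms <- character(n)
  for (i in seq_len(n)) {
    ct <- score_translation_unit(units[i, , drop = FALSE], config)
    en_score[i] <- ct$en_result$score
    es_score[i] <- ct$es_result$score
    final_score[i] <- ct$final_score
    category[i] <- ct$category
    en_transforms[i] <- format(ct$en_result$applied)
    es_transforms[i] <- format(ct$es_result$applied)
  }
  units$en_score <- en_score
  units$es_score <- es_score
  units$final_score <- final_score
  units$category <- category
  units$en_transforms <- en_transforms
  units$es_transforms <- es_transforms
  units
}
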