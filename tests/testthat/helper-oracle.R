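# Independent naive oracle for the transformation search, and random
# pair generators for the property suites.
#
# The oracle enumerates every admissible transformation set by bitmask
# and evaluates it through the exported primitives normalize_pair(),
# percent_word_match() and score_match(); it shares no code with the
# optimized search path inside best_match().

oracle_char_ids <- c("case", "numeral", "diacritic", "space_removal",
                     "punct_removal")
oracle_word_ids <- c("stemming", "stopword_removal", "punct_split")

bit_subsets <- function(ids) {
  n <- length(ids)
  lapply(seq_len(2^n) - 1L, function(mask) {
    ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
  })
}

oracle_best_score <- function(text_a, text_b, language,
                              config = score_config()) {
  best <- -Inf
  for (cs in bit_subsets(oracle_char_ids)) {
    ts <- transformation_set(cs, character(), tokenized = FALSE)
    np <- normalize_pair(text_a, text_b, ts, config, language)
    w <- as.numeric(identical(np$side_a, np$side_b))
    best <- max(best, score_match(w, FALSE, 0, length(cs), config))
  }
  for (cs in bit_subsets(setdiff(oracle_char_ids, "space_removal"))) {
    for (ws in bit_subsets(oracle_word_ids)) {
      ts <- transformation_set(cs, ws, tokenized = TRUE)
      np <- normalize_pair(text_a, text_b, ts, config, language)
      w <- percent_word_match(np$side_a, np$side_b)
      best <- max(best, score_match(w, TRUE, length(ws), length(cs),
                                    config))
    }
  }
  best
}

# random short bilingual-ish text pairs exercising every perturbation
# class the transforms can (and cannot) recover
random_pair <- function() {
  vocab <- list(
    en = c("breast", "lobular", "carcinoma", "fever", "type", "of",
           "the", "Ross", "acute", "IV", "46", "syndrome"),
    es = c("fiebre", "del", "río", "de", "Ross", "síndrome", "tipo",
           "aguda", "V", "5", "mama", "la"))
  lang <- sample(c("en", "es"), 1L)
  words <- vocab[[lang]]
  n <- sample(1:4, 1L)
  base <- sample(words, n, replace = TRUE)
  mutate <- function(tk) {
    if (runif(1) < 0.3 && length(tk) > 1L) tk <- sample(tk)
    if (runif(1) < 0.3) tk <- c(tk, sample(words, 1L))
    if (runif(1) < 0.3 && length(tk) > 1L) tk <- tk[-1L]
    if (runif(1) < 0.4) {
      i <- sample.int(length(tk), 1L)
      tk[i] <- if (runif(1) < 0.5) toupper(tk[i]) else tolower(tk[i])
    }
    txt <- paste(tk, collapse = " ")
    if (runif(1) < 0.2) txt <- sub(" ", ", ", txt, fixed = TRUE)
    if (runif(1) < 0.2) txt <- apply_char_transform(txt, "diacritic")
    txt
  }
  list(a = mutate(base), b = mutate(base), language = lang)
}

# worked-example translation unit used across several test files
worked_unit <- function() {
  list(subject_id = "DOID:0050518", predicate_id = "label",
       source_lang = "en", source_text = "Ross River fever",
       translation_lang = "es",
       professional_text = "fiebre del río de Ross",
       machine_forward_text = "Fiebre del río Ross",
       machine_back_text = "ross river fever")
}

worked_unit_df <- function() {
  as.data.frame(worked_unit(), stringsAsFactors = FALSE)
}

# small ledger fixture built in code
ledger_fixture <- function() {
  data.frame(
    subject_id = c("DOID:0050518", "DOID:0001816", "DOID:14566"),
    predicate_id = c("label", "label", "definition"),
    source_lang = "en",
    source_text = c("Ross River fever", "angiosarcoma",
                    "A disease of cellular proliferation."),
    target_lang = "es",
    target_text = c("fiebre del río de Ross", "angiosarcoma",
                    "Una enfermedad de proliferación celular."),
    status = c("passed", "exact", "pending"),
    score = c("0.88", "1", "0.6"),
    acronym = "FALSE",
    reviewer = "",
    review_date = "",
    method = "professional",
    stringsAsFactors = FALSE)
}
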