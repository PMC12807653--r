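# Seeded synthetic bilingual corpus generator.
#
# Emulates professional/machine translation pairs with controlled
# perturbations so the scorer, calibrator and ledger can be exercised
# end-to-end without any ontology export or translation service. The
# built-in lexicon is intentionally tiny and bijective so that
# backtranslation is a well-defined deterministic map; it is a
# modeling simplification of a real machine-translation service.

# bijective English <-> Spanish content lexicon (disease-name grammar)
.lexicon <- local({
  en <- c(
    # anatomy
    "breast", "lung", "liver", "kidney", "heart", "brain", "skin",
    "bone", "muscle", "blood", "eye", "stomach", "pancreas", "bladder",
    "ovary", "prostate", "colon", "thyroid", "nerve", "spine",
    # disorders
    "fever", "syndrome", "disease", "cancer", "carcinoma", "lymphoma",
    "anemia", "dystrophy", "atrophy", "fibrosis", "stenosis",
    "sclerosis", "deficiency", "infection", "inflammation", "dysplasia",
    "neuropathy", "myopathy", "malformation", "insufficiency",
    # modifiers
    "chronic", "acute", "congenital", "hereditary", "infantile",
    "juvenile", "lobular", "primary", "secondary", "severe", "benign",
    "malignant",
    # structural
    "type")
  es <- c(
    "mama", "pulmón", "hígado", "riñón", "corazón", "cerebro", "piel",
    "hueso", "músculo", "sangre", "ojo", "estómago", "páncreas",
    "vejiga", "ovario", "próstata", "colon", "tiroides", "nervio",
    "columna",
    "fiebre", "síndrome", "enfermedad", "cáncer", "carcinoma",
    "linfoma", "anemia", "distrofia", "atrofia", "fibrosis",
    "estenosis", "esclerosis", "deficiencia", "infección",
    "inflamación", "displasia", "neuropatía", "miopatía",
    "malformación", "insuficiencia",
    "crónica", "aguda", "congénita", "hereditaria", "infantil",
    "juvenil", "lobular", "primaria", "secundaria", "grave", "benigna",
    "maligna",
    "tipo")
  stopifnot(!anyDuplicated(en), !anyDuplicated(es),
            length(en) == length(es))
  list(en = en, es = es,
       anatomy = 1:20, disorder = 21:40, modifier = 41:52)
})

# accent/case-insensitive lookup key
.lex_key <- function(x) {
  stringi::stri_trans_tolower(
    stringi::stri_replace_all_regex(stringi::stri_trans_nfd(x),
                                    "\\p{Mn}", ""))
}

#' Synthetic bilingual lexicon
#'
#' The built-in bijective English/Spanish content-word lexicon used by
#' the synthetic corpus generator.
#'
#' @return Data frame with columns `en` and `es`.
#' @export
synth_lexicon <- function() {
  data.frame(en = .lexicon$en, es = .lexicon$es,
             stringsAsFactors = FALSE)
}

.render_en <- function(struct) {
  parts <- c(struct$modifier, struct$anatomy, struct$disorder)
  if (!is.null(struct$type_num)) {
    parts <- c(parts, "type", as.character(struct$type_num))
  }
  paste(parts, collapse = " ")
}

# Spanish rendering: disorder first, optional modifier, then
# "de <anatomy>"; the type phrase trails. The back-map inverts this.
.render_es <- function(struct) {
  lex <- .lexicon
  to_es <- function(w) lex$es[match(w, lex$en)]
  parts <- c(to_es(struct$disorder), to_es(struct$modifier), "de",
             to_es(struct$anatomy))
  if (!is.null(struct$type_num)) {
    parts <- c(parts, "tipo", as.character(struct$type_num))
  }
  paste(parts, collapse = " ")
}

#' Deterministic lexicon backtranslation
#'
#' Maps a Spanish text back to English through the bijective built-in
#' lexicon: tokens are matched case- and accent-insensitively, Spanish
#' function words are dropped, a trailing "tipo N" phrase becomes
#' "type N", and the leading content word (the disorder in the
#' generator's grammar) is rotated to the end to restore English noun
#' order. Tokens absent from the lexicon pass through unchanged.
#'
#' @param text Spanish text (single string).
#' @return English text.
#' @examples
#' lexicon_backtranslate("fiebre de mama")  # "breast fever"
#' @export
lexicon_backtranslate <- function(text) {
  lex <- .lexicon
  toks <- tokenize(text, punct_split = TRUE)
  if (!length(toks)) return("")
  toks <- toks[!(.lex_key(toks) %in% .default_stopwords$es)]
  if (!length(toks)) return("")
  mapped <- vapply(toks, function(tk) {
    i <- match(.lex_key(tk), .lex_key(lex$es))
    if (is.na(i)) tk else lex$en[i]
  }, "", USE.NAMES = FALSE)
  # split a trailing "type <number>" phrase off before reordering
  tail_part <- character()
  if (length(mapped) >= 2L &&
      mapped[length(mapped) - 1L] == "type" &&
      grepl("^[0-9]+$", mapped[length(mapped)])) {
    tail_part <- mapped[(length(mapped) - 1L):length(mapped)]
    mapped <- mapped[seq_len(length(mapped) - 2L)]
  }
  if (length(mapped) > 1L) {
    mapped <- c(mapped[-1L], mapped[1L])
  }
  paste(c(mapped, tail_part), collapse = " ")
}

#' Generate one synthetic bilingual term pair
#'
#' Draws from a small grammar of disease-like names: optional modifier,
#' anatomy word, disorder word, optional "type <numeral>" slot, with
#' the deterministic bilingual lexicon supplying the Spanish reference
#' rendering. Uses the current RNG stream.
#'
#' @return List with `source` (English), `reference` (Spanish) and the
#'   underlying `struct`.
#' @export
generate_term <- function() {
  lex <- .lexicon
  struct <- list(
    modifier = if (stats::runif(1) < 0.4)
      lex$en[sample(lex$modifier, 1L)] else NULL,
    anatomy = lex$en[sample(lex$anatomy, 1L)],
    disorder = lex$en[sample(lex$disorder, 1L)],
    type_num = if (stats::runif(1) < 0.3) sample(1:12, 1L) else NULL)
  list(source = .render_en(struct), reference = .render_es(struct),
       struct = struct)
}

#' Perturbation profile for the synthetic corpus
#'
#' Independent application probabilities for each perturbation class.
#' All classes except `substitution` mirror transformation-recoverable
#' error classes (letter case, diacritics, stopwords, word order,
#' numeral style, punctuation, whitespace); `substitution` swaps a
#' content word for a different lexicon word and is meaning-changing.
#'
#' @param case,diacritic,stopword,reorder,numeral,punct,whitespace,substitution
#'   Probabilities in `[0, 1]`.
#' @return A list of class `perturbation_profile`.
#' @export
perturbation_profile <- function(case = 0.3, diacritic = 0.2,
                                 stopword = 0.3, reorder = 0.15,
                                 numeral = 0.15, punct = 0.1,
                                 whitespace = 0.1, substitution = 0) {
  p <- list(case = case, diacritic = diacritic, stopword = stopword,
            reorder = reorder, numeral = numeral, punct = punct,
            whitespace = whitespace, substitution = substitution)
  bad <- vapply(p, function(v) v < 0 || v > 1, logical(1))
  if (any(bad)) {
    stop("perturbation probabilities must lie in [0, 1]: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "perturbation_profile")
}

.int_to_roman <- function(n) as.character(utils::as.roman(n))

# replace one content token with a different lexicon word; guaranteed
# to change the text, or NULL when no content token exists
.substitute_token <- function(text, language) {
  tk <- tokenize(text, punct_split = FALSE)
  content <- which(!(.lex_key(tk) %in% .default_stopwords[[language]]) &
                     nchar(tk) > 3L)
  if (!length(content)) return(NULL)
  i <- content[sample.int(length(content), 1L)]
  lex_col <- .lexicon[[language]]
  choices <- lex_col[.lex_key(lex_col) != .lex_key(tk[i])]
  tk[i] <- choices[sample.int(length(choices), 1L)]
  paste(tk, collapse = " ")
}

#' Apply random perturbations to one text
#'
#' Each perturbation class in the profile is applied independently
#' with its probability, in a fixed order, using the current RNG
#' stream. Returns the perturbed text and a log of the classes that
#' actually changed the text.
#'
#' @param text Input text (single string).
#' @param profile A [perturbation_profile()].
#' @param language ISO 639 tag governing stopword/substitution choices.
#' @return List with `text` and `log` (character vector of applied
#'   perturbation classes).
#' @export
perturb <- function(text, profile, language = "es") {
  stopifnot(inherits(profile, "perturbation_profile"))
  log <- character()
  stopwords <- .default_stopwords[[language]]

  toks <- function(x) tokenize(x, punct_split = FALSE)

  if (stats::runif(1) < profile$substitution) {
    sub <- .substitute_token(text, language)
    if (!is.null(sub)) {
      text <- sub
      log <- c(log, "substitution")
    }
  }
  if (stats::runif(1) < profile$case) {
    tk <- toks(text)
    if (length(tk)) {
      i <- sample.int(length(tk), 1L)
      first <- substr(tk[i], 1L, 1L)
      flipped <- if (first == stringi::stri_trans_tolower(first)) {
        stringi::stri_trans_toupper(first)
      } else {
        stringi::stri_trans_tolower(first)
      }
      if (flipped != first) {
        substr(tk[i], 1L, 1L) <- flipped
        text <- paste(tk, collapse = " ")
        log <- c(log, "case")
      }
    }
  }
  if (stats::runif(1) < profile$diacritic) {
    stripped <- apply_char_transform(text, "diacritic")
    if (stripped != text) {
      text <- stripped
      log <- c(log, "diacritic")
    }
  }
  if (stats::runif(1) < profile$stopword) {
    tk <- toks(text)
    present <- which(tk %in% stopwords)
    if (length(present) && stats::runif(1) < 0.5) {
      tk <- tk[-present[sample.int(length(present), 1L)]]
    } else {
      sw <- stopwords[sample.int(length(stopwords), 1L)]
      pos <- sample.int(length(tk) + 1L, 1L) - 1L
      tk <- append(tk, sw, after = pos)
    }
    text <- paste(tk, collapse = " ")
    log <- c(log, "stopword")
  }
  if (stats::runif(1) < profile$reorder) {
    tk <- toks(text)
    if (length(tk) >= 2L) {
      i <- sample.int(length(tk) - 1L, 1L)
      tk[c(i, i + 1L)] <- tk[c(i + 1L, i)]
      text2 <- paste(tk, collapse = " ")
      if (text2 != text) {
        text <- text2
        log <- c(log, "reorder")
      }
    }
  }
  if (stats::runif(1) < profile$numeral) {
    tk <- toks(text)
    arabic <- which(grepl("^[0-9]+$", tk))
    arabic <- arabic[suppressWarnings(as.integer(tk[arabic])) %in% 1:3999]
    if (length(arabic)) {
      i <- arabic[sample.int(length(arabic), 1L)]
      tk[i] <- .int_to_roman(as.integer(tk[i]))
      text <- paste(tk, collapse = " ")
      log <- c(log, "numeral")
    }
  }
  if (stats::runif(1) < profile$punct) {
    tk <- toks(text)
    if (length(tk) >= 2L) {
      i <- sample.int(length(tk) - 1L, 1L)
      tk[i] <- paste0(tk[i], ",")
      text <- paste(tk, collapse = " ")
      log <- c(log, "punct")
    }
  }
  if (stats::runif(1) < profile$whitespace) {
    if (grepl(" ", text, fixed = TRUE)) {
      pos <- which(strsplit(text, "", fixed = TRUE)[[1]] == " ")
      i <- pos[sample.int(length(pos), 1L)]
      text <- paste0(substr(text, 1L, i), " ",
                     substr(text, i + 1L, nchar(text)))
      log <- c(log, "whitespace")
    }
  }
  list(text = text, log = log)
}

# run code under a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a labeled synthetic corpus of translation units
#'
#' Produces `n` translation units. The first `round(n * mix)` units are
#' faithful (perturbations drawn only from transformation-recoverable
#' classes); the rest are unfaithful (their professional translation
#' receives at least the chance of a meaning-changing substitution
#' given by `profile_unfaithful$substitution`). For every unit the
#' professional text and machine forward text are independent
#' perturbations of the Spanish reference, and the machine
#' backtranslation is the deterministic lexicon back-map of the
#' professional text with independent faithful perturbations applied.
#' Each unit draws from its own counter-derived substream of the seed,
#' so the corpus is byte-identical under a fixed seed and units are
#' independent of generation order.
#'
#' @param n Number of units (>= 1).
#' @param profile_faithful [perturbation_profile()] for faithful units.
#' @param profile_unfaithful Profile for unfaithful units (its
#'   `substitution` probability should be high).
#' @param mix Fraction of faithful units.
#' @param seed Integer random seed.
#' @return Data frame of translation units with ground-truth columns
#'   `truth` ("faithful"/"unfaithful"), `verdict` ("accept"/"reject")
#'   and `perturb_log`.
#' @export
generate_corpus <- function(n,
                            profile_faithful = perturbation_profile(),
                            profile_unfaithful = perturbation_profile(substitution = 0.9),
                            mix = 0.5, seed = 1L) {
  stopifnot(n >= 1, mix >= 0, mix <= 1)
  n_faithful <- round(n * mix)
  predicates <- c("label", "exact_synonym", "definition")
  machine_faithful <- profile_faithful
  machine_faithful$substitution <- 0

  rows <- vector("list", n)
  for (k in seq_len(n)) {
    unit_seed <- (as.double(seed) * 1009 + k * 9973) %% 2147483647
    faithful <- k <= n_faithful
    profile <- if (faithful) profile_faithful else profile_unfaithful
    rows[[k]] <- .with_seed(as.integer(unit_seed), {
      term <- generate_term()
      prof <- perturb(term$reference, profile, "es")
      if (!faithful && !("substitution" %in% prof$log)) {
        # an unfaithful unit is guaranteed >= 1 meaning-changing
        # substitution so label, verdict and log stay consistent
        forced <- .substitute_token(prof$text, "es")
        if (!is.null(forced)) {
          prof$text <- forced
          prof$log <- c(prof$log, "substitution")
        }
      }
      fwd <- perturb(term$reference, machine_faithful, "es")
      back_raw <- lexicon_backtranslate(prof$text)
      back <- perturb(back_raw, machine_faithful, "en")
      data.frame(
        subject_id = sprintf("SYNTH:%07d", k),
        predicate_id = predicates[(k - 1L) %% 3L + 1L],
        source_lang = "en",
        source_text = term$source,
        translation_lang = "es",
        professional_text = prof$text,
        machine_forward_text = fwd$text,
        machine_back_text = back$text,
        truth = if (faithful) "faithful" else "unfaithful",
        verdict = if (faithful) "accept" else "reject",
        perturb_log = paste(c(prof$log, paste0("fwd:", fwd$log),
                              paste0("back:", back$log)),
                            collapse = ";"),
        stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}
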