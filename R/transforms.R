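#' @importFrom stringi stri_trans_nfc stri_trans_nfd stri_trans_tolower
#'   stri_replace_all_regex stri_split_regex stri_detect_regex
NULL

# Stable transform identifiers --------------------------------------------

CHAR_TRANSFORMS <- c("case", "numeral", "diacritic", "space_removal",
                     "punct_removal")
WORD_TRANSFORMS <- c("stemming", "stopword_removal", "punct_split")

#' Built-in stopword lists
#'
#' Small, shipped stopword lists for English and Spanish function words.
#' They can be replaced per-language via [score_config()] or loaded from
#' a plain-text file with [read_stopwords()].
#'
#' @format A named list with character vectors `en` and `es`.
#' @keywords internal
.default_stopwords <- list(
  en = c("to", "in", "of", "the", "a", "an", "and", "or", "for",
         "with", "by"),
  es = c("de", "y", "la", "el", "los", "las", "del", "al", "un",
         "una", "en", "o", "con", "por", "para")
)

#' Read a stopword list file
#'
#' One token per line, UTF-8; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path Path to a plain-text stopword file.
#' @return Character vector of stopwords.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) {
    stop("stopword file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Construct a transformation set
#'
#' A transformation set names which character-level and word-level text
#' transformations are applied (identically to both members of a text
#' pair) before comparison. Word-level transformations require
#' tokenization; `space_removal` is incompatible with tokenized mode
#' because tokenization already erases whitespace.
#'
#' @param char_transforms Character vector drawn from
#'   `c("case", "numeral", "diacritic", "space_removal", "punct_removal")`.
#' @param word_transforms Character vector drawn from
#'   `c("stemming", "stopword_removal", "punct_split")`.
#' @param tokenized Logical; compare token sequences instead of whole
#'   strings.
#' @return An object of class `transformation_set`.
#' @examples
#' transformation_set("case")
#' transformation_set(c("case", "diacritic"), "stopword_removal",
#'                    tokenized = TRUE)
#' @export
transformation_set <- function(char_transforms = character(),
                               word_transforms = character(),
                               tokenized = FALSE) {
  char_transforms <- unique(as.character(char_transforms))
  word_transforms <- unique(as.character(word_transforms))
  bad <- setdiff(char_transforms, CHAR_TRANSFORMS)
  if (length(bad)) {
    stop("unknown character transform(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(word_transforms, WORD_TRANSFORMS)
  if (length(bad)) {
    stop("unknown word transform(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(word_transforms) && !tokenized) {
    stop("word transforms require tokenized = TRUE", call. = FALSE)
  }
  if (tokenized && "space_removal" %in% char_transforms) {
    stop("space_removal cannot be combined with tokenization",
         call. = FALSE)
  }
  structure(
    list(char_transforms = char_transforms,
         word_transforms = word_transforms,
         tokenized = isTRUE(tokenized)),
    class = "transformation_set"
  )
}

#' @export
format.transformation_set <- function(x, ...) {
  ids <- c(if (x$tokenized) "tokenize",
           sort(x$char_transforms), sort(x$word_transforms))
  if (!length(ids)) "<identity>" else paste(ids, collapse = ";")
}

#' @export
print.transformation_set <- function(x, ...) {
  cat("<transformation_set> ", format(x), "\n", sep = "")
  invisible(x)
}

# Unicode ingest normalization: canonical composition.
.nfc <- function(x) stringi::stri_trans_nfc(x)

# Roman numeral handling ---------------------------------------------------

# strict canonical form, value 1..3999
.roman_re <- "M{0,3}(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})"

.roman_value <- function(tok) {
  vals <- c(I = 1, V = 5, X = 10, L = 50, C = 100, D = 500, M = 1000)
  v <- vals[strsplit(tok, "", fixed = TRUE)[[1]]]
  if (length(v) == 1L) return(unname(v))
  s <- 0
  for (i in seq_along(v)) {
    s <- s + if (i < length(v) && v[i] < v[i + 1L]) -v[i] else v[i]
  }
  unname(s)
}

# Replace whole letter-runs that are canonical roman numerals with their
# arabic value. Runs are bounded by non-letters (or string edges), so
# letters embedded in words ("mix") are left alone.
.replace_roman_runs <- function(text, case_insensitive) {
  # fast path: anything without a roman-numeral letter is unchanged
  letters_re <- if (case_insensitive) "[IVXLCDMivxlcdm]" else "[IVXLCDM]"
  todo <- stringi::stri_detect_regex(text, letters_re)
  todo[is.na(todo)] <- FALSE
  if (!any(todo)) return(text)
  text[todo] <- vapply(text[todo], function(tx) {
    if (is.na(tx) || !nzchar(tx)) return(tx)
    # split into letter runs and everything else, preserving order
    pieces <- stringi::stri_split_regex(tx, "(?<=[^\\p{L}])(?=[\\p{L}])|(?<=[\\p{L}])(?=[^\\p{L}])")[[1]]
    out <- vapply(pieces, function(p) {
      cand <- if (case_insensitive) toupper(p) else p
      if (nzchar(cand) &&
          grepl(paste0("^(", .roman_re, ")$"), cand) &&
          grepl("^[IVXLCDM]+$", cand)) {
        as.character(.roman_value(cand))
      } else {
        p
      }
    }, "")
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
  text
}

# Character transforms -----------------------------------------------------

#' Apply one character-level transformation
#'
#' Character transformations operate on whole strings (or individual
#' tokens) and are deterministic and idempotent: applying a transform
#' twice equals applying it once.
#'
#' * `case`: locale-independent lower-casing.
#' * `numeral`: whole-token roman numerals (strict canonical form,
#'   value at most 3999) are rewritten as arabic digits; `"type V"`
#'   becomes `"type 5"`.
#' * `diacritic`: canonical decomposition followed by removal of
#'   combining marks, so `"Schönlein"` becomes `"Schonlein"`.
#' * `space_removal`: all whitespace (space, tab, newline) removed.
#' * `punct_removal`: all Unicode punctuation removed.
#'
#' @param text Character vector (canonically composed Unicode).
#' @param transform_id One of `case`, `numeral`, `diacritic`,
#'   `space_removal`, `punct_removal`.
#' @param case_insensitive_numerals Match roman numerals without regard
#'   to letter case (used internally when the `case` transform is
#'   co-applied).
#' @return Transformed character vector.
#' @examples
#' apply_char_transform("Schönlein", "diacritic")
#' apply_char_transform("type V", "numeral")
#' @export
apply_char_transform <- function(text, transform_id,
                                 case_insensitive_numerals = FALSE) {
  switch(
    transform_id,
    case = stringi::stri_trans_tolower(text),
    numeral = .replace_roman_runs(text, case_insensitive_numerals),
    diacritic = stringi::stri_trans_nfc(
      stringi::stri_replace_all_regex(
        stringi::stri_trans_nfd(text), "\\p{Mn}", "")),
    space_removal = stringi::stri_replace_all_regex(text, "\\s+", ""),
    punct_removal = stringi::stri_replace_all_regex(text, "\\p{P}+", ""),
    stop("unknown character transform: ", transform_id, call. = FALSE)
  )
}

# Tokenization -------------------------------------------------------------

#' Tokenize text
#'
#' Tokens are maximal runs of non-separator characters. Separators are
#' whitespace; when `punct_split = TRUE`, punctuation characters also
#' separate tokens (so `"46,XX"` splits into `"46"` and `"XX"`).
#'
#' @param text A single string.
#' @param punct_split Also split on punctuation.
#' @return Character vector of tokens (empty for empty input).
#' @examples
#' tokenize("46,XX sex reversal 5", punct_split = TRUE)
#' @export
tokenize <- function(text, punct_split = FALSE) {
  if (length(text) != 1L) stop("tokenize() expects a single string",
                               call. = FALSE)
  if (is.na(text) || !nzchar(text)) return(character())
  sep <- if (punct_split) "[\\s\\p{P}]+" else "\\s+"
  toks <- stringi::stri_split_regex(text, sep, omit_empty = TRUE)[[1]]
  toks
}

# Stemming -----------------------------------------------------------------

# token -> stem cache, per language (stemming is by far the hottest
# operation in the exhaustive search; tokens repeat heavily)
.stem_cache <- new.env(parent = emptyenv())

#' Stem tokens
#'
#' Snowball-family stemming: the Porter2 ("english") algorithm for
#' English and the Snowball "spanish" algorithm for Spanish, both
#' implemented in the package. Tokens are lower-cased internally for
#' stemming, as the algorithms are defined on lower-case words.
#'
#' @param tokens Character vector of tokens.
#' @param language ISO 639 language tag, `"en"` or `"es"`.
#' @return Character vector of stems.
#' @examples
#' stem(c("ears", "running"), "en")
#' stem(c("inhalación", "inhalar"), "es")
#' @export
stem <- function(tokens, language) {
  if (!language %in% c("en", "es")) {
    stop("unsupported stemmer language: ", language, call. = FALSE)
  }
  if (!length(tokens)) return(character())
  fn <- if (language == "en") .stem_en_token else .stem_es_token
  vapply(tokens, function(tok) {
    key <- paste0(language, "\r", tok)
    hit <- .stem_cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- fn(stringi::stri_trans_tolower(tok))
    assign(key, res, envir = .stem_cache)
    res
  }, "", USE.NAMES = FALSE)
}

#' Remove stopwords
#'
#' Drops tokens found in the configured stopword list for `language`,
#' preserving the order of the surviving tokens. Matching is exact on
#' the (already transformed) token text.
#'
#' @param tokens Character vector of tokens.
#' @param language ISO 639 language tag with a configured list.
#' @param stopwords Optional explicit stopword vector; defaults to the
#'   shipped list for `language`.
#' @return Subsequence of `tokens`.
#' @examples
#' remove_stopwords(c("de", "la", "fiebre"), "es")
#' @export
remove_stopwords <- function(tokens, language, stopwords = NULL) {
  if (is.null(stopwords)) {
    stopwords <- .default_stopwords[[language]]
    if (is.null(stopwords)) {
      stop("no stopword list configured for language: ", language,
           call. = FALSE)
    }
  }
  tokens[!(tokens %in% stopwords)]
}

# Pair normalization -------------------------------------------------------

#' Normalize a text pair under one transformation set
#'
#' Applies the same transformation set to both members of a text pair
#' in the canonical order: tokenization (with optional punctuation
#' word-split) first when tokenized; then the character transforms in
#' the fixed order case, diacritic, numeral, punct_removal,
#' space_removal (per token in tokenized mode, whole-string otherwise);
#' then stopword removal; then stemming. Tokens emptied by character
#' transforms are dropped. Roman-numeral matching is case-insensitive
#' when the `case` transform is co-applied.
#'
#' @param text_a,text_b The two texts (single strings).
#' @param ts A [transformation_set()].
#' @param config A [score_config()]; supplies stopword lists.
#' @param language ISO 639 tag of the pair's language.
#' @return A list of class `normalized_pair` with elements `side_a`,
#'   `side_b` (strings, or token vectors when tokenized), `language`
#'   and `applied` (the transformation set).
#' @examples
#' normalize_pair("Ross River fever", "ross river fever",
#'                transformation_set("case"), score_config(), "en")
#' @export
normalize_pair <- function(text_a, text_b, ts, config = score_config(),
                           language = "en") {
  stopifnot(inherits(ts, "transformation_set"))
  one <- function(text) {
    text <- .nfc(text)
    char_order <- intersect(
      c("case", "diacritic", "numeral", "punct_removal", "space_removal"),
      ts$char_transforms)
    apply_chars <- function(x) {
      for (id in char_order) {
        x <- apply_char_transform(
          x, id,
          case_insensitive_numerals = "case" %in% ts$char_transforms)
      }
      x
    }
    if (!ts$tokenized) {
      return(apply_chars(text))
    }
    toks <- tokenize(text, punct_split = "punct_split" %in% ts$word_transforms)
    toks <- apply_chars(toks)
    toks <- toks[nzchar(toks)]
    if ("stopword_removal" %in% ts$word_transforms) {
      toks <- remove_stopwords(toks, language,
                               stopwords = config$stopwords[[language]])
    }
    if ("stemming" %in% ts$word_transforms) {
      toks <- stem(toks, language)
    }
    toks
  }
  structure(
    list(side_a = one(text_a), side_b = one(text_b),
         language = language, applied = ts),
    class = "normalized_pair"
  )
}
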