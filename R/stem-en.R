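# English (Porter2 / Snowball "english") stemmer, pure R.
#
# Self-contained reimplementation of the published Snowball English
# algorithm so that stemming works without compiled dependencies.
# Operates on one lower-case token at a time; vectorised wrapper in
# stem().

.en_vowels <- c("a", "e", "i", "o", "u", "y")

.en_is_vowel <- function(chars, i) chars[i] %in% .en_vowels

# R1/R2 start positions (1-based index of first character of region;
# length(word)+1 when the region is empty).
.en_regions <- function(chars) {
  n <- length(chars)
  word <- paste(chars, collapse = "")
  r1 <- n + 1L
  # special prefixes fix R1
  for (pre in c("gener", "commun", "arsen")) {
    if (startsWith(word, pre)) {
      r1 <- nchar(pre) + 1L
      break
    }
  }
  if (r1 == n + 1L) {
    i <- 1L
    while (i < n) {
      if (.en_is_vowel(chars, i) && !.en_is_vowel(chars, i + 1L)) {
        r1 <- i + 2L
        break
      }
      i <- i + 1L
    }
  }
  r2 <- n + 1L
  i <- r1
  while (i < n) {
    if (.en_is_vowel(chars, i) && !.en_is_vowel(chars, i + 1L)) {
      r2 <- i + 2L
      break
    }
    i <- i + 1L
  }
  c(r1 = r1, r2 = r2)
}

# A short syllable: vowel followed by non-vowel other than w, x, Y and
# preceded by a non-vowel; or a vowel at the beginning followed by a
# non-vowel.
.en_ends_short_syllable <- function(chars) {
  n <- length(chars)
  if (n == 2L) {
    return(.en_is_vowel(chars, 1L) && !.en_is_vowel(chars, 2L))
  }
  if (n >= 3L) {
    return(!.en_is_vowel(chars, n - 2L) &&
             .en_is_vowel(chars, n - 1L) &&
             !(chars[n] %in% c(.en_vowels, "w", "x", "Y")))
  }
  FALSE
}

.en_is_short <- function(chars, r1) {
  .en_ends_short_syllable(chars) && r1 > length(chars)
}

.en_contains_vowel <- function(chars, from, to) {
  if (from > to) return(FALSE)
  any(chars[from:to] %in% .en_vowels)
}

.en_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.en_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.en_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie",
  tying = "tie", idly = "idl", gently = "gentl", ugly = "ugli",
  early = "earli", only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.en_exceptions2 <- c("inning", "outing", "canning", "herring", "earring",
                     "proceed", "exceed", "succeed")

.stem_en_token <- function(word) {
  if (nchar(word) <= 2L) return(word)
  word <- sub("^'", "", word)
  if (word %in% names(.en_exceptions1)) {
    return(unname(.en_exceptions1[[word]]))
  }
  if (nchar(word) <= 2L) return(word)

  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  # mark consonant y as Y
  if (chars[1] == "y") chars[1] <- "Y"
  if (length(chars) >= 2L) {
    for (i in 2:length(chars)) {
      if (chars[i] == "y" && .en_is_vowel(chars, i - 1L)) chars[i] <- "Y"
    }
  }
  reg <- .en_regions(chars)
  r1 <- reg[["r1"]]
  r2 <- reg[["r2"]]

  w <- function() paste(chars, collapse = "")
  ends <- function(suf) {
    n <- length(chars)
    ns <- nchar(suf)
    n >= ns && substr(w(), n - ns + 1L, n) == suf
  }
  in_r1 <- function(suf) length(chars) - nchar(suf) + 1L >= r1
  in_r2 <- function(suf) length(chars) - nchar(suf) + 1L >= r2
  drop_n <- function(k) chars[seq_len(length(chars) - k)]

  # Step 1a
  if (ends("'s'")) {
    chars <- drop_n(3L)
  } else if (ends("'s")) {
    chars <- drop_n(2L)
  } else if (ends("'")) {
    chars <- drop_n(1L)
  }
  if (ends("sses")) {
    chars <- drop_n(2L)
  } else if (ends("ied") || ends("ies")) {
    chars <- if (length(chars) > 4L) drop_n(2L) else drop_n(1L)
  } else if (ends("us") || ends("ss")) {
    # leave
  } else if (ends("s")) {
    if (length(chars) >= 3L && .en_contains_vowel(chars, 1L, length(chars) - 2L)) {
      chars <- drop_n(1L)
    }
  }

  if (w() %in% .en_exceptions2) return(w())

  # Step 1b
  step1b_del <- FALSE
  if (ends("eedly")) {
    if (in_r1("eedly")) chars <- drop_n(3L)
  } else if (ends("eed")) {
    if (in_r1("eed")) chars <- drop_n(1L)
  } else {
    for (suf in c("ingly", "edly", "ing", "ed")) {
      if (ends(suf)) {
        if (.en_contains_vowel(chars, 1L, length(chars) - nchar(suf))) {
          chars <- drop_n(nchar(suf))
          step1b_del <- TRUE
        }
        break
      }
    }
    if (step1b_del) {
      reg <- .en_regions(chars)  # regions shrink with the word
      r1 <- reg[["r1"]]; r2 <- reg[["r2"]]
      tail2 <- if (length(chars) >= 2L) paste(chars[(length(chars) - 1L):length(chars)], collapse = "") else ""
      if (tail2 %in% c("at", "bl", "iz")) {
        chars <- c(chars, "e")
      } else if (tail2 %in% .en_doubles) {
        chars <- drop_n(1L)
      } else if (.en_is_short(chars, r1)) {
        chars <- c(chars, "e")
      }
    }
  }
  reg <- .en_regions(chars); r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 1c: y -> i when preceded by a non-vowel that is not word-initial
  n <- length(chars)
  if (n > 2L && chars[n] %in% c("y", "Y") && !.en_is_vowel(chars, n - 1L)) {
    chars[n] <- "i"
  }

  # Step 2 (longest suffix, condition in R1)
  step2 <- list(
    c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
    c("ousness", "ous"), c("iveness", "ive"), c("tional", "tion"),
    c("biliti", "ble"), c("lessli", "less"), c("entli", "ent"),
    c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
    c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
    c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
    c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
    c("bli", "ble"), c("ogi", "og"), c("li", "")
  )
  for (rule in step2) {
    suf <- rule[1]
    if (ends(suf)) {
      if (in_r1(suf)) {
        if (suf == "ogi") {
          if (length(chars) > 3L && chars[length(chars) - 3L] == "l") {
            chars <- c(drop_n(3L), "og")
          }
        } else if (suf == "li") {
          if (length(chars) > 2L && chars[length(chars) - 2L] %in% .en_li_valid) {
            chars <- drop_n(2L)
          }
        } else {
          chars <- c(drop_n(nchar(suf)),
                     strsplit(rule[2], "", fixed = TRUE)[[1]])
        }
      }
      break
    }
  }
  reg <- .en_regions(chars); r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 3 (condition in R1; "ative" requires R2)
  step3 <- list(
    c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
    c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (rule in step3) {
    suf <- rule[1]
    if (ends(suf)) {
      if (in_r1(suf)) {
        if (suf == "ative") {
          if (in_r2(suf)) chars <- drop_n(5L)
        } else {
          chars <- c(drop_n(nchar(suf)),
                     strsplit(rule[2], "", fixed = TRUE)[[1]])
        }
      }
      break
    }
  }
  reg <- .en_regions(chars); r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 4 (condition in R2)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment",
             "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize",
             "ion", "al", "er", "ic")
  for (suf in step4) {
    if (ends(suf)) {
      if (in_r2(suf)) {
        if (suf == "ion") {
          if (length(chars) > 3L &&
              chars[length(chars) - 3L] %in% c("s", "t")) {
            chars <- drop_n(3L)
          }
        } else {
          chars <- drop_n(nchar(suf))
        }
      }
      break
    }
  }
  reg <- .en_regions(chars); r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # Step 5
  n <- length(chars)
  if (n >= 1L && chars[n] == "e") {
    if (n >= r2) {
      chars <- drop_n(1L)
    } else if (n >= r1 && !.en_ends_short_syllable(chars[seq_len(n - 1L)])) {
      chars <- drop_n(1L)
    }
  } else if (n >= 2L && chars[n] == "l" && chars[n - 1L] == "l" && n >= r2) {
    chars <- drop_n(1L)
  }

  chartr("Y", "y", paste(chars, collapse = ""))
}
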