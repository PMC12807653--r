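# Spanish (Snowball "spanish") stemmer, pure R.
#
# Reimplementation of the published Snowball Spanish algorithm.
# Tokens are expected lower-case; the final step removes acute accents,
# so "inhalación" and "inhalar" both stem to "inhal".

.es_vowels <- c("a", "e", "i", "o", "u", "á", "é", "í",
                "ó", "ú", "ü")

.es_regions <- function(chars) {
  n <- length(chars)
  isv <- chars %in% .es_vowels

  # RV
  rv <- n + 1L
  if (n >= 2L) {
    if (!isv[2L]) {
      # consonant in position 2: RV after the next vowel
      i <- 3L
      while (i <= n && !isv[i]) i <- i + 1L
      rv <- i + 1L
    } else if (isv[1L] && isv[2L]) {
      # two initial vowels: RV after the next consonant
      i <- 3L
      while (i <= n && isv[i]) i <- i + 1L
      rv <- i + 1L
    } else {
      # consonant-vowel start: RV after the third letter
      rv <- 4L
    }
    if (rv > n + 1L) rv <- n + 1L
  }

  r1 <- n + 1L
  i <- 1L
  while (i < n) {
    if (isv[i] && !isv[i + 1L]) { r1 <- i + 2L; break }
    i <- i + 1L
  }
  r2 <- n + 1L
  i <- r1
  while (i < n) {
    if (isv[i] && !isv[i + 1L]) { r2 <- i + 2L; break }
    i <- i + 1L
  }
  c(rv = rv, r1 = r1, r2 = r2)
}

.es_deaccent <- function(x) {
  chartr("áéíóú", "aeiou", x)
}

.stem_es_token <- function(word) {
  if (nchar(word) <= 2L) return(.es_deaccent(word))
  chars <- strsplit(word, "", fixed = TRUE)[[1]]

  w <- function() paste(chars, collapse = "")
  ends <- function(suf) {
    n <- length(chars); ns <- nchar(suf)
    n >= ns && substr(w(), n - ns + 1L, n) == suf
  }
  suffix_pos <- function(suf) length(chars) - nchar(suf) + 1L
  drop_n <- function(k) chars[seq_len(length(chars) - k)]

  reg <- .es_regions(chars)
  rv <- reg[["rv"]]; r1 <- reg[["r1"]]; r2 <- reg[["r2"]]
  in_rv <- function(suf) suffix_pos(suf) >= rv
  in_r1 <- function(suf) suffix_pos(suf) >= r1
  in_r2 <- function(suf) suffix_pos(suf) >= r2

  # ---- Step 0: attached pronouns -------------------------------------
  pronouns <- c("selas", "selos", "sela", "selo", "las", "les", "los",
                "nos", "me", "se", "la", "le", "lo")
  pre_a <- c("iéndo", "ándo", "ár", "ér", "ír")
  pre_a_plain <- c("iendo", "ando", "ar", "er", "ir")
  pre_b <- c("iendo", "ando", "ar", "er", "ir")
  for (p in pronouns) {
    # suffix search is limited to RV: the longest pronoun lying wholly
    # inside RV is the (single) candidate
    if (!ends(p) || !in_rv(p)) next
    stem_part <- substr(w(), 1L, length(chars) - nchar(p))
    matched <- FALSE
    for (k in seq_along(pre_a)) {
      a <- pre_a[k]
      if (endsWith(stem_part, a) &&
          nchar(stem_part) - nchar(a) + 1L >= rv - 0L &&
          (nchar(stem_part) - nchar(a) + 1L) >= rv) {
        # delete pronoun, de-accent the preceding suffix
        chars <- strsplit(paste0(substr(stem_part, 1L,
                                        nchar(stem_part) - nchar(a)),
                                 pre_a_plain[k]), "", fixed = TRUE)[[1]]
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      for (b in pre_b) {
        if (endsWith(stem_part, b) &&
            (nchar(stem_part) - nchar(b) + 1L) >= rv) {
          chars <- strsplit(stem_part, "", fixed = TRUE)[[1]]
          matched <- TRUE
          break
        }
      }
    }
    if (!matched && endsWith(stem_part, "yendo") &&
        nchar(stem_part) >= 6L &&
        substr(stem_part, nchar(stem_part) - 5L, nchar(stem_part) - 5L) == "u" &&
        (nchar(stem_part) - 5L) >= rv) {
      chars <- strsplit(stem_part, "", fixed = TRUE)[[1]]
      matched <- TRUE
    }
    break  # only the longest matching pronoun is considered
  }
  reg <- .es_regions(chars)
  rv <- reg[["rv"]]; r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # ---- Step 1: standard suffixes -------------------------------------
  n_before <- length(chars)
  s1_del_r2 <- .es_s1_del_r2
  s1_ador <- .es_s1_ador
  matched1 <- FALSE
  for (suf in .es_s1_all) {
    if (!ends(suf)) next
    if (suf %in% s1_del_r2) {
      if (in_r2(suf)) { chars <- drop_n(nchar(suf)); matched1 <- TRUE }
    } else if (suf %in% s1_ador) {
      if (in_r2(suf)) {
        chars <- drop_n(nchar(suf))
        if (ends("ic") && in_r2("ic")) chars <- drop_n(2L)
        matched1 <- TRUE
      }
    } else if (suf %in% c("logías", "logía")) {
      if (in_r2(suf)) {
        chars <- c(drop_n(nchar(suf)), "l", "o", "g")
        matched1 <- TRUE
      }
    } else if (suf %in% c("uciones", "ución")) {
      if (in_r2(suf)) {
        chars <- c(drop_n(nchar(suf)), "u")
        matched1 <- TRUE
      }
    } else if (suf %in% c("encias", "encia")) {
      if (in_r2(suf)) {
        chars <- c(drop_n(nchar(suf)), "e", "n", "t", "e")
        matched1 <- TRUE
      }
    } else if (suf == "amente") {
      if (in_r1(suf)) {
        chars <- drop_n(6L)
        matched1 <- TRUE
        if (ends("iv") && in_r2("iv")) {
          chars <- drop_n(2L)
          if (ends("at") && in_r2("at")) chars <- drop_n(2L)
        } else {
          for (x in c("os", "ic", "ad")) {
            if (ends(x) && in_r2(x)) { chars <- drop_n(2L); break }
          }
        }
      }
    } else if (suf == "mente") {
      if (in_r2(suf)) {
        chars <- drop_n(5L)
        matched1 <- TRUE
        for (x in c("ante", "able", "ible")) {
          if (ends(x) && in_r2(x)) { chars <- drop_n(nchar(x)); break }
        }
      }
    } else if (suf %in% c("idades", "idad")) {
      if (in_r2(suf)) {
        chars <- drop_n(nchar(suf))
        matched1 <- TRUE
        for (x in c("abil", "ic", "iv")) {
          if (ends(x) && in_r2(x)) { chars <- drop_n(nchar(x)); break }
        }
      }
    } else if (suf %in% c("ivas", "ivos", "iva", "ivo")) {
      if (in_r2(suf)) {
        chars <- drop_n(nchar(suf))
        matched1 <- TRUE
        if (ends("at") && in_r2("at")) chars <- drop_n(2L)
      }
    }
    break  # longest suffix found decides; no fallback to shorter ones
  }
  did_step1 <- matched1 || length(chars) != n_before
  reg <- .es_regions(chars)
  rv <- reg[["rv"]]; r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # ---- Step 2a: verb suffixes beginning with y (only if step 1 no-op) -
  did_step2a <- FALSE
  if (!did_step1) {
    s2a <- c("yeron", "yendo", "yamos", "yais", "yan", "yen", "yas",
             "yes", "ya", "ye", "yo", "yó")
    for (suf in s2a) {
      if (!ends(suf) || !in_rv(suf)) next
      pos <- suffix_pos(suf)
      if (pos > 1L && chars[pos - 1L] == "u") {
        chars <- drop_n(nchar(suf))
        did_step2a <- TRUE
      }
      break
    }
  }

  # ---- Step 2b: other verb suffixes (only if 1 and 2a were no-ops) ----
  if (!did_step1 && !did_step2a) {
    s2b_gu <- .es_s2b_gu
    for (suf in .es_s2b_all) {
      if (!ends(suf) || !in_rv(suf)) next
      chars <- drop_n(nchar(suf))
      if (suf %in% s2b_gu && ends("gu") && in_rv("u")) {
        chars <- drop_n(1L)
      }
      break
    }
  }
  reg <- .es_regions(chars)
  rv <- reg[["rv"]]; r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  # ---- Step 3: residual suffix ---------------------------------------
  matched3 <- FALSE
  for (suf in .es_s3) {
    if (ends(suf) && in_rv(suf)) {
      chars <- drop_n(nchar(suf))
      matched3 <- TRUE
      break
    }
  }
  if (!matched3 && (ends("e") || ends("é")) && in_rv("e")) {
    chars <- drop_n(1L)
    # drop a trailing u after g when the u itself lies in RV
    if (ends("gu") && in_rv("u")) chars <- drop_n(1L)
  }

  .es_deaccent(paste(chars, collapse = ""))
}

# suffix tables, hoisted and pre-sorted longest-first
.es_s1_del_r2 <- c("amientos", "imientos", "amiento", "imiento", "anzas",
                   "ismos", "ables", "ibles", "istas", "anza", "icos",
                   "icas", "ismo", "able", "ible", "ista", "osos", "osas",
                   "ico", "ica", "oso", "osa")
.es_s1_ador <- c("aciones", "adoras", "adores", "ancias", "adora",
                 "ación", "antes", "ancia", "ador", "ante")
.es_s1_all <- local({
  all1 <- c(.es_s1_del_r2, .es_s1_ador, "logías", "logía",
            "uciones", "ución", "encias", "encia", "amente",
            "mente", "idades", "idad", "ivas", "ivos", "iva", "ivo")
  all1[order(-nchar(all1))]
})
.es_s2b_gu <- c("emos", "éis", "en", "es")
.es_s2b_all <- local({
  s2b <- c("aríais", "eríais", "iríais", "aríamos",
           "eríamos", "iríamos", "iéramos",
           "iésemos", "aremos", "eremos", "iremos", "arían",
           "arías", "aréis", "erían", "erías",
           "eréis", "irían", "irías", "iréis",
           "ierais", "ieseis", "asteis", "isteis", "ábamos",
           "áramos", "ásemos", "aría", "arán",
           "arás", "ería", "erán", "erás",
           "iría", "irán", "irás", "ieran", "iesen",
           "ieron", "iendo", "ieras", "ieses", "abais", "arais",
           "aseis", "íamos", "ará", "aré",
           "erá", "eré", "irá", "iré", "aba",
           "ada", "ida", "ara", "iera", "ase", "iese", "aste",
           "iste", "aban", "aran", "asen", "aron", "ado", "ido",
           "ando", "abas",
           "adas", "idas", "aras", "ases", "íais", "ados",
           "idos", "amos", "imos", "ía", "ad", "ed", "id",
           "an", "ió", "ar", "er", "ir", "as", "ías",
           "ís", "áis", "ían")
  allb <- c(.es_s2b_gu, s2b)
  allb[order(-nchar(allb))]
})
.es_s3 <- local({
  s3 <- c("os", "a", "o", "á", "í", "ó")
  s3[order(-nchar(s3))]
})
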