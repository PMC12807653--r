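# Character- and word-level transformations.

test_that("character transforms reproduce the canonical examples", {
  expect_identical(apply_char_transform("Schönlein", "diacritic"),
                   "Schonlein")
  expect_identical(
    apply_char_transform("Hemorrágica brasileña", "diacritic"),
    "Hemorragica brasilena")
  expect_identical(apply_char_transform("type V", "numeral"), "type 5")
  expect_identical(apply_char_transform("PKD YS1", "space_removal"),
                   "PKDYS1")
  expect_identical(
    apply_char_transform("46,XX sex reversal 5", "punct_removal"),
    "46XX sex reversal 5")
  expect_identical(apply_char_transform("Syndrome", "case"), "syndrome")
  expect_identical(apply_char_transform("syndrome", "case"), "syndrome")
  expect_error(apply_char_transform("x", "bogus"), "unknown character")
})

test_that("character transforms are idempotent", {
  samples <- c("Schönlein purpura", "type V", "PKD YS1",
               "46,XX sex reversal 5", "Hemorrágica brasileña",
               "fiebre del río de Ross", "", "MIX mix", "a.b,c d")
  for (id in c("case", "numeral", "diacritic", "space_removal",
               "punct_removal")) {
    once <- apply_char_transform(samples, id)
    expect_identical(apply_char_transform(once, id), once,
                     info = paste("transform:", id))
  }
})

test_that("numeral standardization only rewrites whole roman tokens", {
  expect_identical(apply_char_transform("mix of MIX", "numeral"),
                   "mix of 1009")
  expect_identical(apply_char_transform("vitamin B IV", "numeral"),
                   "vitamin B 4")
  # single-letter tokens D/I/C/M are themselves canonical romans
  expect_identical(apply_char_transform("vitamin D", "numeral"),
                   "vitamin 500")
  # lower-case romans convert only under case-insensitive matching
  expect_identical(apply_char_transform("type v", "numeral"), "type v")
  expect_identical(
    apply_char_transform("type v", "numeral",
                         case_insensitive_numerals = TRUE),
    "type 5")
  # IIII is not canonical; IC is not a valid subtractive pair
  expect_identical(apply_char_transform("IIII IC", "numeral"), "IIII IC")
})

test_that("tokenize splits on whitespace and optionally punctuation", {
  expect_identical(tokenize("46,XX sex reversal 5", punct_split = TRUE),
                   c("46", "XX", "sex", "reversal", "5"))
  expect_identical(tokenize("46,XX sex reversal 5", punct_split = FALSE),
                   c("46,XX", "sex", "reversal", "5"))
  expect_identical(tokenize("fiebre del río de Ross"),
                   c("fiebre", "del", "río", "de", "Ross"))
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("  a \t b \n c  "), c("a", "b", "c"))
})

test_that("stopword removal keeps order and is a subsequence", {
  expect_identical(remove_stopwords(c("de", "la", "fiebre"), "es"),
                   "fiebre")
  expect_identical(remove_stopwords(c("to", "of", "in"), "en"),
                   character())
  expect_identical(remove_stopwords(character(), "en"), character())
  expect_error(remove_stopwords("x", "fr"), "no stopword list")
  # property: output is a subsequence of input
  set.seed(11)
  for (i in 1:20) {
    toks <- sample(c("de", "y", "fiebre", "la", "Ross", "río"),
                   sample(0:6, 1L), replace = TRUE)
    out <- remove_stopwords(toks, "es")
    expect_true(all(out %in% toks))
    expect_identical(out, toks[toks %in% out])
  }
})

test_that("diacritic transform yields pure ASCII for Latin composites", {
  latin <- c("Schönlein", "río", "síndrome", "congénita", "fácil",
             "Hemorrágica brasileña ü")
  out <- apply_char_transform(latin, "diacritic")
  expect_true(all(vapply(out, function(s) {
    all(utf8ToInt(s) < 128L)
  }, logical(1))))
})

test_that("transformation_set enforces its invariants", {
  ts <- transformation_set(c("case", "case"), tokenized = FALSE)
  expect_identical(ts$char_transforms, "case")
  expect_error(transformation_set(word_transforms = "stemming"),
               "tokenized")
  expect_error(transformation_set("space_removal", tokenized = TRUE),
               "space_removal")
  expect_error(transformation_set("caseify"), "unknown")
})

test_that("normalize_pair applies one set identically to both sides", {
  cfg <- score_config()
  np <- normalize_pair("Ross River fever", "ross river fever",
                       transformation_set("case"), cfg, "en")
  expect_identical(np$side_a, "ross river fever")
  expect_identical(np$side_b, "ross river fever")

  np <- normalize_pair("unchanged", "unchanged", transformation_set(),
                       cfg, "en")
  expect_identical(np$side_a, "unchanged")
  expect_identical(np$side_b, "unchanged")

  # case + tokenization + Spanish stopword removal: "de" removed,
  # "del" retained per the shipped list's semantics
  np <- normalize_pair(
    "fiebre del río de Ross", "Fiebre del río Ross",
    transformation_set("case", "stopword_removal", tokenized = TRUE),
    cfg, "es")
  expect_identical(np$side_a, c("fiebre", "río", "ross"))
  expect_identical(np$side_b, c("fiebre", "río", "ross"))
})

test_that("normalize_pair is symmetric under side swap", {
  cfg <- score_config()
  sets <- list(
    transformation_set(),
    transformation_set(c("case", "diacritic")),
    transformation_set("case", c("stemming", "stopword_removal"),
                       tokenized = TRUE))
  pairs <- list(c("Fiebre del río", "fiebre ríos"),
                c("46,XX reversal", "46 XX reversal"))
  for (ts in sets) {
    for (p in pairs) {
      ab <- normalize_pair(p[1], p[2], ts, cfg, "es")
      ba <- normalize_pair(p[2], p[1], ts, cfg, "es")
      expect_identical(ab$side_a, ba$side_b)
      expect_identical(ab$side_b, ba$side_a)
    }
  }
})

test_that("unicode ingest composes before transforming", {
  # decomposed n + combining tilde equals precomposed ñ after ingest
  decomposed <- "brasilen\u0303a"
  composed <- "brasile\u00f1a"
  cfg <- score_config()
  np <- normalize_pair(decomposed, composed, transformation_set(), cfg,
                       "es")
  expect_identical(np$side_a, np$side_b)
  expect_equal(best_match(decomposed, composed, "es")$score, 1)
})

test_that("read_stopwords parses files and skips comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# spanish extras", "de", "", "  la  "), f)
  expect_identical(read_stopwords(f), c("de", "la"))
  expect_error(read_stopwords(file.path(tempdir(), "nope.txt")),
               "not found")
})
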