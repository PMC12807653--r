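# Penalized similarity scoring, exhaustive search and classification.

cfg <- score_config()

test_that("percent_word_match is a multiset overlap over the larger count", {
  expect_equal(percent_word_match(c("breast", "lobular", "carcinoma"),
                                  c("lobular", "breast", "carcinoma")), 1)
  expect_equal(percent_word_match("daltonismo",
                                  c("daltonismo", "rojo")), 0.5)
  expect_equal(percent_word_match(c("a", "a"), "a"), 0.5)
  expect_equal(percent_word_match(character(), character()), 1)
  expect_equal(percent_word_match(character(), "x"), 0)
  # symmetry on random token multisets
  set.seed(4)
  for (i in 1:25) {
    x <- sample(letters[1:4], sample(0:5, 1), replace = TRUE)
    y <- sample(letters[1:4], sample(0:5, 1), replace = TRUE)
    expect_equal(percent_word_match(x, y), percent_word_match(y, x))
  }
})

test_that("score_match implements the penalized equation exactly", {
  expect_equal(score_match(1, TRUE, 1, 1, cfg), 0.78)
  expect_equal(score_match(1, FALSE, 0, 1, cfg), 0.98)
  expect_equal(score_match(1, FALSE, 0, 0, cfg), 1)
  expect_equal(score_match(0.5, TRUE, 3, 5, cfg), 0.30)
  # penalties scale with w_pct: never negative, shrink with the match
  for (w in c(0, 0.25, 0.5, 1)) {
    s <- score_match(w, TRUE, 3, 4, cfg)
    expect_equal(s, w * (1 - 0.15 - 3 * 0.05 - 4 * 0.02))
    expect_gte(s, 0)
    expect_lte(s, w)
  }
})

test_that("score_config validates its invariants", {
  expect_error(score_config(cutoff = 1), "cutoff")
  expect_error(score_config(char_weight = -0.1), "non-negative")
  expect_error(score_config(token_penalty = 0.5, word_weight = 0.2,
                            char_weight = 0.1), "< 1")
})

test_that("best_match reproduces the published worked example", {
  es <- best_match("fiebre del río de Ross", "Fiebre del río Ross",
                   "es", cfg)
  expect_equal(es$score, 0.78)
  expect_true(es$tokenized)
  expect_equal(es$w_n, 1L)
  expect_equal(es$c_n, 1L)
  expect_setequal(es$applied$word_transforms, "stopword_removal")
  expect_setequal(es$applied$char_transforms, "case")

  en <- best_match("Ross River fever", "ross river fever", "en", cfg)
  expect_equal(en$score, 0.98)
  expect_false(en$tokenized)
  expect_equal(en$c_n, 1L)
  expect_setequal(en$applied$char_transforms, "case")
})

test_that("best_match identity, symmetry and bounds properties hold", {
  set.seed(21)
  for (i in 1:40) {
    p <- random_pair()
    ab <- best_match(p$a, p$b, p$language, cfg)
    ba <- best_match(p$b, p$a, p$language, cfg)
    expect_equal(ab$score, ba$score, info = paste(p$a, "|", p$b))
    expect_gte(ab$score, 0)
    expect_lte(ab$score, 1)
    expect_lte(ab$score, ab$w_pct + 1e-12)
    ident <- best_match(p$a, p$a, p$language, cfg)
    expect_equal(ident$score, 1)
    expect_length(ident$applied$char_transforms, 0)
    expect_false(ident$applied$tokenized)
  }
})

test_that("best_match equals the naive exhaustive oracle on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    p <- random_pair()
    fast <- best_match(p$a, p$b, p$language, cfg)$score
    slow <- oracle_best_score(p$a, p$b, p$language, cfg)
    expect_equal(fast, slow, info = sprintf("'%s' vs '%s' [%s]",
                                            p$a, p$b, p$language))
  }
})

test_that("single-perturbation closed forms hold", {
  # case-only difference: exactly 1 - char_weight
  expect_equal(best_match("Carcinoma", "carcinoma", "en", cfg)$score,
               1 - cfg$char_weight)
  # single extra stopword (same case): 1 - t - word_weight
  expect_equal(
    best_match("fiebre de Ross", "fiebre Ross", "es", cfg)$score,
    1 - cfg$token_penalty - cfg$word_weight)
  # stopword plus case difference, as in the worked example
  expect_equal(
    best_match("fiebre de ross", "Fiebre ross", "es", cfg)$score,
    1 - cfg$token_penalty - cfg$word_weight - cfg$char_weight)
})

test_that("monotone penalty: each counted transform lowers the score", {
  # fixed full match under tokenization; adding transform types
  # decreases the score by w_pct * weight each
  s0 <- score_match(1, TRUE, 0, 0, cfg)
  s1 <- score_match(1, TRUE, 1, 0, cfg)
  s2 <- score_match(1, TRUE, 1, 1, cfg)
  expect_equal(s0 - s1, cfg$word_weight)
  expect_equal(s1 - s2, cfg$char_weight)
  for (w in c(0.25, 0.75)) {
    expect_equal(score_match(w, TRUE, 1, 0, cfg),
                 score_match(w, TRUE, 0, 0, cfg) - w * cfg$word_weight)
  }
})

test_that("degenerate inputs score per the documented convention", {
  expect_equal(best_match("", "", "en", cfg)$score, 1)
  expect_equal(best_match("", "fever", "en", cfg)$score, 0)
})

test_that("classify applies the at-or-below-cutoff rule", {
  expect_identical(classify(0.88, cfg), "passed")
  expect_identical(classify(1, cfg), "exact")
  expect_identical(classify(0.75, cfg), "pending")
  expect_identical(classify(0.7501, cfg), "passed")
  expect_identical(classify(0, cfg), "pending")
})

test_that("score_translation_unit scores both language pairs and averages", {
  ct <- score_translation_unit(worked_unit(), cfg)
  expect_equal(ct$en_result$score, 0.98)
  expect_equal(ct$es_result$score, 0.78)
  expect_equal(ct$final_score, 0.88)
  expect_identical(ct$category, "passed")

  # two raw-identical pairs: exact
  u <- list(source_text = "angiosarcoma", professional_text = "angiosarcoma",
            machine_forward_text = "angiosarcoma",
            machine_back_text = "angiosarcoma")
  ct <- score_translation_unit(u, cfg)
  expect_equal(ct$final_score, 1)
  expect_identical(ct$category, "exact")

  # each pair engineered to best-score exactly 0.75: pending
  u <- list(source_text = "running of fevers",
            machine_back_text = "run fever",
            professional_text = "inhalaciones de la fiebre",
            machine_forward_text = "inhalar fiebre")
  ct <- score_translation_unit(u, cfg)
  expect_equal(ct$en_result$score, 0.75)
  expect_equal(ct$es_result$score, 0.75)
  expect_equal(ct$final_score, 0.75)
  expect_identical(ct$category, "pending")
})

test_that("incomplete units fail naming the missing field", {
  u <- worked_unit()
  u$machine_back_text <- NULL
  expect_error(score_translation_unit(u, cfg), "machine_back_text")
})

test_that("score_units appends the scoring columns", {
  units <- rbind(worked_unit_df(), worked_unit_df())
  units$subject_id <- c("DOID:1", "DOID:2")
  scored <- score_units(units, cfg)
  expect_equal(scored$final_score, c(0.88, 0.88))
  expect_identical(scored$category, c("passed", "passed"))
  expect_match(scored$es_transforms[1], "stopword_removal")
})
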