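# Ledger lifecycle: TSV dialect, reconciliation, subsets, policy,
# release templates and reports.

test_that("write_master sorts records and round-trips byte-identically", {
  recs <- ledger_fixture()
  shuffled <- recs[c(3, 1, 2), ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_master(shuffled, f)
  back <- read_ledger(f)
  expect_identical(back$subject_id,
                   sort(recs$subject_id, method = "radix"))
  # canonical form is stable: write(read(x)) == x
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_master(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("empty record set writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_master(ledger_fixture()[0, ], f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  back <- read_ledger(f)
  expect_equal(nrow(back), 0L)
})

test_that("escaped tabs and newlines round-trip exactly", {
  recs <- ledger_fixture()[1, ]
  recs$source_text <- "line one\nline\ttwo \\n literal"
  recs$target_text <- "col\tumna"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_master(recs, f)
  back <- read_ledger(f)
  expect_identical(back$source_text, recs$source_text)
  expect_identical(back$target_text, recs$target_text)
})

test_that("malformed rows and duplicate keys are rejected with positions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("subject_id", "predicate_id", "source_lang",
                       "source_text", "target_lang", "target_text",
                       "status"), collapse = "\t"),
               "DOID:1\tlabel\ten\tx\tes\ty"), f)
  expect_error(read_ledger(f), "line")

  dup <- rbind(ledger_fixture(), ledger_fixture()[1, ])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_master(dup, f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("subject_id\tpredicate_id", f3)
  expect_error(read_ledger(f3), "missing required column")
})

test_that("reconcile partitions records and triples per the join rules", {
  recs <- ledger_fixture()
  triples <- data.frame(subject_id = recs$subject_id,
                        predicate_id = recs$predicate_id,
                        text = recs$source_text, lang = "en",
                        stringsAsFactors = FALSE)
  # all three carried
  r <- reconcile(triples, recs)
  expect_equal(nrow(r$carried), 3L)
  expect_equal(nrow(r$changed) + nrow(r$new_untranslated) +
                 nrow(r$retired), 0L)

  # text changed for one (subject, predicate): changed + retired
  triples2 <- triples
  triples2$text[1] <- "Ross River disease"
  r <- reconcile(triples2, recs)
  expect_equal(nrow(r$carried), 2L)
  expect_equal(nrow(r$changed), 1L)
  expect_equal(nrow(r$retired), 1L)
  expect_identical(r$changed$text, "Ross River disease")

  # brand new triple, no record
  triples3 <- rbind(triples, data.frame(
    subject_id = "DOID:999", predicate_id = "label",
    text = "new disease", lang = "en", stringsAsFactors = FALSE))
  r <- reconcile(triples3, recs)
  expect_equal(nrow(r$new_untranslated), 1L)
  expect_equal(nrow(r$carried), 3L)
})

test_that("reconcile partition conservation holds on randomized tables", {
  set.seed(31)
  n <- 10000L
  ids <- sprintf("DOID:%06d", sample.int(4000L, n, replace = TRUE))
  preds <- sample(c("label", "definition", "exact_synonym"), n, TRUE)
  texts <- sprintf("text %d", sample.int(6000L, n, TRUE))
  key <- paste(ids, preds, texts)
  keep <- !duplicated(key)
  triples <- data.frame(subject_id = ids[keep], predicate_id = preds[keep],
                        text = texts[keep], lang = "en",
                        stringsAsFactors = FALSE)
  # prior records: a random subset of triples, with a fraction mutated
  take <- sample.int(nrow(triples), floor(nrow(triples) * 0.6))
  recs <- data.frame(subject_id = triples$subject_id[take],
                     predicate_id = triples$predicate_id[take],
                     source_lang = "en",
                     source_text = triples$text[take],
                     target_lang = "es",
                     target_text = "tr",
                     status = sample(c("exact", "passed", "pending"),
                                     length(take), TRUE),
                     stringsAsFactors = FALSE)
  mut <- sample.int(nrow(recs), floor(nrow(recs) * 0.2))
  recs$source_text[mut] <- paste0(recs$source_text[mut], " edited")
  recs <- recs[!duplicated(paste(recs$subject_id, recs$predicate_id,
                                 recs$source_text)), ]
  r <- reconcile(triples, recs)
  expect_equal(nrow(r$carried) + nrow(r$retired), nrow(recs))
  expect_equal(nrow(r$carried) + nrow(r$changed) +
                 nrow(r$new_untranslated), nrow(triples))
  # no overlap between subsets
  sub <- make_subsets(r)
  expect_equal(anyDuplicated(c(
    paste(sub$needs_translation$subject_id,
          sub$needs_translation$predicate_id,
          sub$needs_translation$text),
    paste(sub$changed_text$subject_id, sub$changed_text$predicate_id,
          sub$changed_text$text),
    paste(sub$pending_review$subject_id, sub$pending_review$predicate_id,
          sub$pending_review$source_text))), 0L)
})

test_that("make_subsets applies the three membership rules", {
  recs <- ledger_fixture()
  triples <- data.frame(subject_id = c(recs$subject_id, "DOID:42"),
                        predicate_id = c(recs$predicate_id, "label"),
                        text = c("CHANGED", recs$source_text[2:3],
                                 "brand new"),
                        lang = "en", stringsAsFactors = FALSE)
  r <- reconcile(triples, recs)
  sub <- make_subsets(r)
  expect_equal(nrow(sub$needs_translation), 1L)
  expect_identical(sub$needs_translation$text, "brand new")
  expect_equal(nrow(sub$changed_text), 1L)
  expect_identical(sub$changed_text$text, "CHANGED")
  expect_equal(nrow(sub$pending_review), 1L)
  expect_identical(sub$pending_review$status, "pending")

  empty <- reconcile(triples[0, ], recs[0, ])
  sub0 <- make_subsets(empty)
  expect_true(all(vapply(sub0, nrow, integer(1)) == 0L))
})

test_that("definition policy releases signed-off pending definitions only", {
  recs <- ledger_fixture()
  recs$signoff <- c("TRUE", "TRUE", "TRUE")
  # row 1: pending? no (passed) -> unchanged; row 3 is a pending definition
  recs$status <- c("passed", "exact", "pending")
  expect_warning(out <- apply_definition_policy(recs),
                 "non-definition")
  expect_identical(out$status, c("passed", "exact", "pending_included"))

  # passed definition stays put, no warning when only definitions signed
  recs2 <- ledger_fixture()[3, ]
  recs2$status <- "passed"
  recs2$signoff <- "TRUE"
  expect_silent(out2 <- apply_definition_policy(recs2))
  expect_identical(out2$status, "passed")
})

test_that("release templates carry directive rows and eligibility rules", {
  recs <- ledger_fixture()  # passed, exact, pending
  t <- emit_release_templates(recs)
  # directive row + the two eligible records; pending excluded
  expect_equal(nrow(t$international_table), 3L)
  expect_equal(nrow(t$target_language_table), 3L)
  expect_identical(t$international_table$subject_id[1], "ID")
  expect_match(t$international_table$source_text[1], "@en")
  expect_match(t$international_table$target_text[1], "@es")
  expect_false("DOID:14566" %in% t$international_table$subject_id)
  expect_true("acronym" %in% names(t$international_table))

  # empty target text on an eligible record is an error
  recs$target_text[1] <- ""
  expect_error(emit_release_templates(recs), "empty target")
})

test_that("summarize_records counts, percentages and coverage", {
  recs <- data.frame(
    predicate_id = rep("label", 10),
    category = c(rep("exact", 4), rep("passed", 4), rep("pending", 2)),
    stringsAsFactors = FALSE)
  rep1 <- summarize_records(recs)
  lab <- rep1$table[rep1$table$text_type == "labels", ]
  expect_equal(lab$count, c(4, 4, 2))
  expect_equal(lab$percent, c(40, 40, 20))
  expect_equal(sum(lab$percent), 100, tolerance = 0.05)

  expect_equal(format_pct(11078, 11946), 92.73)

  rep0 <- summarize_records(recs[0, ])
  expect_equal(nrow(rep0$table), 0L)

  # percentages per type sum to 100 within rounding on random input
  set.seed(5)
  recs2 <- data.frame(
    predicate_id = sample(c("label", "definition", "exact_synonym",
                            "related_synonym"), 200, TRUE),
    category = sample(c("exact", "passed", "pending"), 200, TRUE),
    stringsAsFactors = FALSE)
  rep2 <- summarize_records(recs2)
  sums <- tapply(rep2$table$percent, rep2$table$text_type, sum)
  expect_true(all(abs(sums - 100) <= 0.05))
  expect_equal(sum(rep2$table$count), 200L)
})
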