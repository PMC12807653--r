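# Translation-ledger lifecycle: TSV dialect, reconciliation against
# current ontology text triples, task subsets, release templates and
# category reports.

# TSV dialect: UTF-8, header row, no quoting; literal tab/newline in
# text escaped as \t and \n (and backslash as \\). Chosen so that the
# master file is byte-stable and diff-friendly.

.tsv_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.tsv_unescape <- function(x) {
  # scan character-wise escape sequences left-to-right so that "\\t"
  # round-trips as backslash + t, not a tab
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", "\\" = "\\",
                             paste0("\\", nxt)))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"))
  if (nrow(df)) {
    cols <- lapply(df, function(col) .tsv_escape(as.character(col)))
    body <- do.call(paste, c(cols, sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty file (no header): ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!is.null(required)) {
    missing <- setdiff(required, header)
    if (length(missing)) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    df <- as.data.frame(setNames(replicate(length(header),
                                           character(), simplify = FALSE),
                                 header),
                        stringsAsFactors = FALSE)
    return(df)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop("malformed row(s) in ", path, " (wrong field count) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(
    setNames(lapply(seq_along(header), function(j) {
      .tsv_unescape(vapply(parts, `[[`, "", j))
    }), header),
    stringsAsFactors = FALSE)
  df
}

# Ledger schema ------------------------------------------------------------

LEDGER_COLUMNS <- c("subject_id", "predicate_id", "source_lang",
                    "source_text", "target_lang", "target_text",
                    "status", "score", "acronym", "reviewer",
                    "review_date", "method")

LEDGER_STATUSES <- c("exact", "passed", "pending", "reviewed_accepted",
                     "reviewed_rejected", "pending_included")

PREDICATE_IDS <- c("label", "definition", "exact_synonym",
                   "narrow_synonym", "broad_synonym", "related_synonym",
                   "comment")

RELEASE_STATUSES <- c("exact", "passed", "reviewed_accepted",
                      "pending_included")

.triple_key <- function(df, text_col = "source_text") {
  paste(df$subject_id, df$predicate_id, df[[text_col]], sep = "\r")
}

.check_unique_keys <- function(df, what, text_col = "source_text") {
  key <- .triple_key(df, text_col)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate triple key(s) in ", what, " at row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(key)
}

#' Read a translation ledger TSV
#'
#' Reads a master-style ledger file (UTF-8 TSV, no quoting, `\\t` and
#' `\\n` escaped inside text fields). Rows must carry unique
#' (subject_id, predicate_id, source_text) triple keys.
#'
#' @param path Path to the ledger TSV.
#' @return Data frame of ledger records.
#' @export
read_ledger <- function(path) {
  df <- .read_tsv(path, required = c("subject_id", "predicate_id",
                                     "source_lang", "source_text",
                                     "target_lang", "target_text",
                                     "status"))
  for (col in setdiff(LEDGER_COLUMNS, names(df))) df[[col]] <- ""
  df <- df[LEDGER_COLUMNS]
  df$source_text <- stringi::stri_trans_nfc(df$source_text)
  df$target_text <- stringi::stri_trans_nfc(df$target_text)
  .check_unique_keys(df, paste0("ledger '", path, "'"))
  df
}

#' Write the sorted master ledger
#'
#' Sorts records lexicographically (binary code-point order, locale
#' independent) by (subject_id, predicate_id, source_text) and writes
#' the canonical TSV. Re-serializing a file read with [read_ledger()]
#' is byte-identical.
#'
#' @param records Ledger data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_master <- function(records, path) {
  for (col in setdiff(LEDGER_COLUMNS, names(records))) records[[col]] <- ""
  records <- records[LEDGER_COLUMNS]
  .check_unique_keys(records, "records")
  old <- Sys.getlocale("LC_COLLATE")
  Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  ord <- order(records$subject_id, records$predicate_id,
               records$source_text, method = "radix")
  records <- records[ord, , drop = FALSE]
  .write_tsv(records, path)
  invisible(path)
}

#' Read current ontology text triples
#'
#' A triples export has one row per (id, predicate, text) with a
#' language tag: columns `subject_id`, `predicate_id`, `text`, `lang`.
#'
#' @param path Path to the triples TSV.
#' @return Data frame of triples.
#' @export
read_triples <- function(path) {
  df <- .read_tsv(path, required = c("subject_id", "predicate_id",
                                     "text", "lang"))
  df$text <- stringi::stri_trans_nfc(df$text)
  .check_unique_keys(df, paste0("triples '", path, "'"), text_col = "text")
  df
}

#' Reconcile translated records with current ontology triples
#'
#' Matches and changes are identified by comparing identifiers,
#' predicates and source-language text (triples), using exact string
#' equality after canonical Unicode composition. The result is a
#' partition: every prior record lands in exactly one of
#' `carried` / `retired`, and every current triple in exactly one of
#' `carried` / `changed` / `new_untranslated`.
#'
#' * `carried`: records whose full triple key matches a current triple.
#' * `changed`: current triples whose (subject, predicate) exists among
#'   the prior records but whose text differs.
#' * `new_untranslated`: current triples with no record at all for the
#'   (subject, predicate).
#' * `retired`: prior records with no matching current triple.
#'
#' @param current_triples Data frame from [read_triples()].
#' @param prior_records Ledger data frame from [read_ledger()].
#' @return A list of class `reconcile_result` with the four parts.
#' @export
reconcile <- function(current_triples, prior_records) {
  tkey <- .check_unique_keys(current_triples, "current_triples",
                             text_col = "text")
  rkey <- .check_unique_keys(prior_records, "prior_records")

  carried_mask <- rkey %in% tkey
  carried <- prior_records[carried_mask, , drop = FALSE]
  retired <- prior_records[!carried_mask, , drop = FALSE]

  pair_records <- paste(prior_records$subject_id,
                        prior_records$predicate_id, sep = "\r")
  pair_triples <- paste(current_triples$subject_id,
                        current_triples$predicate_id, sep = "\r")
  matched_triple <- tkey %in% rkey
  changed_mask <- !matched_triple & (pair_triples %in% pair_records)
  new_mask <- !matched_triple & !changed_mask

  structure(
    list(carried = carried,
         changed = current_triples[changed_mask, , drop = FALSE],
         new_untranslated = current_triples[new_mask, , drop = FALSE],
         retired = retired),
    class = "reconcile_result"
  )
}

#' @export
print.reconcile_result <- function(x, ...) {
  cat(sprintf(
    "<reconcile_result> carried=%d changed=%d new_untranslated=%d retired=%d\n",
    nrow(x$carried), nrow(x$changed), nrow(x$new_untranslated),
    nrow(x$retired)))
  invisible(x)
}

#' Build task-specific data subsets from a reconcile result
#'
#' @param result A [reconcile()] result.
#' @return Named list of data frames: `needs_translation` (new
#'   untranslated triples), `pending_review` (carried records still in
#'   status `pending`), `changed_text` (current triples whose text
#'   changed). No record appears in two subsets.
#' @export
make_subsets <- function(result) {
  stopifnot(inherits(result, "reconcile_result"))
  list(
    needs_translation = result$new_untranslated,
    pending_review = result$carried[result$carried$status == "pending", ,
                                    drop = FALSE],
    changed_text = result$changed
  )
}

#' Apply the definition-inclusion policy
#'
#' Definitions score poorly under the label-optimized cutoff, so
#' machine-era definition translations below the cutoff are released
#' anyway when a fluent reviewer has glanced over them and found no
#' obvious error. Records with `predicate_id == "definition"`, status
#' `pending` and a truthy `signoff` flag move to status
#' `pending_included`; a sign-off flag on any other record is ignored
#' with a warning.
#'
#' @param records Scored ledger data frame with a logical-like
#'   `signoff` column (`"TRUE"`/`"FALSE"` or logical).
#' @return The records with statuses updated.
#' @export
apply_definition_policy <- function(records) {
  if (is.null(records$signoff)) return(records)
  signed <- as.logical(records$signoff)
  signed[is.na(signed)] <- FALSE
  eligible <- signed & records$predicate_id == "definition" &
    records$status == "pending"
  stray <- signed & records$predicate_id != "definition"
  if (any(stray)) {
    warning(sum(stray), " sign-off flag(s) on non-definition records ",
            "ignored", call. = FALSE)
  }
  records$status[eligible] <- "pending_included"
  records
}

#' Emit release template tables
#'
#' Converts release-eligible records (status `exact`, `passed`,
#' `reviewed_accepted` or `pending_included`) into template tables for
#' downstream ontology-release tooling: a first row of column names, a
#' second row of template directive strings carrying ISO 639 language
#' tags, then one data row per triple key. The international table
#' carries both the source and target text; the target-language table
#' carries the target text only. Acronym-flagged synonyms keep their
#' acronym annotation column.
#'
#' @param records Ledger data frame.
#' @return List with `international_table` and `target_language_table`
#'   data frames (directive row included as the first data row).
#' @export
emit_release_templates <- function(records) {
  eligible <- records[records$status %in% RELEASE_STATUSES, , drop = FALSE]
  if (nrow(eligible) && any(!nzchar(eligible$target_text))) {
    stop("release-eligible record(s) with empty target text: row(s) ",
         paste(which(!nzchar(eligible$target_text)), collapse = ", "),
         call. = FALSE)
  }
  src_tag <- if (nrow(eligible)) eligible$source_lang[1] else "en"
  trg_tag <- if (nrow(eligible)) eligible$target_lang[1] else "es"
  directive <- function(tag) paste0("AL ", "%predicate%", "@", tag)

  international <- data.frame(
    subject_id = c("ID", eligible$subject_id),
    predicate_id = c(">A", eligible$predicate_id),
    source_text = c(directive(src_tag), eligible$source_text),
    target_text = c(directive(trg_tag), eligible$target_text),
    acronym = c(">A oboInOwl:hasSynonymType", eligible$acronym),
    stringsAsFactors = FALSE)

  target_only <- data.frame(
    subject_id = c("ID", eligible$subject_id),
    predicate_id = c(">A", eligible$predicate_id),
    target_text = c(directive(trg_tag), eligible$target_text),
    acronym = c(">A oboInOwl:hasSynonymType", eligible$acronym),
    stringsAsFactors = FALSE)

  list(international_table = international,
       target_language_table = target_only)
}

# predicate -> reported text type
.text_type <- function(predicate_id) {
  ifelse(predicate_id == "label", "labels",
         ifelse(predicate_id == "definition", "definitions",
                ifelse(grepl("_synonym$", predicate_id), "synonyms",
                       "comments")))
}

#' Percentage formatter
#'
#' Formats a count over a total as a percentage with two decimals, the
#' convention used in the category report (e.g. 11078 of 11946 is
#' `92.73`).
#'
#' @param count,total Non-negative numbers.
#' @return Numeric percentage rounded to 2 decimal places.
#' @examples
#' format_pct(11078, 11946)  # 92.73
#' @export
format_pct <- function(count, total) {
  if (total == 0) return(NA_real_)
  round(100 * count / total, 2)
}

#' Summarize classified records into a category report
#'
#' Counts and percentages of records per text type (labels, synonyms,
#' definitions, comments) and classification category (exact, passed,
#' pending). Optionally reports translated coverage per type when the
#' totals of the full ontology are supplied.
#'
#' @param records Data frame with `predicate_id` and `category`
#'   columns.
#' @param totals Optional named numeric vector of total text-element
#'   counts per type, for coverage fractions.
#' @return A list of class `translation_report` with a `table` data
#'   frame (`text_type`, `category`, `count`, `percent`) and an
#'   optional `coverage` data frame.
#' @export
summarize_records <- function(records, totals = NULL) {
  categories <- c("exact", "passed", "pending")
  if (nrow(records)) {
    type <- .text_type(records$predicate_id)
    cat_col <- if (!is.null(records$category)) records$category else records$status
    # reviewed/pending_included statuses report under their review
    # outcome's original category bucket
    cat_col[cat_col == "pending_included"] <- "pending"
    cat_col[cat_col == "reviewed_accepted"] <- "passed"
    cat_col[cat_col == "reviewed_rejected"] <- "pending"
    types <- unique(.text_type(PREDICATE_IDS))
    types <- types[types %in% type]
    rows <- list()
    for (ty in types) {
      n_type <- sum(type == ty)
      for (cc in categories) {
        cnt <- sum(type == ty & cat_col == cc)
        rows[[length(rows) + 1L]] <- data.frame(
          text_type = ty, category = cc, count = cnt,
          percent = format_pct(cnt, n_type), stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
  } else {
    tab <- data.frame(text_type = character(), category = character(),
                      count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE)
  }
  coverage <- NULL
  if (!is.null(totals)) {
    type <- if (nrow(records)) .text_type(records$predicate_id) else character()
    coverage <- do.call(rbind, lapply(names(totals), function(ty) {
      translated <- sum(type == ty)
      data.frame(text_type = ty, translated = translated,
                 total = as.numeric(totals[[ty]]),
                 percent = format_pct(translated, totals[[ty]]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, coverage = coverage),
            class = "translation_report")
}

#' @export
print.translation_report <- function(x, ...) {
  if (!nrow(x$table)) {
    cat("Translation report: no records\n")
    return(invisible(x))
  }
  cat("Text type    Category   Total   Percent\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    first <- i == 1L || x$table$text_type[i - 1L] != r$text_type
    cat(sprintf("%-12s %-9s %6d %9.2f\n",
                if (first) r$text_type else "", r$category, r$count,
                r$percent))
  }
  if (!is.null(x$coverage)) {
    cat("\nCoverage\n")
    for (i in seq_len(nrow(x$coverage))) {
      r <- x$coverage[i, ]
      cat(sprintf("%-12s %6d / %6d = %6.2f%%\n", r$text_type,
                  r$translated, r$total, r$percent))
    }
  }
  invisible(x)
}

#' Write a report as TSV
#'
#' @param report A [summarize_records()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  .write_tsv(report$table, path)
  invisible(path)
}
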