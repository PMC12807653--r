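# Translation-unit table IO (the scoring/calibration input format).

UNIT_COLUMNS <- c("subject_id", "predicate_id", "source_lang",
                  "source_text", "translation_lang", "professional_text",
                  "machine_forward_text", "machine_back_text")

#' Read a translation-unit TSV
#'
#' One row per ontology text element with its four texts: the source
#' text, the professional translation, the machine forward translation
#' and the machine backtranslation. Machine translations are inputs
#' here -- no translation service is ever called. A `verdict` column
#' (accept/reject), when present, makes the table usable for
#' calibration.
#'
#' @param path Path to the units TSV.
#' @return Data frame of translation units.
#' @export
read_units <- function(path) {
  df <- .read_tsv(path, required = UNIT_COLUMNS)
  for (col in c("source_text", "professional_text",
                "machine_forward_text", "machine_back_text")) {
    df[[col]] <- stringi::stri_trans_nfc(df[[col]])
  }
  df
}

#' Write a translation-unit TSV
#'
#' @param units Data frame of translation units.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_units <- function(units, path) {
  .write_tsv(units, path)
  invisible(path)
}
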