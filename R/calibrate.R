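# Penalty-weight and cutoff calibration against manually reviewed
# translations, by grid search with an asymmetric preference against
# false positives.

#' Confusion counts of the automatic classifier against human verdicts
#'
#' Scores every labeled unit with [score_translation_unit()] under
#' `config`. Auto-positive means category `exact` or `passed`. A false
#' positive is an auto-passed unit the human reviewer rejected; a
#' false negative is an auto-pending unit the reviewer accepted.
#'
#' @param units Data frame of translation units with a `verdict`
#'   column (`"accept"` or `"reject"`).
#' @param config A [score_config()].
#' @return Named integer vector with `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_config <- function(units, config = score_config()) {
  if (!nrow(units)) stop("at least one labeled unit required",
                         call. = FALSE)
  if (is.null(units$verdict) ||
      !all(units$verdict %in% c("accept", "reject"))) {
    stop("units must carry a binary verdict column (accept|reject)",
         call. = FALSE)
  }
  scored <- score_units(units, config)
  auto_pos <- scored$category %in% c("exact", "passed")
  accept <- scored$verdict == "accept"
  c(tp = sum(auto_pos & accept),
    fp = sum(auto_pos & !accept),
    tn = sum(!auto_pos & !accept),
    fn = sum(!auto_pos & accept))
}

# re-classify pre-computed final scores under a different cutoff; used
# to avoid re-running the transformation search for every cutoff value
.confusion_at_cutoff <- function(final_scores, accept, cutoff) {
  auto_pos <- final_scores > cutoff
  c(tp = sum(auto_pos & accept),
    fp = sum(auto_pos & !accept),
    tn = sum(!auto_pos & !accept),
    fn = sum(!auto_pos & accept))
}

#' Grid-search calibration of penalties and cutoff
#'
#' Evaluates every combination of the supplied penalty weights and
#' cutoffs on a labeled unit set and selects the configuration that
#' minimizes (false positives, false negatives) lexicographically --
#' the operational form of a strong preference against false
#' positives. Deterministic tie-break: smaller cutoff, then smaller
#' `char_weight`, `word_weight`, `token_penalty` in that order.
#' Alternatively, `fp_weight` switches to minimizing the weighted sum
#' `fp_weight * FP + FN` for sensitivity analysis.
#'
#' Scores depend on the penalty weights but not on the cutoff, so the
#' expensive transformation search runs once per weight combination
#' and all cutoffs reuse its scores.
#'
#' @param units Labeled unit data frame (see [evaluate_config()]).
#' @param char_grid,word_grid,token_grid,cutoff_grid Numeric vectors of
#'   candidate values. Defaults bracket the production values.
#' @param fp_weight `NULL` for lexicographic (FP, FN) minimization, or
#'   a positive number for weighted-sum minimization.
#' @param base_config Template [score_config()] supplying stopwords and
#'   enabled transforms.
#' @return A list of class `calibration_result`: `best_config`,
#'   `confusion`, and `trace` (a data frame of every grid point with
#'   its confusion counts).
#' @export
grid_search <- function(units,
                        char_grid = seq(0.01, 0.05, by = 0.01),
                        word_grid = seq(0.02, 0.10, by = 0.01),
                        token_grid = seq(0.05, 0.30, by = 0.05),
                        cutoff_grid = seq(0.50, 0.95, by = 0.05),
                        fp_weight = NULL,
                        base_config = score_config()) {
  if (!length(char_grid) || !length(word_grid) || !length(token_grid) ||
      !length(cutoff_grid)) {
    stop("all calibration grids must be non-empty", call. = FALSE)
  }
  if (!nrow(units)) stop("at least one labeled unit required",
                         call. = FALSE)
  if (is.null(units$verdict) ||
      !all(units$verdict %in% c("accept", "reject"))) {
    stop("units must carry a binary verdict column (accept|reject)",
         call. = FALSE)
  }
  accept <- units$verdict == "accept"
  trace <- list()
  best <- NULL
  for (tk in sort(token_grid)) {
    for (ww in sort(word_grid)) {
      for (cw in sort(char_grid)) {
        cfg <- score_config(char_weight = cw, word_weight = ww,
                            token_penalty = tk,
                            cutoff = base_config$cutoff,
                            stopwords = base_config$stopwords,
                            transforms = base_config$transforms)
        scored <- score_units(units, cfg)
        for (co in sort(cutoff_grid)) {
          conf <- .confusion_at_cutoff(scored$final_score, accept, co)
          trace[[length(trace) + 1L]] <- data.frame(
            char_weight = cw, word_weight = ww, token_penalty = tk,
            cutoff = co, tp = conf[["tp"]], fp = conf[["fp"]],
            tn = conf[["tn"]], fn = conf[["fn"]])
          objective <- if (is.null(fp_weight)) {
            c(conf[["fp"]], conf[["fn"]])
          } else {
            c(fp_weight * conf[["fp"]] + conf[["fn"]], 0)
          }
          cand <- list(objective = objective,
                       tie = c(co, cw, ww, tk),
                       config = cfg, cutoff = co, confusion = conf)
          if (is.null(best) || .cal_better(cand, best)) best <- cand
        }
      }
    }
  }
  best_config <- score_config(
    char_weight = best$config$char_weight,
    word_weight = best$config$word_weight,
    token_penalty = best$config$token_penalty,
    cutoff = best$cutoff,
    stopwords = base_config$stopwords,
    transforms = base_config$transforms)
  structure(
    list(best_config = best_config, confusion = best$confusion,
         trace = do.call(rbind, trace)),
    class = "calibration_result")
}

# lexicographic comparison: objective first, then the tie-break vector
.cal_better <- function(cand, best) {
  a <- c(cand$objective, cand$tie)
  b <- c(best$objective, best$tie)
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.calibration_result <- function(x, ...) {
  cfg <- x$best_config
  cat(sprintf(
    "<calibration_result> cutoff=%.2f char=%.2f word=%.2f token=%.2f | tp=%d fp=%d tn=%d fn=%d\n",
    cfg$cutoff, cfg$char_weight, cfg$word_weight, cfg$token_penalty,
    x$confusion[["tp"]], x$confusion[["fp"]], x$confusion[["tn"]],
    x$confusion[["fn"]]))
  invisible(x)
}
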