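#' F-measure from precision and recall
#'
#' `2 * p * r / (p + r)`, defined as 0 when both are 0.
#'
#' @param precision,recall Numeric vectors (same scale, e.g. both percentages
#'   or both fractions).
#' @return Numeric vector on the same scale.
#' @examples
#' f_measure(91.78, 88.59) # ~90.16
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Read a gold-standard coding file
#'
#' TSV with columns phrase and code (or the literal `NO_MATCH`).
#'
#' @param path Path to the gold TSV.
#' @return Tibble with columns `phrase`, `code`.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2
  if (any(bad)) abort(sprintf("Gold file row(s) with fewer than 2 columns: %s",
                              paste(head(which(bad), 5), collapse = ", ")))
  tibble(phrase = trimws(vapply(fields, `[[`, character(1), 1)),
         code = trimws(vapply(fields, `[[`, character(1), 2)))
}

#' Evaluate coding results against a gold standard
#'
#' Counts follow the coding-specific definitions: a true positive is a phrase
#' assigned its gold code; a false negative is a gold-coded phrase assigned a
#' different code or `NO_MATCH`; a false positive is a gold-`NO_MATCH` phrase
#' that was nevertheless assigned a code. Note these differ from the usual
#' classification bookkeeping (a wrong code counts only against recall, not
#' precision); `standard_metrics = TRUE` switches to the conventional variant
#' in which any wrong or spurious assignment is also a false positive.
#'
#' @param results Tibble from [code_phrases()] (columns `phrase`, `assigned`).
#' @param gold Tibble with columns `phrase`, `code`, or a named character
#'   vector `phrase -> code`; `NO_MATCH` marks phrases with no gold code.
#' @param standard_metrics Use the conventional FP definition. Default
#'   `FALSE`.
#' @param allow_missing If `TRUE`, result phrases absent from the gold table
#'   are excluded with a message; the default is an error naming the phrase.
#' @return An object of class `radcoder_eval`: list with `tp`, `fn`, `fp`,
#'   `precision`, `recall`, `f1`, `n`, `undefined` (flags for 0/0 ratios
#'   reported as 0) and `standard_metrics`.
#' @export
evaluate_coding <- function(results, gold, standard_metrics = FALSE,
                            allow_missing = FALSE) {
  if (!is.data.frame(gold)) {
    gold <- tibble(phrase = names(gold), code = unname(gold))
  }
  idx <- match(results$phrase, gold$phrase)
  if (anyNA(idx)) {
    missing <- results$phrase[is.na(idx)]
    if (!allow_missing) {
      abort(sprintf("Phrase(s) missing from gold standard: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    inform(sprintf("Excluded %d phrase(s) absent from the gold standard.",
                   length(missing)))
    results <- results[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  gold_code <- gold$code[idx]
  assigned <- results$assigned
  has_gold <- gold_code != "NO_MATCH"
  has_assigned <- assigned != "NO_MATCH"

  tp <- sum(has_assigned & assigned == gold_code)
  fn <- sum(has_gold & assigned != gold_code)
  fp <- if (standard_metrics) {
    sum(has_assigned & assigned != gold_code)
  } else {
    sum(!has_gold & has_assigned)
  }

  undefined <- c(precision = tp + fp == 0, recall = tp + fn == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0

  structure(
    list(tp = tp, fn = fn, fp = fp,
         precision = precision, recall = recall,
         f1 = f_measure(precision, recall),
         n = nrow(results), undefined = undefined,
         standard_metrics = standard_metrics),
    class = "radcoder_eval"
  )
}

#' @export
print.radcoder_eval <- function(x, ...) {
  cat(sprintf("<radcoder_eval>%s %d phrases\n",
              if (x$standard_metrics) " (standard metrics)" else "", x$n))
  cat(sprintf("  TP %d  FN %d  FP %d\n", x$tp, x$fn, x$fp))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  if (any(x$undefined)) {
    cat(sprintf("  undefined (reported as 0): %s\n",
                paste(names(x$undefined)[x$undefined], collapse = ", ")))
  }
  invisible(x)
}

#' @export
#' @method glance radcoder_eval
glance.radcoder_eval <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, precision = x$precision,
         recall = x$recall, f1 = x$f1, n = x$n,
         standard_metrics = x$standard_metrics)
}

#' @export
#' @method tidy radcoder_eval
tidy.radcoder_eval <- function(x, ...) {
  tibble(metric = c("tp", "fn", "fp", "precision", "recall", "f1"),
         value = c(x$tp, x$fn, x$fp, x$precision, x$recall, x$f1))
}

#' Write an evaluation report as JSON
#'
#' `{tp, fn, fp, precision, recall, f1}`, deterministic formatting.
#'
#' @param report A `radcoder_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(tp = report$tp, fn = report$fn, fp = report$fp,
         precision = report$precision, recall = report$recall,
         f1 = report$f1, n = report$n),
    path, auto_unbox = TRUE, digits = 12
  )
  invisible(path)
}
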