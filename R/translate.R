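#' Look up a source phrase in the bilingual dictionary
#'
#' Exact match on the normalised phrase; returns all stored targets in row
#' order. A miss is an empty character vector, not an error.
#'
#' @param dict Dictionary tibble (`source`, `target`).
#' @param phrase Single source-language phrase.
#' @return Character vector of target phrases (possibly empty).
#' @export
dictionary_lookup <- function(dict, phrase) {
  assert_scalar_chr(phrase, "phrase")
  key <- normalize_term(phrase)
  dict$target[dict$source == key]
}

#' Construct a translator backend
#'
#' A backend is a name plus a function mapping one source phrase to a
#' character vector of target phrases (possibly empty). This abstracts any
#' external machine-translation service behind a deterministic contract.
#'
#' @param name Backend name.
#' @param translate Function `function(phrase) -> character()`.
#' @return An object of class `radcoder_translator`.
#' @export
translator_backend <- function(name, translate) {
  assert_scalar_chr(name, "name")
  if (!is.function(translate)) abort("`translate` must be a function.")
  structure(list(name = name, translate = translate),
            class = "radcoder_translator")
}

#' Deterministic table-driven mock translator
#'
#' Echoes a fixed lookup table, so every downstream result is reproducible.
#' This is the stand-in used in tests and synthetic benchmarks for a real
#' machine-translation service.
#'
#' @param table Tibble/data frame with columns `source`, `target`, or a path
#'   to a two-column TSV. Multiple rows per source yield multiple candidates.
#' @return A `radcoder_translator`.
#' @export
mock_translator <- function(table) {
  if (is.character(table) && length(table) == 1) {
    table <- read_glossary(table)
  }
  tab <- tibble(source = normalize_term(table$source),
                target = as.character(table$target))
  translator_backend("mock", function(phrase) {
    tab$target[tab$source == normalize_term(phrase)]
  })
}

#' Hybrid dictionary + external translation of one phrase
#'
#' Runs dictionary lookup and the external backend in parallel and keeps the
#' deduplicated union of their candidates: when both agree the single shared
#' candidate is tagged `"both"`; when only one backend produces output its
#' result is taken; when they differ, all candidates are kept for downstream
#' similarity scoring. An external backend that throws is logged and treated
#' as returning nothing, so translation degrades to dictionary-only.
#'
#' @param phrase Single source phrase.
#' @param dict Dictionary tibble.
#' @param external A `radcoder_translator`.
#' @return Tibble with columns `text` (candidate target phrase, normalised)
#'   and `origin` (`"dictionary"`, `"external"`, or `"both"`), plus attributes
#'   `source` (the input phrase) and `failed` (`TRUE` iff no candidates).
#' @seealso [translate_phrases()] for the data-frame-first vectorised version.
#' @export
hybrid_translate <- function(phrase, dict, external) {
  assert_scalar_chr(phrase, "phrase")
  d <- normalize_term(dictionary_lookup(dict, phrase))
  e <- tryCatch(
    normalize_term(external$translate(phrase)),
    error = function(cnd) {
      warn(sprintf("External translator '%s' failed on '%s': %s",
                   external$name, phrase, conditionMessage(cnd)))
      character(0)
    }
  )
  d <- unique(d[nzchar(d)])
  e <- unique(e[nzchar(e)])
  texts <- unique(c(d, e))
  origin <- dplyr::case_when(
    texts %in% d & texts %in% e ~ "both",
    texts %in% d ~ "dictionary",
    TRUE ~ "external"
  )
  out <- tibble(text = texts, origin = origin)
  attr(out, "source") <- phrase
  attr(out, "failed") <- nrow(out) == 0
  out
}

#' Did a translation set fail?
#'
#' @param x Result of [hybrid_translate()].
#' @return Logical scalar.
#' @export
translation_failed <- function(x) isTRUE(attr(x, "failed")) || nrow(x) == 0

#' Translate a table of phrases
#'
#' Vectorised, pipe-friendly wrapper over [hybrid_translate()].
#'
#' @param phrases Character vector, or data frame with a `phrase` column.
#' @param dict Dictionary tibble.
#' @param external A `radcoder_translator`.
#' @return Long tibble with columns `phrase`, `text`, `origin`, `failed`.
#'   A failed phrase contributes one row with `NA` text/origin and
#'   `failed = TRUE`.
#' @export
translate_phrases <- function(phrases, dict, external) {
  if (is.data.frame(phrases)) phrases <- phrases$phrase
  purrr::map_dfr(phrases, function(p) {
    ts <- hybrid_translate(p, dict, external)
    if (translation_failed(ts)) {
      tibble(phrase = p, text = NA_character_, origin = NA_character_,
             failed = TRUE)
    } else {
      tibble(phrase = p, text = ts$text, origin = ts$origin, failed = FALSE)
    }
  })
}
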