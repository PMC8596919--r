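#' Canonicalise a term for matching
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' surrounding punctuation and whitespace. This is the canonical form used for
#' every exact-match comparison in the package: dictionary keys, translation
#' dedup, and lexicon term matching.
#'
#' @param x Character vector of terms.
#' @return Character vector of the same length.
#' @examples
#' normalize_term(c("  Lobe of  Lung ", "nodule,"))
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  trimws(x)
}

#' Tokenize phrases into lowercase word tokens
#'
#' Splits on runs of characters that are neither letters, digits (Unicode
#' classes) nor underscores, after lowercasing; the underscore counts as a
#' word character so synthetic identifiers survive intact. No stemming is
#' applied; inflectional variation is absorbed upstream by fuzzy dictionary
#' extraction instead.
#'
#' @param x Character vector of phrases.
#' @return List of character vectors, one per input phrase.
#' @examples
#' tokenize("Upper lobe of lung")
#' @export
tokenize <- function(x) {
  parts <- strsplit(tolower(as.character(x)), "[^\\p{L}\\p{N}_]+", perl = TRUE)
  lapply(parts, function(t) t[nzchar(t)])
}

# single-phrase convenience
tokenize1 <- function(x) tokenize(x)[[1]]

is_single_word <- function(x) {
  lengths(tokenize(x)) <= 1L
}

assert_scalar_chr <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
  invisible(x)
}
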