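#' Read a standard lexicon from a TSV file
#'
#' The lexicon is the coding target: one concept per row with an opaque code
#' (RadLex-style, e.g. `"RID39357"`), a preferred name, and an optional
#' pipe-separated synonym list in the third column. Rows may have two or three
#' columns; no header by default.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param header Logical; skip a header row when `TRUE`.
#' @return A tibble with columns `code`, `preferred_name` and a list-column
#'   `synonyms` (character vectors, possibly empty). Row order follows the file.
#' @details Codes must be unique; a duplicate code is a hard error naming the
#'   code. An empty preferred name is a hard error naming the row. Synonyms are
#'   normalised with [normalize_term()]; synonyms equal to the preferred name
#'   after normalisation are dropped, as are duplicates.
#' @seealso [write_lexicon()], [lexicon_terms()]
#' @export
read_lexicon <- function(path, header = FALSE) {
  if (!file.exists(path)) abort(sprintf("Lexicon file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("Lexicon file '%s' is empty; returning an empty lexicon.", path))
    return(tibble(code = character(), preferred_name = character(),
                  synonyms = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < 2) {
      abort(sprintf("Lexicon row %d has fewer than 2 columns.", i))
    }
    code <- trimws(f[[1]])
    pref <- normalize_term(f[[2]])
    if (!nzchar(pref)) {
      abort(sprintf("Empty preferred name in lexicon row %d (code '%s').", i, code))
    }
    syn <- if (length(f) >= 3 && nzchar(f[[3]])) {
      s <- normalize_term(strsplit(f[[3]], "|", fixed = TRUE)[[1]])
      unique(s[nzchar(s) & s != pref])
    } else character(0)
    tibble(code = code, preferred_name = pref, synonyms = list(syn))
  })
  out <- dplyr::bind_rows(rows)
  dup <- out$code[duplicated(out$code)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate lexicon code(s): %s", paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write a lexicon tibble to TSV
#'
#' @param lexicon Tibble as returned by [read_lexicon()] or [make_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  syn <- purrr::map_chr(lexicon$synonyms, paste, collapse = "|")
  lines <- ifelse(nzchar(syn),
                  paste(lexicon$code, lexicon$preferred_name, syn, sep = "\t"),
                  paste(lexicon$code, lexicon$preferred_name, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Flatten a lexicon to one row per term
#'
#' Expands preferred names and synonyms into a long table, the shape used for
#' candidate generation and fuzzy matching.
#'
#' @param lexicon Lexicon tibble.
#' @return Tibble with columns `code`, `term`, `is_preferred`.
#' @export
lexicon_terms <- function(lexicon) {
  pref <- tibble(code = lexicon$code, term = lexicon$preferred_name,
                 is_preferred = TRUE)
  syn <- tibble(code = rep(lexicon$code, lengths(lexicon$synonyms)),
                term = unlist(lexicon$synonyms) %||% character(0),
                is_preferred = FALSE)
  dplyr::bind_rows(pref, syn)
}
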