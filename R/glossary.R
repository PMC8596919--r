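#' Read a bilingual glossary (source, target) TSV
#'
#' Malformed rows (fewer than two non-empty fields) are skipped with a single
#' warning giving the count; absence of data is not an error.
#'
#' @param path Path to a UTF-8 TSV with columns source, target.
#' @return Tibble with columns `source`, `target` (both normalised with
#'   [normalize_term()]) and `provenance` (list-column; the file's base name).
#' @export
read_glossary <- function(path) {
  if (!file.exists(path)) abort(sprintf("Glossary file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 2 && nzchar(normalize_term(f[[1]])) && nzchar(normalize_term(f[[2]]))
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("Skipped %d malformed row(s) in glossary '%s'.", sum(!ok), path))
  }
  fields <- fields[ok]
  tibble(
    source = normalize_term(vapply(fields, `[[`, character(1), 1)),
    target = normalize_term(vapply(fields, `[[`, character(1), 2)),
    provenance = rep(list(basename(path)), length(fields))
  )
}

#' Merge bilingual glossaries into a deduplicated dictionary
#'
#' Builds the comprehensive bilingual dictionary by combining glossary files
#' and deduplicating. Identical (source, target) pairs contributed by several
#' files collapse to a single row with merged provenance; the same source with
#' different targets keeps one row per distinct target. Lookup keys are the
#' normalised source terms.
#'
#' @param paths Character vector of glossary TSV paths (at least one).
#' @return A tibble with columns `source`, `target`, `provenance` (list-column
#'   of contributing glossary names). One row per distinct (source, target)
#'   pair; the number of dictionary entries is `dplyr::n_distinct(source)`.
#' @seealso [extract_domain_dictionary()], [dictionary_lookup()]
#' @examples
#' f <- tempfile(); writeLines(c("s1\tnodule", "s2\tlung"), f)
#' merge_glossaries(f)
#' @export
merge_glossaries <- function(paths) {
  if (length(paths) < 1) abort("At least one glossary path is required.")
  all <- dplyr::bind_rows(lapply(paths, read_glossary))
  all |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      provenance = list(sort(unique(unlist(.data$provenance)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Write a bilingual dictionary to TSV
#'
#' @param dict Dictionary tibble (`source`, `target` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glossary <- function(dict, path) {
  writeLines(paste(dict$source, dict$target, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Extract the domain-specific dictionary by fuzzy lexicon matching
#'
#' Filters a merged bilingual dictionary down to entries whose targets look
#' like lexicon terms. A multi-word target matches a lexicon term (preferred
#' name or synonym) when their Levenshtein distance is at most `max_dist`
#' ("less than 4" at the default); a single-word target matches only exactly,
#' since short fuzzy matches routinely cross concept boundaries
#' (e.g. "nodule" vs "nodules" of a different concept). An entry (source) is
#' retained if any of its targets matches, and retained entries keep all their
#' targets.
#'
#' @param dict Dictionary tibble from [merge_glossaries()].
#' @param lexicon Lexicon tibble; must be non-empty.
#' @param max_dist Maximum Levenshtein distance for multi-word targets
#'   (default 3).
#' @param prefilter Use the lossless length-window prefilter
#'   (|length difference| <= max_dist) before computing distances.
#' @param match_filter Optional extra predicate `function(target, term)`
#'   applied to within-distance candidate pairs (e.g. a token-difference
#'   linguistic check); `NULL` (default) accepts all.
#' @return The retained subset of `dict`, same columns, original row order.
#' @export
extract_domain_dictionary <- function(dict, lexicon, max_dist = 3,
                                      prefilter = TRUE, match_filter = NULL) {
  if (is.null(lexicon) || nrow(lexicon) == 0) abort("Lexicon must be non-empty.")
  if (max_dist < 0) abort("`max_dist` must be >= 0.")
  terms <- unique(normalize_term(lexicon_terms(lexicon)$term))
  term_len <- nchar(terms)

  targets <- unique(dict$target)
  target_matches <- vapply(targets, function(tg) {
    single <- is_single_word(tg)
    if (single) return(tg %in% terms)
    cand <- terms
    if (prefilter) cand <- terms[abs(term_len - nchar(tg)) <= max_dist]
    if (length(cand) == 0) return(FALSE)
    d <- drop(adist(tg, cand))
    ok <- d <= max_dist
    if (!is.null(match_filter) && any(ok)) {
      ok[ok] <- vapply(cand[ok], function(tm) isTRUE(match_filter(tg, tm)), logical(1))
    }
    any(ok)
  }, logical(1))

  matched_targets <- targets[target_matches]
  keep_sources <- unique(dict$source[dict$target %in% matched_targets])
  dict[dict$source %in% keep_sources, , drop = FALSE]
}
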