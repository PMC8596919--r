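#' Generate candidate (translation, lexicon term) pairs
#'
#' Cross product of the translation candidates of one phrase with every
#' lexicon term (preferred names and synonyms), each pair carrying its concept
#' code. The optional token-overlap prefilter drops pairs whose token sets are
#' disjoint, which shrinks the scoring workload without changing any exact or
#' near match.
#'
#' @param translations Result of [hybrid_translate()] (tibble with a `text`
#'   column); an empty/failed set yields an empty candidate list.
#' @param lexicon Lexicon tibble; must be non-empty.
#' @param prefilter `"none"` (default) or `"token-overlap"`.
#' @return Tibble with columns `text`, `term`, `code`, `is_preferred`.
#' @export
generate_candidates <- function(translations, lexicon,
                                prefilter = c("none", "token-overlap")) {
  prefilter <- match.arg(prefilter)
  if (is.null(lexicon) || nrow(lexicon) == 0) abort("Lexicon must be non-empty.")
  if (is.null(translations) || nrow(translations) == 0) {
    return(tibble(text = character(), term = character(), code = character(),
                  is_preferred = logical()))
  }
  terms <- lexicon_terms(lexicon)
  out <- tidyr::expand_grid(text = unique(translations$text), terms)
  if (prefilter == "token-overlap") {
    keep <- mapply(function(x, y) length(intersect(x, y)) > 0,
                   tokenize(out$text), tokenize(out$term))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Code one source phrase against the lexicon
#'
#' The full per-phrase pipeline: hybrid translation, candidate generation,
#' four-way similarity scoring, MLP synonym decision, and code assignment.
#' Among candidate pairs the MLP labels synonym, the concept of the
#' highest-probability pair wins; ties break by higher Wu-Palmer score, then
#' lexicographically smaller code. When no pair is labelled synonym (or
#' translation fails outright) the phrase gets `NO_MATCH`.
#'
#' @param phrase Single source phrase.
#' @param dict Domain dictionary tibble.
#' @param external A `radcoder_translator`.
#' @param lexicon Lexicon tibble.
#' @param embeddings A `radcoder_cbow` (or `NULL`).
#' @param taxonomy A `radcoder_taxonomy` (or `NULL`).
#' @param word_map Token-to-node tibble; defaults to
#'   [taxonomy_word_map()] of `taxonomy`.
#' @param mlp A trained `radcoder_mlp`.
#' @param threshold Optional override of the MLP decision threshold.
#' @param k_alternatives Number of runner-up codes to keep. Default 3.
#' @param prefilter Candidate prefilter, see [generate_candidates()].
#' @return One-row tibble: `phrase`, `assigned` (code or `"NO_MATCH"`),
#'   `score` (winning probability; `NA` for `NO_MATCH`), `n_candidates`, and
#'   list-column `alternatives` (tibble `code`, `probability`).
#' @export
code_phrase <- function(phrase, dict, external, lexicon, embeddings = NULL,
                        taxonomy = NULL, word_map = NULL, mlp,
                        threshold = NULL, k_alternatives = 3,
                        prefilter = "none") {
  no_match <- function(n_cand) {
    tibble(phrase = phrase, assigned = "NO_MATCH", score = NA_real_,
           n_candidates = n_cand,
           alternatives = list(tibble(code = character(),
                                      probability = numeric())))
  }
  ts <- hybrid_translate(phrase, dict, external)
  if (translation_failed(ts)) return(no_match(0L))
  cands <- generate_candidates(ts, lexicon, prefilter)
  if (nrow(cands) == 0) return(no_match(0L))
  if (is.null(word_map) && !is.null(taxonomy)) {
    word_map <- taxonomy_word_map(taxonomy)
  }
  scored <- score_pairs(tibble(a = cands$text, b = cands$term),
                        embeddings, taxonomy, word_map)
  pred <- predict_synonym(mlp, scored, threshold = threshold)
  scored$code <- cands$code
  scored$probability <- pred$probability
  syn <- scored[pred$label == 1L, , drop = FALSE]
  if (nrow(syn) == 0) return(no_match(nrow(cands)))
  per_code <- syn |>
    dplyr::group_by(.data$code) |>
    dplyr::slice_max(.data$probability, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$probability), dplyr::desc(.data$wup),
                   .data$code)
  winner <- per_code[1, ]
  alts <- per_code[-1, , drop = FALSE]
  alts <- utils::head(tibble(code = alts$code, probability = alts$probability),
                      k_alternatives)
  tibble(phrase = phrase, assigned = winner$code, score = winner$probability,
         n_candidates = nrow(cands), alternatives = list(alts))
}

#' Code a batch of phrases
#'
#' Data-frame-first wrapper over [code_phrase()].
#'
#' @param phrases Character vector, or data frame with a `phrase` column.
#' @inheritParams code_phrase
#' @param ... Passed to [code_phrase()].
#' @return Tibble with one row per phrase (see [code_phrase()]).
#' @export
code_phrases <- function(phrases, dict, external, lexicon, embeddings = NULL,
                         taxonomy = NULL, word_map = NULL, mlp, ...) {
  if (is.data.frame(phrases)) phrases <- phrases$phrase
  if (is.null(word_map) && !is.null(taxonomy)) {
    word_map <- taxonomy_word_map(taxonomy)
  }
  purrr::map_dfr(phrases, code_phrase, dict = dict, external = external,
                 lexicon = lexicon, embeddings = embeddings,
                 taxonomy = taxonomy, word_map = word_map, mlp = mlp, ...)
}

#' Write coding results as JSON lines
#'
#' One JSON object per phrase: `phrase`, `assigned`, `score`, `n_candidates`,
#' `alternatives` (array of code/probability records). Deterministic output:
#' identical results produce byte-identical files.
#'
#' @param results Tibble from [code_phrases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  lines <- vapply(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    jsonlite::toJSON(
      list(phrase = row$phrase, assigned = row$assigned,
           score = row$score, n_candidates = row$n_candidates,
           alternatives = row$alternatives[[1]]),
      dataframe = "rows", auto_unbox = TRUE, digits = 12, na = "null"
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read coding results written by [write_results()]
#'
#' @param path Path to a JSON-lines file.
#' @return Tibble in the shape produced by [code_phrases()].
#' @export
read_results <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  purrr::map_dfr(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    alts <- as_tibble(obj$alternatives)
    if (nrow(alts) == 0) alts <- tibble(code = character(), probability = numeric())
    tibble(phrase = obj$phrase, assigned = obj$assigned,
           score = obj$score %||% NA_real_,
           n_candidates = obj$n_candidates,
           alternatives = list(alts))
  })
}
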