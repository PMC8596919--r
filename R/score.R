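#' Score phrase pairs with the four similarity measures
#'
#' Data-frame-first scorer: takes a table of pairs and appends the four
#' per-pair similarity scores that feed the ensemble — normalised Levenshtein
#' (`lev`), token-set Jaccard (`jac`), CBOW embedding cosine (`cbow`) and
#' phrase-level Wu-Palmer (`wup`) — plus imputation flags. A score whose
#' resource is missing (`NULL` model/taxonomy) or lacks coverage
#' (out-of-vocabulary, unresolvable tokens) is imputed 0 and flagged, so every
#' component is always in `[0, 1]`.
#'
#' @param pairs Tibble/data frame with character columns `a`, `b`. Extra
#'   columns (e.g. `label`) pass through untouched.
#' @param embeddings A `radcoder_cbow`, or `NULL` to impute `cbow = 0`.
#' @param taxonomy A `radcoder_taxonomy`, or `NULL` to impute `wup = 0`.
#' @param word_map Token-to-node tibble (see [taxonomy_word_map()]); required
#'   when `taxonomy` is given.
#' @return The input tibble with added numeric columns `lev`, `jac`, `cbow`,
#'   `wup` and logical flags `cbow_oov`, `wup_unresolved`.
#' @seealso [similarity_vector()] for a single pair.
#' @export
score_pairs <- function(pairs, embeddings = NULL, taxonomy = NULL,
                        word_map = NULL) {
  pairs <- as_tibble(pairs)
  if (!all(c("a", "b") %in% names(pairs))) {
    abort("`pairs` must have columns `a` and `b`.")
  }
  out <- pairs
  out$lev <- levenshtein_similarity(pairs$a, pairs$b)
  out$jac <- jaccard_similarity(pairs$a, pairs$b)
  if (is.null(embeddings)) {
    out$cbow <- 0
    out$cbow_oov <- TRUE
  } else {
    cb <- cbow_phrase_similarity(embeddings, pairs$a, pairs$b)
    out$cbow <- as.numeric(cb)
    out$cbow_oov <- attr(cb, "oov")
  }
  if (is.null(taxonomy)) {
    out$wup <- 0
    out$wup_unresolved <- TRUE
  } else {
    if (is.null(word_map)) word_map <- taxonomy_word_map(taxonomy)
    wp <- wup_phrase_similarity(taxonomy, word_map, pairs$a, pairs$b)
    out$wup <- as.numeric(wp)
    out$wup_unresolved <- attr(wp, "unresolved")
  }
  out
}

#' Similarity vector for a single phrase pair
#'
#' @param a,b Single phrases.
#' @inheritParams score_pairs
#' @return One-row tibble with columns `a`, `b`, `lev`, `jac`, `cbow`, `wup`,
#'   `cbow_oov`, `wup_unresolved`.
#' @export
similarity_vector <- function(a, b, embeddings = NULL, taxonomy = NULL,
                              word_map = NULL) {
  assert_scalar_chr(a, "a"); assert_scalar_chr(b, "b")
  score_pairs(tibble(a = a, b = b), embeddings, taxonomy, word_map)
}

#' Best single-score threshold classifier
#'
#' Sweeps a decision threshold over a grid for one similarity score and
#' returns the best operating point by F1. This linear baseline is the
#' comparator the ensemble is expected to beat; it is not part of the coding
#' path.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param label Binary labels (0/1).
#' @param grid Thresholds to sweep. Default `seq(0, 1, by = 0.01)`.
#' @return One-row tibble: `threshold`, `precision`, `recall`, `f1`.
#' @export
best_threshold_f1 <- function(score, label, grid = seq(0, 1, by = 0.01)) {
  label <- as.integer(label)
  rows <- purrr::map_dfr(grid, function(th) {
    pred <- as.integer(score >= th)
    tp <- sum(pred == 1 & label == 1)
    fp <- sum(pred == 1 & label == 0)
    fn <- sum(pred == 0 & label == 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    tibble(threshold = th, precision = p, recall = r, f1 = f_measure(p, r))
  })
  rows[which.max(rows$f1), ]
}
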