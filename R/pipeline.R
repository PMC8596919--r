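#' Run the full coding pipeline from fixture files
#'
#' End-to-end driver over the standard fixture layout written by
#' [simulate_benchmark()]: merge the glossaries, extract the domain
#' dictionary against the lexicon, train CBOW embeddings on the corpus, score
#' the labelled pairs, train the synonym MLP, code the phrase list with the
#' mock translator, and evaluate against the gold standard. Every stochastic
#' step is seeded from `seed` (embeddings use `seed + 1`, the ensemble
#' `seed + 2`), so repeated runs write byte-identical `results.jsonl` and
#' `report.json`.
#'
#' @param fixture_dir Directory holding `lexicon.tsv`, `taxonomy.tsv`,
#'   `corpus.txt`, `glossary_1.tsv`, `glossary_2.tsv`, `pairs.csv`,
#'   `phrases.txt`, `mock_translation.tsv`, `gold.tsv`.
#' @param out_dir Output directory for `results.jsonl` and `report.json`;
#'   `NULL` writes nothing.
#' @param seed Integer master seed for the run.
#' @param dim,window,epochs Embedding hyperparameters, see [train_cbow()].
#' @param max_dist Fuzzy-extraction threshold, see
#'   [extract_domain_dictionary()].
#' @param threshold MLP decision threshold.
#' @param ... Passed to [train_mlp()] via [fit_ensemble()].
#' @return List with `dictionary`, `domain_dictionary`, `embeddings`,
#'   `scores` (scored labelled pairs), `mlp`, `results` (coding results),
#'   `report` (a `radcoder_eval`), and `files` (written paths, if any).
#' @export
run_pipeline <- function(fixture_dir, out_dir = NULL, seed = 1L,
                         dim = 100, window = 5, epochs = 20,
                         max_dist = 3, threshold = 0.5, ...) {
  path <- function(f) file.path(fixture_dir, f)
  lexicon <- read_lexicon(path("lexicon.tsv"))
  taxonomy <- read_taxonomy(path("taxonomy.tsv"))
  word_map <- taxonomy_word_map(taxonomy)

  dictionary <- merge_glossaries(c(path("glossary_1.tsv"), path("glossary_2.tsv")))
  domain <- extract_domain_dictionary(dictionary, lexicon, max_dist = max_dist)

  corpus <- read_corpus(path("corpus.txt"))
  embeddings <- train_cbow(corpus, dim = dim, window = window,
                           epochs = epochs, seed = seed + 1L)

  pairs <- readr::read_csv(path("pairs.csv"), show_col_types = FALSE,
                           progress = FALSE)
  scores <- score_pairs(pairs, embeddings, taxonomy, word_map)
  mlp <- fit_ensemble(scores, seed = seed + 2L, threshold = threshold, ...)

  mock <- mock_translator(path("mock_translation.tsv"))
  phrases <- readLines(path("phrases.txt"), encoding = "UTF-8", warn = FALSE)
  phrases <- phrases[nzchar(trimws(phrases))]
  results <- code_phrases(phrases, domain, mock, lexicon, embeddings,
                          taxonomy, word_map, mlp)
  gold <- read_gold(path("gold.tsv"))
  report <- evaluate_coding(results, gold)

  out <- list(dictionary = dictionary, domain_dictionary = domain,
              embeddings = embeddings, scores = scores, mlp = mlp,
              results = results, report = report)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(results = file.path(out_dir, "results.jsonl"),
               report = file.path(out_dir, "report.json"))
    write_results(results, files[["results"]])
    write_eval_report(report, files[["report"]])
    out$files <- files
  }
  out
}

#' Train/test evaluation of the ensemble against single-score baselines
#'
#' Splits a scored, labelled pair table into stratified train and held-out
#' parts, fits the 4-5-5-1 ensemble on the training part, and compares its
#' held-out F1 with the best threshold classifier on each single similarity
#' score (threshold swept on the held-out part, i.e. the single-score
#' baselines get an oracle-chosen operating point) and with an equal-weight
#' mean-score baseline.
#'
#' @param scores Tibble from [score_pairs()] with a `label` column.
#' @param seed Integer seed (split + training).
#' @param test_fraction Held-out fraction. Default 0.3.
#' @param ... Passed to [fit_ensemble()].
#' @return List with `ensemble_f1`, `singles` (tibble `score`, `threshold`,
#'   `f1`), `best_single_f1`, `equal_weight_f1`, `mlp`, `n_test`.
#' @export
ensemble_benchmark <- function(scores, seed = 1L, test_fraction = 0.3, ...) {
  y <- as.integer(scores$label)
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, floor(length(ix) * test_fraction))
    }), use.names = FALSE)
  })
  train <- scores[-test_idx, , drop = FALSE]
  test <- scores[test_idx, , drop = FALSE]
  mlp <- fit_ensemble(train, seed = seed, ...)
  pred <- predict_synonym(mlp, test)
  tp <- sum(pred$label == 1 & test$label == 1)
  fp <- sum(pred$label == 1 & test$label == 0)
  fn <- sum(pred$label == 0 & test$label == 1)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  ens_f1 <- f_measure(p, r)
  singles <- purrr::map_dfr(c("lev", "jac", "cbow", "wup"), function(sc) {
    best <- best_threshold_f1(test[[sc]], test$label)
    tibble(score = sc, threshold = best$threshold, f1 = best$f1)
  })
  eq <- best_threshold_f1(rowMeans(as.matrix(test[c("lev", "jac", "cbow", "wup")])),
                          test$label)
  list(ensemble_f1 = ens_f1, singles = singles,
       best_single_f1 = max(singles$f1), equal_weight_f1 = eq$f1,
       mlp = mlp, n_test = nrow(test))
}
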