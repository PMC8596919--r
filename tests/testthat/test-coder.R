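# a rule-based stand-in trained on the planted mean rule: deterministic and
# known to label (1,1,1,1) synonym and (0,0,0,0) non-synonym
planted_mlp <- function() {
  withr::with_seed(31, {
    X <- matrix(runif(1200 * 4), 1200, 4,
                dimnames = list(NULL, c("lev", "jac", "cbow", "wup")))
    y <- as.integer(rowMeans(X) > 0.5)
    df <- tibble::as_tibble(X); df$label <- y
    fit_ensemble(df, seed = 31)
  })
}

test_that("candidate generation is the translations-by-terms cross product", {
  lex <- tibble::tibble(
    code = c("RID1", "RID2", "RID3"),
    preferred_name = c("aa bb", "cc dd", "ee ff"),
    synonyms = list("aa", "cc", "ee"))
  ts <- tibble::tibble(text = c("aa bb", "gg hh"), origin = "dictionary")
  cands <- generate_candidates(ts, lex)
  expect_equal(nrow(cands), 2 * 6)
  filtered <- generate_candidates(ts, lex, prefilter = "token-overlap")
  expect_true(all(paste(filtered$text, filtered$term) %in%
                  paste(cands$text, cands$term)))
  expect_true(all(mapply(function(x, y) length(intersect(x, y)) > 0,
                         tokenize(filtered$text), tokenize(filtered$term))))
  empty <- generate_candidates(ts[0, ], lex)
  expect_equal(nrow(empty), 0)
})

test_that("an exact dictionary translation is coded to its concept", {
  lex <- tiny_lexicon()
  f <- withr::local_tempfile(lines = "s3\tlobe of lung")
  dict <- merge_glossaries(f)
  silent <- translator_backend("silent", function(p) character(0))
  res <- code_phrase("s3", dict, silent, lex, mlp = planted_mlp())
  expect_equal(res$assigned, "RID3")
  expect_gte(res$score, 0.5)
})

test_that("failed translation and no-synonym candidates give NO_MATCH", {
  lex <- tiny_lexicon()
  f <- withr::local_tempfile(lines = "s1\tlung")
  dict <- merge_glossaries(f)
  silent <- translator_backend("silent", function(p) character(0))
  m <- planted_mlp()
  res <- code_phrase("missing", dict, silent, lex, mlp = m)
  expect_equal(res$assigned, "NO_MATCH")
  expect_true(is.na(res$score))
  # a translation far from every lexicon term is rejected by the ensemble
  far <- mock_translator(tibble::tibble(source = "junk", target = "qqqq wwww zzzz"))
  res2 <- code_phrase("junk", dict, far, lex, mlp = m)
  expect_equal(res2$assigned, "NO_MATCH")
})

test_that("ties on probability break by wup then lexicographically smaller code", {
  # two concepts with identical terms: scores and probabilities tie exactly
  lex <- tibble::tibble(code = c("RID9", "RID2"),
                        preferred_name = c("same term", "same term"),
                        synonyms = list(character(0), character(0)))
  f <- withr::local_tempfile(lines = "s1\tsame term")
  dict <- merge_glossaries(f)
  silent <- translator_backend("silent", function(p) character(0))
  res <- code_phrase("s1", dict, silent, lex, mlp = planted_mlp())
  expect_equal(res$assigned, "RID2")
})

test_that("raising the decision threshold never assigns more phrases", {
  sim <- bench_sim()
  run <- bench_run()
  mock <- mock_translator(sim$mock)
  wm <- taxonomy_word_map(sim$taxonomy)
  phrases <- sim$phrases[1:10]
  n_assigned <- vapply(c(0.3, 0.6, 0.9), function(th) {
    res <- code_phrases(phrases, run$domain_dictionary, mock, sim$lexicon,
                        run$embeddings, sim$taxonomy, wm, run$mlp,
                        threshold = th)
    sum(res$assigned != "NO_MATCH")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("coding results round-trip through JSON lines", {
  sim <- bench_sim()
  run <- bench_run()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_results(run$results, f)
  back <- read_results(f)
  expect_equal(back$phrase, run$results$phrase)
  expect_equal(back$assigned, run$results$assigned)
  expect_equal(back$score, run$results$score, tolerance = 1e-9)
})
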