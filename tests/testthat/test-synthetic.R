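test_that("configuration invariants are enforced", {
  expect_error(synth_config(regime_mix = c(glyph = 0.5, token_subset = 0.5,
                                           distributional = 0.2,
                                           taxonomic = -0.2)),
               ">= 0")
  expect_error(synth_config(regime_mix = c(glyph = 0.5, token_subset = 0.3,
                                           distributional = 0.1,
                                           taxonomic = 0.2)), "sum to 1")
  expect_error(synth_config(taxonomy_branching = 1), "branching")
  expect_error(synth_config(glossary_coverage = 1.2), "coverage")
})

test_that("the complete taxonomy has the predicted shape", {
  cfg <- synth_config(taxonomy_branching = 2, taxonomy_depth = 3)
  tax <- make_taxonomy(cfg)
  expect_equal(nrow(tax$nodes), 7)          # 2^3 - 1
  expect_equal(min(tax$depth), 1L)
  expect_equal(max(tax$depth), 3L)
  tax2 <- make_taxonomy(cfg)
  expect_equal(tax$nodes, tax2$nodes)
})

test_that("lexicon generation is deterministic with distinct RID codes", {
  cfg <- synth_config()
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  expect_equal(nrow(lex), cfg$n_concepts)
  expect_false(anyDuplicated(lex$code) > 0)
  expect_true(all(grepl("^RID\\d+$", lex$code)))
  expect_equal(lex, make_lexicon(cfg, tax))
  expect_error(make_lexicon(synth_config(n_concepts = 1000), tax), "leaf count")
})

test_that("generated glyph synonyms stay within oracle edit distance 3", {
  cfg <- synth_config()
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  for (i in seq_len(nrow(lex))) {
    for (syn in lex$synonyms[[i]]) {
      toks_p <- tokenize(lex$preferred_name[i])[[1]]
      toks_s <- tokenize(syn)[[1]]
      if (length(toks_s) < length(toks_p)) next   # token-subset variant
      expect_lte(oracle_levenshtein(syn, lex$preferred_name[i]), 3)
    }
  }
})

test_that("the corpus embeds alias/label interchangeably at the stated size", {
  cfg <- synth_config(corpus_sentences = 300)
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  corpus <- make_corpus(cfg, lex, tax)
  expect_length(corpus, 300)
  flat <- unlist(corpus)
  leaf <- unname(tax$label[lex$node[1]])
  expect_true(lex$alias[1] %in% flat && leaf %in% flat)
  expect_equal(corpus, make_corpus(cfg, lex, tax))
})

test_that("full coverage without typos makes every concept an exact lookup", {
  cfg <- synth_config(typo_rate = 0)
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  gl <- make_glossaries(cfg, lex)
  dict <- dplyr::distinct(dplyr::bind_rows(gl), source, target)
  for (i in seq_len(nrow(lex))) {
    src <- paste0("src_", tolower(lex$code[i]))
    expect_true(lex$preferred_name[i] %in% dict$target[dict$source == src])
  }
})

test_that("corrupted multi-word targets stay recoverable by fuzzy extraction", {
  cfg <- synth_config(typo_rate = 0.5)
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  gl <- make_glossaries(cfg, lex)
  terms <- lexicon_terms(lex)$term
  rows <- dplyr::bind_rows(gl)
  multi <- rows$target[lengths(tokenize(rows$target)) > 1]
  dists <- vapply(multi, function(tg) {
    min(adist(tg, terms))
  }, numeric(1))
  expect_true(all(dists <= 3))
  # and extraction indeed retains every source
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_glossary(gl$glossary_1, f1); write_glossary(gl$glossary_2, f2)
  dom <- extract_domain_dictionary(merge_glossaries(c(f1, f2)), lex)
  expect_setequal(unique(dom$source), unique(rows$source))
})

test_that("overlap rows appear in both glossaries but once after merging", {
  cfg <- synth_config()
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  gl <- make_glossaries(cfg, lex)
  overlap <- dplyr::intersect(gl$glossary_1, gl$glossary_2)
  expect_gt(nrow(overlap), 0)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_glossary(gl$glossary_1, f1); write_glossary(gl$glossary_2, f2)
  merged <- merge_glossaries(c(f1, f2))
  expect_equal(nrow(merged), nrow(dplyr::union(gl$glossary_1, gl$glossary_2)))
})

test_that("labelled pairs have the configured counts, regimes and properties", {
  cfg <- synth_config()
  tax <- make_taxonomy(cfg)
  lex <- make_lexicon(cfg, tax)
  pairs <- make_labeled_pairs(cfg, lex, tax)
  expect_equal(sum(pairs$label == 1), 400)
  expect_equal(sum(pairs$label == 0), 400)
  expect_equal(unname(table(pairs$regime[pairs$label == 1])[
    c("glyph", "token_subset", "distributional", "taxonomic")]),
    rep(100L, 4), ignore_attr = TRUE)
  glyph <- pairs[pairs$regime == "glyph", ]
  expect_true(all(levenshtein_similarity(glyph$a, glyph$b) >= 0.5))
  adv <- pairs[pairs$regime == "adversarial", ]
  expect_true(all(levenshtein_distance(adv$a, adv$b) <= 3))
  expect_true(all(adv$a != adv$b))
  expect_equal(pairs, make_labeled_pairs(cfg, lex, tax))
})

test_that("regeneration under one config writes byte-identical fixtures", {
  cfg <- synth_config(corpus_sentences = 100, n_pairs = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_benchmark(cfg, d1)
  simulate_benchmark(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = paste("file", f))
  }
})
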