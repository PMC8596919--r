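make_glossary_file <- function(lines) withr::local_tempfile(lines = lines,
                                                            .local_envir = parent.frame())

test_that("merging two glossaries sharing one identical pair gives the union", {
  f1 <- make_glossary_file(c("s1\tnodule", "s2\tlung", "s3\tpleura"))
  f2 <- make_glossary_file(c("s1\tnodule", "s4\tlobe of lung"))
  dict <- merge_glossaries(c(f1, f2))
  expect_equal(dplyr::n_distinct(dict$source), 4)
  shared <- dict[dict$source == "s1", ]
  expect_equal(nrow(shared), 1)
  expect_setequal(shared$provenance[[1]], basename(c(f1, f2)))
})

test_that("same source with different targets accumulates both targets", {
  f1 <- make_glossary_file("S1\tnodule")
  f2 <- make_glossary_file("s1\ttubercle")
  dict <- merge_glossaries(c(f1, f2))
  expect_setequal(dict$target[dict$source == "s1"], c("nodule", "tubercle"))
})

test_that("merging with an empty glossary is the identity", {
  f1 <- make_glossary_file(c("s1\ta", "s2\tb", "s3\tc", "s4\td", "s5\te"))
  f2 <- make_glossary_file(character(0))
  dict <- merge_glossaries(c(f1, f2))
  expect_equal(dplyr::n_distinct(dict$source), 5)
})

test_that("merge is order-insensitive up to row order", {
  f1 <- make_glossary_file(c("s1\ta", "s2\tb"))
  f2 <- make_glossary_file(c("s2\tb", "s3\tc"))
  d12 <- merge_glossaries(c(f1, f2))
  d21 <- merge_glossaries(c(f2, f1))
  expect_equal(d12[c("source", "target")], d21[c("source", "target")])
})

test_that("malformed rows are skipped with a warning; zero paths error", {
  f <- make_glossary_file(c("s1\ta", "only-one-column", "s2\tb"))
  expect_warning(g <- read_glossary(f), "1 malformed")
  expect_equal(nrow(g), 2)
  expect_error(merge_glossaries(character(0)), "At least one")
})

test_that("fuzzy extraction keeps close multi-word targets, exact single words", {
  lex <- tiny_lexicon()
  f <- make_glossary_file(c(
    "s1\tlobes of lung",   # distance 1 from "lobe of lung", multi-word
    "s2\tnodules",         # distance 1 from "nodule" but single-word: out
    "s3\ttubercle",        # exact synonym match
    "s4\tzzzz qqqq xxxx"   # far from everything
  ))
  dict <- merge_glossaries(f)
  # oracle-verified premises for the distances used above
  expect_equal(oracle_levenshtein("lobes of lung", "lobe of lung"), 1)
  expect_equal(oracle_levenshtein("nodules", "nodule"), 1)
  dom <- extract_domain_dictionary(dict, lex, max_dist = 3)
  expect_setequal(dom$source, c("s1", "s3"))
})

test_that("retained entries keep all their targets", {
  lex <- tiny_lexicon()
  f <- make_glossary_file(c("s1\tlung", "s1\tzzzzzz yyyyyy"))
  dom <- extract_domain_dictionary(merge_glossaries(f), lex)
  expect_setequal(dom$target, c("lung", "zzzzzz yyyyyy"))
})

test_that("extraction is a subset, idempotent, and monotone in max_dist", {
  withr::local_seed(42)
  lex <- tiny_lexicon()
  targets <- c("lobe of lung", "lobes of lung", "lobe of lungs on", "pulmonary lobe",
               "nodule", "nodules", "tubercle", "wwww ooo", "lung", "lungs")
  f <- make_glossary_file(sprintf("s%d\t%s", seq_along(targets), targets))
  dict <- merge_glossaries(f)
  prev <- NULL
  for (md in 0:4) {
    dom <- extract_domain_dictionary(dict, lex, max_dist = md)
    expect_true(all(dom$source %in% dict$source))
    again <- extract_domain_dictionary(dom, lex, max_dist = md)
    expect_equal(again, dom)
    if (!is.null(prev)) expect_true(all(prev$source %in% dom$source))
    prev <- dom
  }
})

test_that("retained set is exactly the oracle-predicted set on known distances", {
  lex <- tiny_lexicon()
  terms <- lexicon_terms(lex)$term
  targets <- c("lobe of lung",      # 0
               "lobe off lung",     # 1
               "lobby of lungs",    # 3
               "lobby oaf lungs",   # 4 -> out
               "pulmonary lobes",   # 1 (synonym base)
               "nodule",            # single word exact -> in
               "nodles",            # single word, distance > 0 -> out
               "qqqq wwww eeee")    # far -> out
  dist_to_lex <- vapply(targets, function(tg) {
    min(vapply(terms, function(tm) oracle_levenshtein(tg, tm), numeric(1)))
  }, numeric(1))
  single <- lengths(tokenize(targets)) == 1
  expected <- targets[(!single & dist_to_lex <= 3) | (single & dist_to_lex == 0)]
  f <- make_glossary_file(sprintf("s%02d\t%s", seq_along(targets), targets))
  dom <- extract_domain_dictionary(merge_glossaries(f), lex, max_dist = 3)
  expect_setequal(dom$target, expected)
})

test_that("prefilter never changes the retained set", {
  lex <- tiny_lexicon()
  targets <- c("lobe of lung", "lobe of la", "nodule", "pulmonary lobe zz")
  f <- make_glossary_file(sprintf("s%d\t%s", seq_along(targets), targets))
  dict <- merge_glossaries(f)
  expect_equal(extract_domain_dictionary(dict, lex, prefilter = TRUE),
               extract_domain_dictionary(dict, lex, prefilter = FALSE))
})

test_that("empty lexicon is an error", {
  f <- make_glossary_file("s1\ta")
  empty_lex <- tiny_lexicon()[0, ]
  expect_error(extract_domain_dictionary(merge_glossaries(f), empty_lex),
               "non-empty")
})
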