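res_row <- function(phrase, assigned) {
  tibble::tibble(phrase = phrase, assigned = assigned)
}

test_that("counts follow the coding-specific TP/FN/FP definitions", {
  gold <- tibble::tibble(phrase = c("p1", "p2", "p3", "p4", "p5"),
                         code = c("RID1", "RID2", "RID3", "NO_MATCH", "NO_MATCH"))
  results <- res_row(c("p1", "p2", "p3", "p4", "p5"),
                     c("RID1", "RID9", "NO_MATCH", "RID7", "NO_MATCH"))
  ev <- evaluate_coding(results, gold)
  expect_equal(ev$tp, 1)  # p1 correct
  expect_equal(ev$fn, 2)  # p2 wrong code, p3 missed
  expect_equal(ev$fp, 1)  # p4 no-match recorded as matched
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1 / 3)
})

test_that("all-correct coding gives unit metrics; tp=fp=fn=1 gives 0.5", {
  gold <- tibble::tibble(phrase = c("p1", "p2"), code = c("RID1", "NO_MATCH"))
  ev <- evaluate_coding(res_row(c("p1", "p2"), c("RID1", "NO_MATCH")), gold)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))
  gold2 <- tibble::tibble(phrase = c("a", "b", "c"),
                          code = c("RID1", "RID2", "NO_MATCH"))
  ev2 <- evaluate_coding(res_row(c("a", "b", "c"), c("RID1", "RID9", "RIDx")),
                         gold2)
  expect_equal(c(ev2$precision, ev2$recall, ev2$f1), c(0.5, 0.5, 0.5))
})

test_that("the F1 identity holds and degenerate ratios are flagged as 0", {
  expect_equal(f_measure(0.9178, 0.8859), 2 * 0.9178 * 0.8859 / (0.9178 + 0.8859))
  expect_equal(f_measure(0, 0), 0)
  gold <- tibble::tibble(phrase = "p", code = "RID1")
  ev <- evaluate_coding(res_row("p", "NO_MATCH"), gold)
  expect_equal(ev$precision, 0)
  expect_true(ev$undefined[["precision"]])
})

test_that("phrases missing from gold error by default, excluded on request", {
  gold <- tibble::tibble(phrase = "p1", code = "RID1")
  results <- res_row(c("p1", "p2"), c("RID1", "RID1"))
  expect_error(evaluate_coding(results, gold), "p2")
  expect_message(ev <- evaluate_coding(results, gold, allow_missing = TRUE),
                 "Excluded 1")
  expect_equal(ev$n, 1)
})

test_that("standard metrics count wrong codes as false positives too", {
  gold <- tibble::tibble(phrase = c("p1", "p2"), code = c("RID1", "RID2"))
  results <- res_row(c("p1", "p2"), c("RID1", "RID9"))
  paperlike <- evaluate_coding(results, gold)
  standard <- evaluate_coding(results, gold, standard_metrics = TRUE)
  expect_equal(paperlike$fp, 0)
  expect_equal(standard$fp, 1)
  expect_equal(paperlike$tp, standard$tp)
})

test_that("count identities hold on random gold/result tables", {
  withr::local_seed(41)
  codes <- c(sprintf("RID%d", 1:6), "NO_MATCH")
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    gold <- tibble::tibble(phrase = sprintf("p%02d", 1:n),
                           code = sample(codes, n, replace = TRUE))
    results <- res_row(gold$phrase, sample(codes, n, replace = TRUE))
    ev <- evaluate_coding(results, gold)
    expect_equal(ev$tp + ev$fn, sum(gold$code != "NO_MATCH"))
    expect_lte(ev$fp, sum(gold$code == "NO_MATCH"))
    if (ev$precision > 0 && ev$recall > 0) {
      expect_gte(ev$f1, min(ev$precision, ev$recall))
      expect_lte(ev$f1, max(ev$precision, ev$recall))
    }
  }
})

test_that("glance and tidy expose the report as tibbles", {
  gold <- tibble::tibble(phrase = "p", code = "RID1")
  ev <- evaluate_coding(res_row("p", "RID1"), gold)
  expect_equal(glance(ev)$f1, 1)
  expect_equal(nrow(tidy(ev)), 6)
})
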