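planted_rule_data <- function(n = 2000, noise = 0.02, seed = 11) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * 4), n, 4,
                dimnames = list(NULL, c("lev", "jac", "cbow", "wup")))
    y <- as.integer(rowMeans(X) > 0.5)
    flip <- runif(n) < noise
    y[flip] <- 1L - y[flip]
    df <- tibble::as_tibble(X)
    df$label <- y
    df
  })
}

classification_f1 <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  f_measure(if (tp + fp > 0) tp / (tp + fp) else 0,
            if (tp + fn > 0) tp / (tp + fn) else 0)
}

test_that("initialisation is seeded, shaped 4-5-5-1, and outputs probabilities", {
  m1 <- mlp_init(3); m2 <- mlp_init(3); m3 <- mlp_init(4)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))
  expect_equal(m1$layer_sizes, c(4L, 5L, 5L, 1L))
  expect_equal(vapply(m1$weights, dim, integer(2)), matrix(c(4, 5, 5, 5, 5, 1), 2))
  p <- predict_synonym(m1, matrix(runif(40), 10, 4))$probability
  expect_true(all(p >= 0 & p <= 1))
})

test_that("forward pass matches the loop oracle on random configurations", {
  withr::local_seed(21)
  for (k in 1:50) {
    m <- mlp_init(sample.int(1e6, 1))
    # random biases too, so the check covers the affine part
    m$biases <- lapply(m$biases, function(b) runif(length(b), -1, 1))
    x <- runif(4)
    expect_equal(predict_synonym(m, x)$probability,
                 oracle_mlp_forward(m, x)[1], tolerance = 1e-9)
  }
})

test_that("training recovers the planted mean-threshold rule", {
  df <- planted_rule_data()
  tr <- df[1:1400, ]; te <- df[1401:2000, ]
  model <- fit_ensemble(tr, seed = 5)
  pred <- predict_synonym(model, te)
  expect_gte(classification_f1(pred$label, te$label), 0.95)
  expect_equal(predict_synonym(model, c(1, 1, 1, 1))$label, 1L)
  expect_equal(predict_synonym(model, c(0, 0, 0, 0))$label, 0L)
})

test_that("training loss decreases from the first epoch and is recorded", {
  df <- planted_rule_data(600)
  model <- fit_ensemble(df, seed = 5)
  hist <- model$training_meta$loss_history
  expect_true(length(hist) >= 2)
  expect_lte(hist[length(hist)], hist[1])
  expect_true(is.finite(model$training_meta$final_loss))
})

test_that("same data, seed and hyperparameters give identical weights", {
  df <- planted_rule_data(400)
  m1 <- fit_ensemble(df, seed = 8)
  m2 <- fit_ensemble(df, seed = 8)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict_synonym(m1, df), predict_synonym(m2, df))
})

test_that("single-class data and out-of-range features are rejected", {
  df <- planted_rule_data(100)
  df$label <- 1L
  expect_error(fit_ensemble(df, seed = 1), "both classes")
  m <- mlp_init(1)
  expect_error(predict_synonym(m, c(0.5, 1.2, 0.1, 0)), "\\[0, 1\\]")
})

test_that("raising the threshold never flips a negative to positive", {
  df <- planted_rule_data(500)
  m <- fit_ensemble(df, seed = 5)
  p50 <- predict_synonym(m, df, threshold = 0.5)$label
  p80 <- predict_synonym(m, df, threshold = 0.8)$label
  expect_true(all(p80 <= p50))
})

test_that("models round-trip through JSON serialisation", {
  df <- planted_rule_data(300)
  m <- fit_ensemble(df, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_mlp(m, f)
  back <- read_mlp(f)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$biases, m$biases, tolerance = 1e-12)
  expect_equal(predict_synonym(back, df)$probability,
               predict_synonym(m, df)$probability, tolerance = 1e-9)
})

test_that("tidy and glance summarise the fitted ensemble", {
  m <- fit_ensemble(planted_rule_data(300), seed = 5)
  td <- tidy(m)
  expect_equal(sum(td$from != "bias"), 4 * 5 + 5 * 5 + 5 * 1)
  gl <- glance(m)
  expect_equal(gl$architecture, "4-5-5-1")
  expect_equal(gl$n_parameters, 61)
  expect_true(gl$trained)
})
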