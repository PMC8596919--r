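#' Train a CBOW word-embedding model
#'
#' Continuous bag-of-words training: for each corpus position the mean of the
#' context vectors inside a symmetric window of `window` tokens predicts the
#' centre word, and the average log-probability of the centre words is
#' maximised by stochastic gradient ascent with negative sampling (negatives
#' drawn from the unigram distribution raised to 3/4). The learning rate
#' decays linearly over the run. All randomness (initialisation, negative
#' draws) flows from `seed`, and training is single-threaded, so the same
#' corpus, configuration and seed reproduce the same vectors bit for bit.
#'
#' @param corpus Character vector of sentences (tokenised with [tokenize()])
#'   or a list of token vectors, one per sentence.
#' @param dim Embedding dimension (>= 2). Default 100.
#' @param window Symmetric context window size (>= 1). Default 5.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary. Default 1 (small corpora).
#' @param epochs Number of passes over the corpus (>= 1). Default 20.
#' @param negative Number of negative samples per position. Default 5.
#' @param learning_rate Initial learning rate. Default 0.05.
#' @param seed Integer seed; required.
#' @return An object of class `radcoder_cbow`: list with `vectors` (matrix,
#'   vocabulary x `dim`, rownames are tokens), `vocab` (tibble `token`,
#'   `count`), and `config`.
#' @seealso [cbow_phrase_similarity()], [write_embeddings()]
#' @export
train_cbow <- function(corpus, dim = 100, window = 5, min_count = 1,
                       epochs = 20, negative = 5, learning_rate = 0.05,
                       seed) {
  if (missing(seed)) abort("`seed` is required for reproducible training.")
  if (is.character(corpus)) corpus <- tokenize(corpus)
  if (!is.list(corpus) || length(corpus) == 0) abort("Corpus must be non-empty.")
  if (dim < 2) abort("`dim` must be >= 2.")
  if (window < 1) abort("`window` must be >= 1.")
  if (epochs < 1) abort("`epochs` must be >= 1.")

  counts <- table(unlist(corpus))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) abort("Vocabulary is empty after min_count filtering.")
  vocab <- sort(names(counts))
  counts <- as.integer(counts[vocab])
  V <- length(vocab)
  idx <- stats::setNames(seq_len(V), vocab)
  sents <- lapply(corpus, function(s) unname(idx[s[s %in% vocab]]))
  sents <- sents[lengths(sents) >= 2]
  if (length(sents) == 0) abort("No sentence has >= 2 in-vocabulary tokens.")

  # unigram^(3/4) negative-sampling table as cumulative probabilities
  p_neg <- counts^0.75
  cum_neg <- cumsum(p_neg) / sum(p_neg)

  total_steps <- sum(lengths(sents)) * epochs
  step <- 0L

  withr::with_seed(seed, {
    W <- matrix(runif(V * dim, -0.5, 0.5) / dim, V, dim)   # input vectors
    C <- matrix(0, V, dim)                                  # output vectors
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(sents))
      for (si in ord) {
        s <- sents[[si]]
        len <- length(s)
        for (t in seq_len(len)) {
          step <- step + 1L
          lo <- max(1L, t - window); hi <- min(len, t + window)
          ctx <- s[setdiff(lo:hi, t)]
          nc <- length(ctx)
          if (nc == 0) next
          alpha <- max(learning_rate * (1 - step / total_steps),
                       learning_rate * 1e-4)
          h <- .colMeans(W[ctx, , drop = FALSE], nc, dim)
          negs <- findInterval(runif(negative), cum_neg) + 1L
          negs <- negs[negs != s[t]]
          targets <- c(s[t], negs)
          lab <- c(1, rep(0, length(negs)))
          f <- 1 / (1 + exp(-drop(C[targets, , drop = FALSE] %*% h)))
          g <- (lab - f) * alpha
          e <- drop(crossprod(C[targets, , drop = FALSE], g))
          C[targets, ] <- C[targets, , drop = FALSE] + tcrossprod(g, h)
          W[ctx, ] <- W[ctx, , drop = FALSE] + rep(e / nc, each = nc)
        }
      }
    }
  })
  rownames(W) <- vocab
  structure(
    list(
      vectors = W,
      vocab = tibble(token = vocab, count = counts),
      config = list(V = V, dim = dim, window = window, min_count = min_count,
                    epochs = epochs, negative = negative,
                    learning_rate = learning_rate, seed = seed)
    ),
    class = "radcoder_cbow"
  )
}

#' @export
print.radcoder_cbow <- function(x, ...) {
  cat(sprintf("<radcoder_cbow> %d tokens x %d dims (window %d, %d epochs, seed %s)\n",
              x$config$V, x$config$dim, x$config$window, x$config$epochs,
              x$config$seed))
  invisible(x)
}

cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Embedding cosine similarity between phrases
#'
#' Each phrase is represented by the mean of its in-vocabulary token vectors;
#' the score is the cosine of the two phrase vectors, clamped below at 0 so
#' that anti-similar pairs sit at the floor like the other scorers. A phrase
#' with no in-vocabulary token is out-of-vocabulary: the pair scores 0 and is
#' flagged.
#'
#' @param model A `radcoder_cbow`.
#' @param a,b Character vectors of phrases (recycled).
#' @return Numeric vector in `[0, 1]` with attribute `oov` (logical vector:
#'   at least one side had no in-vocabulary token).
#' @export
cbow_phrase_similarity <- function(model, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vecs <- model$vectors
  phrase_vec <- function(p) {
    toks <- intersect(tokenize1(p), rownames(vecs))
    if (length(toks) == 0) return(NULL)
    .colMeans(vecs[toks, , drop = FALSE], length(toks), ncol(vecs))
  }
  out <- numeric(n); oov <- logical(n)
  for (i in seq_len(n)) {
    va <- phrase_vec(a[i]); vb <- phrase_vec(b[i])
    if (is.null(va) || is.null(vb)) {
      out[i] <- 0; oov[i] <- TRUE
    } else {
      out[i] <- min(max(cosine(va, vb), 0), 1)
    }
  }
  attr(out, "oov") <- oov
  out
}

#' Write embeddings in word2vec text format
#'
#' First line `"<V> <dim>"`, then one token per line followed by its vector
#' components. Plain text, reloadable with [read_embeddings()].
#'
#' @param model A `radcoder_cbow`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), ncol(model$vectors)), con)
  rows <- apply(model$vectors, 1, function(v) {
    paste(formatC(v, format = "g", digits = 17), collapse = " ")
  })
  writeLines(paste(rownames(model$vectors), rows), con)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param path Path to a word2vec-text-format file.
#' @return A `radcoder_cbow` (with `vocab` counts unknown, set to `NA`).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  tokens <- vapply(body, `[[`, character(1), 1)
  W <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  rownames(W) <- tokens
  structure(
    list(vectors = W,
         vocab = tibble(token = tokens, count = NA_integer_),
         config = list(V = hdr[1], dim = hdr[2])),
    class = "radcoder_cbow"
  )
}

#' Read a plain-text corpus (one sentence per line)
#'
#' @param path Path to a UTF-8 text file.
#' @return List of token vectors.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tokenize(lines[nzchar(trimws(lines))])
}

#' Write a tokenised corpus as plain text
#'
#' @param corpus List of token vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1), collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}
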