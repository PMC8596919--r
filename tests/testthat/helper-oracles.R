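# Independent oracles used to check the implementation. Each is written from
# the defining recursion/arithmetic, deliberately not sharing code with the
# package internals.

# exhaustive recursive edit-search (memoised on (i, j); still the plain
# three-way recursion, independent of the package's DP route)
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    v <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(v)) return(v)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1, j) + 1L,        # delete
             rec(i, j - 1) + 1L,        # insert
             rec(i - 1, j - 1) + cost)  # substitute / keep
    assign(key, v, envir = memo)
    v
  }
  rec(nchar(a), nchar(b))
}

# direct set arithmetic on token vectors
oracle_jaccard <- function(tokens_a, tokens_b) {
  A <- unique(tokens_a)
  B <- unique(tokens_b)
  inter <- sum(A %in% B)
  uni <- length(A) + length(B) - inter
  if (uni == 0) 1 else inter / uni
}

# forward pass with explicit neuron-by-neuron loops
oracle_mlp_forward <- function(model, x) {
  a <- x
  L <- length(model$weights)
  for (l in seq_len(L)) {
    W <- model$weights[[l]]
    b <- model$biases[[l]]
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (i in seq_len(nrow(W))) s <- s + a[i] * W[i, j]
      out[j] <- if (l < L) max(s, 0) else 1 / (1 + exp(-s))
    }
    a <- out
  }
  a
}

random_strings <- function(n, max_len = 7, alphabet = letters[1:6]) {
  vapply(seq_len(n), function(i) {
    k <- sample(0:max_len, 1)
    paste(sample(alphabet, k, replace = TRUE), collapse = "")
  }, character(1))
}

random_phrases <- function(n, vocab = c("lobe", "lung", "nodule", "upper",
                                        "lower", "left", "right", "of",
                                        "pleura", "wall")) {
  vapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    paste(sample(vocab, k, replace = TRUE), collapse = " ")
  }, character(1))
}
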