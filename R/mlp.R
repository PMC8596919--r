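#' Initialise the 4-5-5-1 synonym-decision MLP
#'
#' Fully connected multilayer perceptron with four inputs (the similarity
#' vector), two hidden layers of five rectified-linear neurons, and one
#' logistic output read as the probability that the pair is a synonym pair.
#' Weights are drawn uniformly from `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`,
#' biases start at zero; the scheme is recorded in `training_meta`.
#'
#' @param seed Integer seed for the weight draw.
#' @param layer_sizes Integer vector of layer widths; default `c(4, 5, 5, 1)`.
#' @param threshold Decision threshold on the output probability, in (0, 1).
#' @return An object of class `radcoder_mlp`.
#' @seealso [train_mlp()], [predict_synonym()]
#' @export
mlp_init <- function(seed, layer_sizes = c(4L, 5L, 5L, 1L), threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  withr::with_seed(seed, {
    for (l in seq_len(L)) {
      r <- 1 / sqrt(layer_sizes[l])
      weights[[l]] <- matrix(runif(layer_sizes[l] * layer_sizes[l + 1], -r, r),
                             layer_sizes[l], layer_sizes[l + 1])
      biases[[l]] <- rep(0, layer_sizes[l + 1])
    }
  })
  structure(
    list(layer_sizes = as.integer(layer_sizes), weights = weights,
         biases = biases, threshold = threshold,
         training_meta = list(seed = seed, trained = FALSE,
                              init = "uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)), zero biases")),
    class = "radcoder_mlp"
  )
}

#' @export
print.radcoder_mlp <- function(x, ...) {
  cat(sprintf("<radcoder_mlp> %s, threshold %.2f, %s\n",
              paste(x$layer_sizes, collapse = "-"), x$threshold,
              if (isTRUE(x$training_meta$trained)) {
                sprintf("trained (%d epochs, final loss %.4f)",
                        x$training_meta$epochs_run, x$training_meta$final_loss)
              } else "untrained"))
  invisible(x)
}

# forward pass on a feature matrix (n x 4): ReLU hiddens, logistic output
mlp_forward <- function(model, X) {
  A <- X
  L <- length(model$weights)
  for (l in seq_len(L)) {
    Z <- A %*% model$weights[[l]] +
      matrix(model$biases[[l]], nrow(A), length(model$biases[[l]]), byrow = TRUE)
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.vector(A)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    need <- c("lev", "jac", "cbow", "wup")
    if (!all(need %in% names(features))) {
      abort("Feature data frame must have columns lev, jac, cbow, wup.")
    }
    X <- as.matrix(features[need])
  } else if (is.numeric(features) && is.null(dim(features))) {
    X <- matrix(features, nrow = 1)
  } else {
    X <- as.matrix(features)
  }
  storage.mode(X) <- "double"
  if (anyNA(X) || any(X < -1e-8) || any(X > 1 + 1e-8)) {
    abort("Similarity features must lie in [0, 1]; a corrupt upstream score was detected.")
  }
  pmin(pmax(X, 0), 1)
}

#' Train the synonym MLP by backpropagation
#'
#' Per-example stochastic gradient descent on the binary cross-entropy loss,
#' with a fixed learning rate, per-epoch reshuffling driven by `seed`, and
#' early stopping: a stratified validation split is held out and training
#' stops when the validation loss has not improved for `patience` epochs
#' (the weights from the best validation epoch are kept). Because candidate
#' generation yields far more non-synonym pairs than synonym pairs, the
#' training split is rebalanced by default by downsampling the majority class
#' to a 1:1 ratio.
#'
#' @param model A `radcoder_mlp` (typically from [mlp_init()]).
#' @param features Data frame with columns `lev`, `jac`, `cbow`, `wup`, or a
#'   numeric matrix with those four columns. All values must lie in `[0, 1]`.
#' @param labels Binary labels (0/1); both classes must be present.
#' @param epochs Maximum epochs (>= 1). Default 200.
#' @param learning_rate Fixed SGD learning rate. Default 0.01.
#' @param validation_fraction Fraction held out for early stopping.
#'   Default 0.2.
#' @param patience Early-stopping patience in epochs. Default 10.
#' @param balance Downsample the majority class in the training split to 1:1.
#'   Default `TRUE`.
#' @param seed Seed for the split, balancing and shuffles. Defaults to the
#'   init seed.
#' @return The trained `radcoder_mlp`; `training_meta` records the seed,
#'   epochs run, learning rate, final training loss and best validation loss.
#' @export
train_mlp <- function(model, features, labels, epochs = 200,
                      learning_rate = 0.01, validation_fraction = 0.2,
                      patience = 10, balance = TRUE,
                      seed = model$training_meta$seed) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) abort("`labels` length must match feature rows.")
  if (length(y) == 0) abort("Training data must be non-empty.")
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes (synonym and non-synonym).")
  }
  if (epochs < 1) abort("`epochs` must be >= 1.")

  L <- length(model$weights)
  W <- model$weights
  B <- model$biases

  withr::with_seed(seed, {
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      k <- floor(length(ix) * validation_fraction)
      if (k > 0) sample(ix, k) else integer(0)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_along(y), val_idx)
    if (balance) {
      by_class <- split(tr_idx, y[tr_idx])
      n_min <- min(lengths(by_class))
      tr_idx <- unlist(lapply(by_class, function(ix) {
        if (length(ix) > n_min) sample(ix, n_min) else ix
      }), use.names = FALSE)
    }
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    has_val <- length(val_idx) > 0

    best_val <- Inf; best_W <- W; best_B <- B; wait <- 0L
    epochs_run <- 0L; loss_history <- numeric(0)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (i in ord) {
        a <- vector("list", L + 1)
        z <- vector("list", L)
        a[[1]] <- X_row <- Xtr[i, ]
        for (l in seq_len(L)) {
          z[[l]] <- drop(crossprod(W[[l]], a[[l]])) + B[[l]]
          a[[l + 1]] <- if (l < L) pmax(z[[l]], 0) else 1 / (1 + exp(-z[[l]]))
        }
        delta <- a[[L + 1]] - ytr[i]            # logistic + cross-entropy
        for (l in rev(seq_len(L))) {
          # propagate through the pre-update weights
          delta_prev <- if (l > 1) drop(W[[l]] %*% delta) * (z[[l - 1]] > 0)
          W[[l]] <- W[[l]] - learning_rate * tcrossprod(a[[l]], delta)
          B[[l]] <- B[[l]] - learning_rate * delta
          if (l > 1) delta <- delta_prev
        }
      }
      epochs_run <- ep
      m_tmp <- list(weights = W, biases = B)
      train_loss <- bce_loss(mlp_forward(m_tmp, Xtr), ytr)
      if (!is.finite(train_loss)) {
        abort(sprintf("Non-finite training loss at epoch %d (lr = %g).", ep,
                      learning_rate))
      }
      loss_history <- c(loss_history, train_loss)
      if (has_val) {
        val_loss <- bce_loss(mlp_forward(m_tmp, Xval), yval)
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss; best_W <- W; best_B <- B; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else {
        best_W <- W; best_B <- B; best_val <- NA_real_
      }
    }
  })

  model$weights <- best_W
  model$biases <- best_B
  model$training_meta <- list(
    seed = seed, trained = TRUE, epochs_run = epochs_run,
    learning_rate = learning_rate, patience = patience, balance = balance,
    validation_fraction = validation_fraction,
    final_loss = loss_history[length(loss_history)],
    best_val_loss = best_val,
    loss_history = loss_history,
    init = model$training_meta$init
  )
  model
}

#' Fit the synonym ensemble from a scored pair table
#'
#' Pipe-friendly wrapper: initialises the 4-5-5-1 MLP and trains it on a
#' table that carries the four similarity scores and a binary `label` column
#' (as produced by [score_pairs()] on labelled pairs).
#'
#' @param data Tibble with columns `lev`, `jac`, `cbow`, `wup`, `label`.
#' @param seed Integer seed (initialisation + training).
#' @param threshold Decision threshold. Default 0.5.
#' @param ... Passed to [train_mlp()].
#' @return A trained `radcoder_mlp`.
#' @export
fit_ensemble <- function(data, seed, threshold = 0.5, ...) {
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  model <- mlp_init(seed, threshold = threshold)
  train_mlp(model, data, data$label, seed = seed, ...)
}

#' Predict synonym probability and label for similarity vectors
#'
#' Forward pass through the MLP; `label = 1` iff the probability is at least
#' the model's decision threshold. Features outside `[0, 1]` are rejected as
#' corrupt upstream scores.
#'
#' @param model A `radcoder_mlp`.
#' @param features Data frame with columns `lev`, `jac`, `cbow`, `wup`, a
#'   numeric length-4 vector, or an n x 4 matrix.
#' @param threshold Optional threshold override.
#' @return Tibble with columns `probability`, `label`.
#' @export
predict_synonym <- function(model, features, threshold = NULL) {
  X <- as_feature_matrix(features)
  th <- threshold %||% model$threshold
  p <- mlp_forward(model, X)
  tibble(probability = p, label = as.integer(p >= th))
}

#' @export
#' @method tidy radcoder_mlp
tidy.radcoder_mlp <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights), function(l) {
    W <- x$weights[[l]]
    dplyr::bind_rows(
      tibble(layer = l,
             from = rep(sprintf("n%d", seq_len(nrow(W))), ncol(W)),
             to = rep(sprintf("n%d", seq_len(ncol(W))), each = nrow(W)),
             weight = as.vector(W)),
      tibble(layer = l, from = "bias",
             to = sprintf("n%d", seq_along(x$biases[[l]])),
             weight = x$biases[[l]])
    )
  })
}

#' @export
#' @method glance radcoder_mlp
glance.radcoder_mlp <- function(x, ...) {
  tm <- x$training_meta
  tibble(
    architecture = paste(x$layer_sizes, collapse = "-"),
    n_parameters = sum(vapply(x$weights, length, integer(1))) +
      sum(vapply(x$biases, length, integer(1))),
    trained = isTRUE(tm$trained),
    epochs_run = tm$epochs_run %||% NA_integer_,
    final_loss = tm$final_loss %||% NA_real_,
    best_val_loss = tm$best_val_loss %||% NA_real_,
    threshold = x$threshold,
    seed = tm$seed
  )
}

#' Serialise an MLP to JSON
#'
#' Single JSON file holding layer sizes, row-major weight arrays, biases, the
#' decision threshold and the training metadata; reloadable with
#' [read_mlp()].
#'
#' @param model A `radcoder_mlp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mlp <- function(model, path) {
  obj <- list(
    layer_sizes = model$layer_sizes,
    weights = lapply(model$weights, function(m) {
      list(nrow = nrow(m), ncol = ncol(m), values = as.vector(t(m)))
    }),
    biases = model$biases,
    threshold = model$threshold,
    training_meta = model$training_meta[setdiff(names(model$training_meta),
                                                "loss_history")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MLP written by [write_mlp()]
#'
#' @param path Path to the JSON file.
#' @return A `radcoder_mlp`.
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- purrr::pmap(obj$weights, function(nrow, ncol, values) {
    matrix(unlist(values), nrow, ncol, byrow = TRUE)
  })
  biases <- obj$biases
  if (is.matrix(biases)) biases <- asplit(biases, 1)
  biases <- lapply(biases, as.numeric)
  structure(
    list(layer_sizes = as.integer(obj$layer_sizes), weights = weights,
         biases = biases, threshold = obj$threshold,
         training_meta = obj$training_meta),
    class = "radcoder_mlp"
  )
}
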