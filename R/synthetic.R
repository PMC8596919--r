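#' Configuration for the synthetic benchmark
#'
#' Bundles every knob of the generator. All randomness in the generator flows
#' from `seed`, so a fixed configuration regenerates byte-identical fixtures.
#' Source-language phrases are synthetic identifiers: the coding arithmetic
#' operates entirely on the translated side, so tests only need a consistent
#' source-to-target mapping.
#'
#' @param seed Integer master seed.
#' @param n_concepts Number of lexicon concepts (must not exceed the taxonomy
#'   leaf count).
#' @param taxonomy_branching Children per internal node (>= 2).
#' @param taxonomy_depth Tree depth in levels, root included (>= 2).
#' @param corpus_sentences Number of corpus sentences for embedding training.
#' @param glossary_coverage Fraction of concepts present in the glossaries.
#' @param typo_rate Fraction of multi-word glossary targets corrupted by 1-3
#'   character edits (never deleting a whole token).
#' @param regime_mix Proportions of positive pairs over the four synonym
#'   regimes `glyph`, `token_subset`, `distributional`, `taxonomic`; must sum
#'   to 1.
#' @param n_pairs Number of positive labelled pairs.
#' @param negative_ratio Negatives per positive (>= 1).
#' @return An object of class `radcoder_synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L, n_concepts = 24L, taxonomy_branching = 3L,
                         taxonomy_depth = 4L, corpus_sentences = 2000L,
                         glossary_coverage = 1, typo_rate = 0.1,
                         regime_mix = c(glyph = 0.25, token_subset = 0.25,
                                        distributional = 0.25, taxonomic = 0.25),
                         n_pairs = 400L, negative_ratio = 1) {
  cfg <- list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
              taxonomy_branching = as.integer(taxonomy_branching),
              taxonomy_depth = as.integer(taxonomy_depth),
              corpus_sentences = as.integer(corpus_sentences),
              glossary_coverage = glossary_coverage, typo_rate = typo_rate,
              regime_mix = regime_mix, n_pairs = as.integer(n_pairs),
              negative_ratio = negative_ratio)
  regimes <- c("glyph", "token_subset", "distributional", "taxonomic")
  if (!setequal(names(cfg$regime_mix), regimes)) {
    abort(sprintf("`regime_mix` must be named: %s.", paste(regimes, collapse = ", ")))
  }
  if (abs(sum(cfg$regime_mix) - 1) > 1e-9) abort("`regime_mix` must sum to 1.")
  if (any(cfg$regime_mix < 0)) abort("`regime_mix` proportions must be >= 0.")
  counts <- c(cfg$n_concepts, cfg$corpus_sentences, cfg$n_pairs)
  if (any(counts <= 0)) abort("Counts must be positive.")
  if (cfg$taxonomy_branching < 2) abort("`taxonomy_branching` must be >= 2.")
  if (cfg$taxonomy_depth < 2) abort("`taxonomy_depth` must be >= 2.")
  if (cfg$glossary_coverage < 0 || cfg$glossary_coverage > 1) {
    abort("`glossary_coverage` must be in [0, 1].")
  }
  if (cfg$typo_rate < 0 || cfg$typo_rate > 1) abort("`typo_rate` must be in [0, 1].")
  if (cfg$negative_ratio < 1) abort("`negative_ratio` must be >= 1.")
  cfg$regime_mix <- cfg$regime_mix[regimes]
  structure(cfg, class = "radcoder_synth_config")
}

# pronounceable pseudo-words (consonant-vowel syllables), unique and disjoint
# from `exclude`; expects an active RNG
pseudo_words <- function(n, exclude = character(0)) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, 1)
    w <- paste0(sample(cons, k, TRUE), sample(vow, k, TRUE), collapse = "")
    if (!(w %in% out) && !(w %in% exclude)) out <- c(out, w)
  }
  out
}

# substitute one character of a word, avoiding `exclude` collisions
mutate_word <- function(w, exclude = character(0)) {
  repeat {
    chars <- strsplit(w, "")[[1]]
    i <- sample.int(length(chars), 1)
    chars[i] <- sample(setdiff(letters, chars[i]), 1)
    w2 <- paste(chars, collapse = "")
    if (!(w2 %in% exclude)) return(w2)
  }
}

#' Corrupt a term by random character edits
#'
#' Applies `n_edits` random single-character substitutions, insertions or
#' deletions, never touching spaces and never deleting a whole token (a
#' deletion on a one-character token becomes a substitution). The result is
#' therefore within Levenshtein distance `n_edits` of the input and keeps its
#' token count. Expects an active RNG (wrap in [withr::with_seed()] for
#' reproducibility).
#'
#' @param x Single term string.
#' @param n_edits Number of edits (>= 1).
#' @return The corrupted term (guaranteed different from `x`).
#' @export
corrupt_term <- function(x, n_edits = 1) {
  orig <- x
  for (attempt in 1:10) {
    y <- orig
    for (k in seq_len(n_edits)) {
      chars <- strsplit(y, "")[[1]]
      nonspace <- which(chars != " ")
      pos <- nonspace[sample.int(length(nonspace), 1)]
      op <- sample(c("sub", "ins", "del"), 1)
      if (op == "del") {
        # token boundaries around pos
        l <- pos; while (l > 1 && chars[l - 1] != " ") l <- l - 1
        r <- pos; while (r < length(chars) && chars[r + 1] != " ") r <- r + 1
        if (r - l + 1 <= 1) op <- "sub"
      }
      if (op == "sub") {
        chars[pos] <- sample(setdiff(letters, chars[pos]), 1)
      } else if (op == "ins") {
        chars <- append(chars, sample(letters, 1), after = pos)
      } else {
        chars <- chars[-pos]
      }
      y <- paste(chars, collapse = "")
    }
    if (y != orig) return(y)
  }
  # edits cancelled repeatedly; force a substitution
  chars <- strsplit(orig, "")[[1]]
  nonspace <- which(chars != " ")
  pos <- nonspace[sample.int(length(nonspace), 1)]
  chars[pos] <- sample(setdiff(letters, chars[pos]), 1)
  paste(chars, collapse = "")
}

# substitute one character in each of up to `max_tokens` distinct tokens:
# every touched token becomes out-of-vocabulary while the string stays within
# Levenshtein distance `max_tokens`
corrupt_each_token <- function(x, max_tokens = 3) {
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  pick <- sort(sample.int(length(toks), min(max_tokens, length(toks))))
  for (i in pick) toks[i] <- mutate_word(toks[i], exclude = toks[i])
  paste(toks, collapse = " ")
}

#' Generate a complete synthetic taxonomy
#'
#' Complete tree of the configured branching and depth with pseudo-word
#' labels, node-counted depths (root depth 1). A share of the deepest parents
#' receives a "mirror twin" leaf pair whose labels differ by a single
#' character — the synthetic analogue of glyph-similar non-synonym concepts
#' such as left/right anatomy — used downstream as adversarial negatives.
#'
#' @param cfg A [synth_config()].
#' @return A `radcoder_taxonomy`.
#' @export
make_taxonomy <- function(cfg) {
  b <- cfg$taxonomy_branching; D <- cfg$taxonomy_depth
  withr::with_seed(cfg$seed + 101L, {
    per_level <- b^(0:(D - 1))
    n_total <- sum(per_level)
    ids <- sprintf("n%04d", seq_len(n_total))
    parent <- rep(NA_character_, n_total)
    level_start <- cumsum(c(1, per_level))[seq_len(D)]
    for (lev in 2:D) {
      offs <- seq_len(per_level[lev]) - 1L
      parent[level_start[lev] + offs] <-
        ids[level_start[lev - 1] + offs %/% b]
    }
    labels <- c("root", pseudo_words(n_total - 1))
    # mirror twins among leaf parents
    leaf_parents_idx <- seq(level_start[D - 1], length.out = per_level[D - 1])
    n_twin <- max(1L, round(0.3 * length(leaf_parents_idx)))
    twin_parents <- sort(sample(leaf_parents_idx, n_twin))
    for (pi in twin_parents) {
      kids <- which(parent == ids[pi])
      labels[kids[2]] <- mutate_word(labels[kids[1]], exclude = labels)
    }
    build_taxonomy(tibble(id = ids, parent = parent, label = labels))
  })
}

concept_path_name <- function(tax, node) {
  path <- rev(tax_path_to_root(tax, node))[-1] # below root, top-down
  paste(tax$label[path], collapse = " ")
}

#' Generate a synthetic lexicon from taxonomy leaves
#'
#' Selects whole sibling families of leaves (so same-parent concept pairs
#' exist for the taxonomic regime) until `n_concepts` concepts are reached.
#' Each concept gets a RID-style code, a preferred name built from its label
#' path below the root, 0-2 synonyms (a glyph variant within edit distance 3
#' and/or a token-subset variant), and a designated distributional-alias
#' token for its leaf label, used by the corpus generator.
#'
#' @param cfg A [synth_config()].
#' @param tax Taxonomy from [make_taxonomy()].
#' @return Tibble with columns `code`, `preferred_name`, `synonyms`
#'   (list-column), `node` (leaf id), `alias`.
#' @export
make_lexicon <- function(cfg, tax) {
  leaves <- tax$nodes$id[!(tax$nodes$id %in% stats::na.omit(tax$nodes$parent))]
  if (cfg$n_concepts > length(leaves)) {
    abort(sprintf("n_concepts (%d) exceeds taxonomy leaf count (%d).",
                  cfg$n_concepts, length(leaves)))
  }
  withr::with_seed(cfg$seed + 202L, {
    families <- split(leaves, tax$parent[leaves])
    ord <- sample.int(length(families))
    chosen <- utils::head(unlist(families[ord], use.names = FALSE),
                          cfg$n_concepts)
    names_full <- vapply(chosen, concept_path_name, character(1), tax = tax)
    leaf_labels <- unname(tax$label[chosen])
    aliases <- pseudo_words(length(chosen), exclude = tax$nodes$label)
    synonyms <- vector("list", length(chosen))
    for (i in seq_along(chosen)) {
      syn <- character(0)
      if (runif(1) < 0.6) syn <- c(syn, corrupt_term(names_full[i], sample(1:3, 1)))
      toks <- strsplit(names_full[i], " ", fixed = TRUE)[[1]]
      if (length(toks) >= 2 && runif(1) < 0.6) {
        drop_i <- sample.int(length(toks), 1)
        syn <- c(syn, paste(toks[-drop_i], collapse = " "))
      }
      synonyms[[i]] <- unique(normalize_term(syn))
    }
    tibble(
      code = sprintf("RID%d", 1000L + match(chosen, leaves)),
      preferred_name = normalize_term(names_full),
      synonyms = synonyms,
      node = chosen,
      alias = aliases
    )
  })
}

#' Generate the embedding-training corpus
#'
#' Template sentences embedding the lexicon names: each sentence wraps one
#' concept's name tokens in filler tokens specific to the concept's top-level
#' subtree (so unrelated subtrees get distinguishable contexts), and the leaf
#' token is swapped for the concept's distributional alias with probability
#' 0.5 — alias and leaf label are sampled interchangeably in identical
#' templates, which is what lets CBOW place them close together.
#'
#' @param cfg A [synth_config()].
#' @param lexicon Lexicon from [make_lexicon()].
#' @param tax Taxonomy from [make_taxonomy()].
#' @return List of `corpus_sentences` token vectors.
#' @export
make_corpus <- function(cfg, lexicon, tax) {
  withr::with_seed(cfg$seed + 303L, {
    branch_of <- vapply(lexicon$node, function(n) {
      p <- rev(tax_path_to_root(tax, n)) # root first
      p[min(2L, length(p))]
    }, character(1))
    branches <- unique(branch_of)
    filler_pool <- pseudo_words(6L * length(branches),
                                exclude = c(tax$nodes$label, lexicon$alias))
    fillers <- split(filler_pool, rep(branches, each = 6L))
    name_toks <- strsplit(lexicon$preferred_name, " ", fixed = TRUE)
    lapply(seq_len(cfg$corpus_sentences), function(i) {
      ci <- sample.int(nrow(lexicon), 1)
      toks <- name_toks[[ci]]
      if (runif(1) < 0.5) toks[length(toks)] <- lexicon$alias[ci]
      f <- sample(fillers[[branch_of[ci]]], 4, replace = FALSE)
      c(f[1], f[2], toks, f[3], f[4])
    })
  })
}

#' Generate overlapping bilingual glossary tables
#'
#' Pseudo-source identifiers mapped to English lexicon terms, covering
#' `glossary_coverage` of the concepts. A `typo_rate` fraction of multi-word
#' targets is corrupted by 1-3 random edits (token count preserved), keeping
#' every corrupted target within Levenshtein distance 3 of a lexicon term so
#' fuzzy extraction can recover it. Entries are split across two tables with
#' a deliberate overlap to exercise merge deduplication.
#'
#' @param cfg A [synth_config()].
#' @param lexicon Lexicon from [make_lexicon()].
#' @return Named list of two tibbles (`glossary_1`, `glossary_2`) with
#'   columns `source`, `target`.
#' @export
make_glossaries <- function(cfg, lexicon) {
  withr::with_seed(cfg$seed + 404L, {
    n <- nrow(lexicon)
    n_cov <- round(cfg$glossary_coverage * n)
    covered <- sort(sample.int(n, n_cov))
    rows <- purrr::map_dfr(covered, function(i) {
      tg <- lexicon$preferred_name[i]
      syn <- lexicon$synonyms[[i]]
      extra <- syn[runif(length(syn)) < 0.5]
      tibble(source = paste0("src_", tolower(lexicon$code[i])),
             target = c(tg, extra))
    })
    multi <- !is_single_word(rows$target)
    corrupt <- multi & runif(nrow(rows)) < cfg$typo_rate
    rows$target[corrupt] <- vapply(rows$target[corrupt], function(tg) {
      corrupt_term(tg, sample(1:3, 1))
    }, character(1))
    m <- nrow(rows)
    i1 <- seq_len(ceiling(0.65 * m))
    i2 <- seq(max(1L, floor(0.35 * m)), m)
    list(glossary_1 = rows[i1, ], glossary_2 = rows[i2, ])
  })
}

#' Generate labelled synonym/non-synonym pairs
#'
#' Positives are drawn per `regime_mix` and constructed so that each regime
#' has a distinctive similarity signature:
#' * `glyph` — a name vs a copy with one character substituted in each of up
#'   to three tokens (high Levenshtein, everything else near 0);
#' * `token_subset` — a name vs the name with one token dropped (high
#'   Jaccard/taxonomy/embedding, moderate Levenshtein);
#' * `distributional` — a leaf label vs its corpus alias (only the embedding
#'   scorer fires);
#' * `taxonomic` — preferred names of same-parent sibling concepts with
#'   dissimilar leaf labels (taxonomy/embedding fire, Levenshtein low).
#' Negatives are cross-concept term pairs from different parents, plus an
#' adversarial share of mirror-twin sibling pairs whose names are within
#' Levenshtein distance 3 yet denote different concepts.
#'
#' @param cfg A [synth_config()].
#' @param lexicon Lexicon from [make_lexicon()].
#' @param tax Taxonomy from [make_taxonomy()].
#' @return Tibble with columns `a`, `b`, `label` (1/0), `regime`.
#' @export
make_labeled_pairs <- function(cfg, lexicon, tax) {
  withr::with_seed(cfg$seed + 505L, {
    regimes <- names(cfg$regime_mix)
    n_pos <- cfg$n_pairs
    counts <- floor(cfg$regime_mix * n_pos)
    rem <- n_pos - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L

    leaf_label <- stats::setNames(unname(tax$label[lexicon$node]), lexicon$code)
    parent_of <- stats::setNames(unname(tax$parent[lexicon$node]), lexicon$code)

    # same-parent concept pairs, split into dissimilar (taxonomic positives)
    # and near-glyph twins (adversarial negatives)
    fam <- split(seq_len(nrow(lexicon)), parent_of[lexicon$code])
    sib_pairs <- purrr::map_dfr(fam[lengths(fam) >= 2], function(ix) {
      cmb <- utils::combn(ix, 2)
      tibble(i = cmb[1, ], j = cmb[2, ])
    })
    if (nrow(sib_pairs) > 0) {
      d <- levenshtein_distance(lexicon$preferred_name[sib_pairs$i],
                                lexicon$preferred_name[sib_pairs$j])
      tax_pool <- sib_pairs[d > 3, , drop = FALSE]
      adv_pool <- sib_pairs[d <= 3, , drop = FALSE]
    } else {
      tax_pool <- adv_pool <- tibble(i = integer(), j = integer())
    }

    sample_rows <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE), ]

    pos <- list()
    if (counts[["glyph"]] > 0) {
      ix <- sample.int(nrow(lexicon), counts[["glyph"]], replace = TRUE)
      # edit distances 0-3: exact duplicates (the dominant true-positive case
      # in coding), light typos, and heavy per-token corruption that leaves
      # only the character-level signal standing
      u <- runif(length(ix))
      pos$glyph <- tibble(
        a = lexicon$preferred_name[ix],
        b = vapply(seq_along(ix), function(k) {
          nm <- lexicon$preferred_name[ix[k]]
          if (u[k] < 0.3) nm
          else if (u[k] < 0.65) corrupt_term(nm, sample(1:3, 1))
          else corrupt_each_token(nm)
        }, character(1)),
        label = 1L, regime = "glyph")
    }
    if (counts[["token_subset"]] > 0) {
      multi <- which(!is_single_word(lexicon$preferred_name))
      if (length(multi) == 0) abort("No multi-word concept names for the token_subset regime.")
      ix <- multi[sample.int(length(multi), counts[["token_subset"]], replace = TRUE)]
      pos$token_subset <- tibble(
        a = lexicon$preferred_name[ix],
        b = vapply(lexicon$preferred_name[ix], function(nm) {
          toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
          paste(toks[-sample.int(length(toks), 1)], collapse = " ")
        }, character(1)),
        label = 1L, regime = "token_subset")
    }
    if (counts[["distributional"]] > 0) {
      ix <- sample.int(nrow(lexicon), counts[["distributional"]], replace = TRUE)
      pos$distributional <- tibble(
        a = unname(leaf_label[lexicon$code[ix]]),
        b = lexicon$alias[ix],
        label = 1L, regime = "distributional")
    }
    if (counts[["taxonomic"]] > 0) {
      if (nrow(tax_pool) == 0) {
        abort("No dissimilar same-parent concept pairs available for the taxonomic regime.")
      }
      pr <- sample_rows(tax_pool, counts[["taxonomic"]])
      pos$taxonomic <- tibble(
        a = lexicon$preferred_name[pr$i],
        b = lexicon$preferred_name[pr$j],
        label = 1L, regime = "taxonomic")
    }

    n_neg <- round(n_pos * cfg$negative_ratio)
    n_adv <- if (nrow(adv_pool) > 0) round(0.15 * n_neg) else 0L
    neg <- list()
    if (n_adv > 0) {
      pr <- sample_rows(adv_pool, n_adv)
      neg$adversarial <- tibble(
        a = lexicon$preferred_name[pr$i],
        b = lexicon$preferred_name[pr$j],
        label = 0L, regime = "adversarial")
    }
    n_rand <- n_neg - n_adv
    pick_term <- function(i) {
      terms <- c(lexicon$preferred_name[i], lexicon$synonyms[[i]])
      terms[sample.int(length(terms), 1)]
    }
    rand <- purrr::map_dfr(seq_len(n_rand), function(k) {
      repeat {
        ij <- sample.int(nrow(lexicon), 2)
        if (parent_of[[lexicon$code[ij[1]]]] != parent_of[[lexicon$code[ij[2]]]]) break
      }
      tibble(a = pick_term(ij[1]), b = pick_term(ij[2]),
             label = 0L, regime = "negative")
    })
    dplyr::bind_rows(c(pos, neg, list(random = rand)))
  })
}

#' Generate the coding task: phrases, mock translations and gold standard
#'
#' Every concept gets one source phrase (its glossary identifier). The mock
#' external translator returns the preferred name, corrupted by one edit with
#' probability 0.3 (a noisy but usable machine translation). A set of noise
#' phrases (20% of the concept count, at least 3) has no dictionary entry and
#' a gibberish mock translation; their gold code is `NO_MATCH`.
#'
#' @param cfg A [synth_config()].
#' @param lexicon Lexicon from [make_lexicon()].
#' @param tax Taxonomy from [make_taxonomy()].
#' @return List with `phrases` (character), `mock` (tibble `source`,
#'   `target`) and `gold` (tibble `phrase`, `code`).
#' @export
make_coding_tasks <- function(cfg, lexicon, tax) {
  withr::with_seed(cfg$seed + 606L, {
    src <- paste0("src_", tolower(lexicon$code))
    mock_target <- vapply(lexicon$preferred_name, function(nm) {
      if (runif(1) < 0.3) corrupt_term(nm, 1) else nm
    }, character(1))
    n_noise <- max(3L, round(0.2 * nrow(lexicon)))
    noise_src <- sprintf("noise_%02d", seq_len(n_noise))
    noise_target <- vapply(seq_len(n_noise), function(i) {
      paste(pseudo_words(3, exclude = c(tax$nodes$label, lexicon$alias)),
            collapse = " ")
    }, character(1))
    list(
      phrases = c(src, noise_src),
      mock = tibble(source = c(src, noise_src),
                    target = unname(c(mock_target, noise_target))),
      gold = tibble(phrase = c(src, noise_src),
                    code = c(lexicon$code, rep("NO_MATCH", n_noise)))
    )
  })
}

#' Generate the full synthetic benchmark, optionally writing fixture files
#'
#' One call producing every input the coding pipeline needs: taxonomy,
#' lexicon, corpus, two overlapping glossaries, labelled pairs, phrases to
#' code, mock translation table and gold standard. With `dir` set, the
#' standard plain-text fixture files are written (`lexicon.tsv`,
#' `taxonomy.tsv`, `corpus.txt`, `glossary_1.tsv`, `glossary_2.tsv`,
#' `pairs.csv`, `phrases.txt`, `mock_translation.tsv`, `gold.tsv`).
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory for fixture files, or `NULL` (no files).
#' @return (Invisibly when `dir` is set.) List with components `cfg`,
#'   `taxonomy`, `lexicon`, `corpus`, `glossaries`, `pairs`, `phrases`,
#'   `mock`, `gold`, and `files` (named paths, when written).
#' @export
simulate_benchmark <- function(cfg = synth_config(), dir = NULL) {
  tax <- make_taxonomy(cfg)
  lexicon <- make_lexicon(cfg, tax)
  corpus <- make_corpus(cfg, lexicon, tax)
  glossaries <- make_glossaries(cfg, lexicon)
  pairs <- make_labeled_pairs(cfg, lexicon, tax)
  tasks <- make_coding_tasks(cfg, lexicon, tax)
  out <- list(cfg = cfg, taxonomy = tax, lexicon = lexicon, corpus = corpus,
              glossaries = glossaries, pairs = pairs,
              phrases = tasks$phrases, mock = tasks$mock, gold = tasks$gold)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(
      lexicon = file.path(dir, "lexicon.tsv"),
      taxonomy = file.path(dir, "taxonomy.tsv"),
      corpus = file.path(dir, "corpus.txt"),
      glossary_1 = file.path(dir, "glossary_1.tsv"),
      glossary_2 = file.path(dir, "glossary_2.tsv"),
      pairs = file.path(dir, "pairs.csv"),
      phrases = file.path(dir, "phrases.txt"),
      mock_translation = file.path(dir, "mock_translation.tsv"),
      gold = file.path(dir, "gold.tsv")
    )
    write_lexicon(lexicon, files[["lexicon"]])
    write_taxonomy(tax, files[["taxonomy"]])
    write_corpus(corpus, files[["corpus"]])
    write_glossary(glossaries$glossary_1, files[["glossary_1"]])
    write_glossary(glossaries$glossary_2, files[["glossary_2"]])
    readr::write_csv(pairs, files[["pairs"]])
    writeLines(tasks$phrases, files[["phrases"]], useBytes = TRUE)
    write_glossary(tasks$mock, files[["mock_translation"]])
    writeLines(paste(tasks$gold$phrase, tasks$gold$code, sep = "\t"),
               files[["gold"]], useBytes = TRUE)
    out$files <- files
    return(invisible(out))
  }
  out
}
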