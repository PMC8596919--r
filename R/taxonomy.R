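#' Build a taxonomy from an edge table
#'
#' A taxonomy is a single-rooted tree given as a child-to-parent map with node
#' labels. Depth is node-counted from the root inclusive: the root has depth 1
#' and `depth(child) = depth(parent) + 1`. The constructor validates that
#' exactly one root exists, that ids are unique, and that every node is
#' reachable from the root (which also rules out cycles).
#'
#' @param nodes Tibble/data frame with columns `id`, `parent` (NA or "" for
#'   the root) and `label`.
#' @return An object of class `radcoder_taxonomy`.
#' @seealso [read_taxonomy()], [wup_similarity()]
#' @export
build_taxonomy <- function(nodes) {
  nodes <- tibble(
    id = as.character(nodes$id),
    parent = as.character(nodes$parent),
    label = as.character(nodes$label)
  )
  nodes$parent[!is.na(nodes$parent) & !nzchar(nodes$parent)] <- NA_character_
  if (anyDuplicated(nodes$id)) {
    abort(sprintf("Duplicate taxonomy node id(s): %s",
                  paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1) {
    abort(sprintf("Taxonomy must have exactly one root; found %d.", length(root)))
  }
  missing_parent <- setdiff(stats::na.omit(nodes$parent), nodes$id)
  if (length(missing_parent) > 0) {
    abort(sprintf("Parent id(s) not present as nodes: %s",
                  paste(missing_parent, collapse = ", ")))
  }
  # BFS from the root assigns node-counted depths and detects unreachable nodes
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  depth[root] <- 1L
  frontier <- root
  children <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  while (length(frontier) > 0) {
    nxt <- unlist(children[frontier], use.names = FALSE)
    depth[nxt] <- depth[frontier[match(nodes$parent[match(nxt, nodes$id)], frontier)]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    abort(sprintf("Node(s) unreachable from root: %s",
                  paste(names(depth)[is.na(depth)], collapse = ", ")))
  }
  nodes$depth <- unname(depth[nodes$id])
  structure(
    list(
      nodes = nodes,
      root = root,
      parent = stats::setNames(nodes$parent, nodes$id),
      depth = stats::setNames(nodes$depth, nodes$id),
      label = stats::setNames(nodes$label, nodes$id),
      .wup_cache = new.env(parent = emptyenv())
    ),
    class = "radcoder_taxonomy"
  )
}

#' @export
print.radcoder_taxonomy <- function(x, ...) {
  cat(sprintf("<radcoder_taxonomy> %d nodes, max depth %d, root '%s'\n",
              nrow(x$nodes), max(x$depth), x$root))
  invisible(x)
}

#' Read a taxonomy from a TSV edge list
#'
#' Format: `child_id<TAB>parent_id<TAB>label`, one row per node, exactly one
#' row with an empty parent field (the root).
#'
#' @param path Path to the edge-list TSV.
#' @return A `radcoder_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("Taxonomy file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("Taxonomy row(s) with fewer than 3 columns: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  build_taxonomy(tibble(
    id = vapply(fields, `[[`, character(1), 1),
    parent = vapply(fields, `[[`, character(1), 2),
    label = vapply(fields, `[[`, character(1), 3)
  ))
}

#' Write a taxonomy to a TSV edge list
#'
#' @param tax A `radcoder_taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  p <- ifelse(is.na(tax$nodes$parent), "", tax$nodes$parent)
  writeLines(paste(tax$nodes$id, p, tax$nodes$label, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

# path of node ids from `node` up to and including the root
tax_path_to_root <- function(tax, node) {
  path <- character(0)
  cur <- node
  n_max <- length(tax$depth) + 1L
  while (!is.na(cur)) {
    path <- c(path, cur)
    if (length(path) > n_max) abort("Cycle detected in taxonomy.")
    cur <- tax$parent[[cur]]
  }
  path
}

wup_one <- function(tax, a, b) {
  key <- paste(a, b, sep = "\r")
  cached <- get0(key, envir = tax$.wup_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  pa <- tax_path_to_root(tax, a)
  pb <- tax_path_to_root(tax, b)
  common <- intersect(pa, pb)
  lcs <- common[which.max(tax$depth[common])]
  val <- 2 * tax$depth[[lcs]] / (tax$depth[[a]] + tax$depth[[b]])
  assign(key, val, envir = tax$.wup_cache)
  assign(paste(b, a, sep = "\r"), val, envir = tax$.wup_cache)
  val
}

#' Wu-Palmer similarity between taxonomy nodes
#'
#' `2 * depth(LCS) / (depth(a) + depth(b))` where the LCS (least common
#' subsumer) is the deepest node having both `a` and `b` as descendants (a
#' node is its own descendant) and depths are node-counted with root depth 1.
#' Under this convention the score is symmetric, lies in `(0, 1]`, and equals
#' 1 exactly when `a == b`.
#'
#' @param tax A `radcoder_taxonomy`.
#' @param a,b Character vectors of node ids (recycled).
#' @return Numeric vector in `(0, 1]`.
#' @examples
#' tax <- build_taxonomy(tibble::tibble(
#'   id = c("r", "A", "x", "y"), parent = c(NA, "r", "A", "A"),
#'   label = c("root", "a", "x", "y")))
#' wup_similarity(tax, "x", "y") # 2*2 / (3+3) = 2/3
#' @export
wup_similarity <- function(tax, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  unknown <- setdiff(unique(c(a, b)), names(tax$depth))
  if (length(unknown) > 0) {
    abort(sprintf("Node(s) not in taxonomy: %s", paste(unknown, collapse = ", ")))
  }
  vapply(seq_len(n), function(i) wup_one(tax, a[i], b[i]), numeric(1))
}

#' Word map from taxonomy labels
#'
#' Maps each token of each node label to that node, giving the token-to-node
#' resolution table used by [wup_phrase_similarity()]. A token labelling
#' several nodes yields several rows (multiple senses).
#'
#' @param tax A `radcoder_taxonomy`.
#' @return Tibble with columns `token`, `node`.
#' @export
taxonomy_word_map <- function(tax) {
  toks <- tokenize(tax$nodes$label)
  tibble(token = unlist(toks) %||% character(0),
         node = rep(tax$nodes$id, lengths(toks)))
}

#' Wu-Palmer similarity between phrases
#'
#' Token-level Wu-Palmer aggregated to phrase level by bidirectional greedy
#' alignment: each resolvable token of one phrase takes its best match among
#' the resolvable tokens of the other (maximising over senses when a token
#' maps to several nodes), the per-token maxima are averaged, and the two
#' directions are averaged. Phrases with no resolvable tokens on either side
#' score 0.
#'
#' @param tax A `radcoder_taxonomy`.
#' @param word_map Tibble with columns `token`, `node` (see
#'   [taxonomy_word_map()]).
#' @param a,b Character vectors of phrases (recycled).
#' @return Numeric vector in `[0, 1]`, with attribute `unresolved` (logical:
#'   no resolvable tokens on at least one side).
#' @export
wup_phrase_similarity <- function(tax, word_map, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  senses <- split(word_map$node, word_map$token)
  resolve <- function(phrase) {
    toks <- unique(tokenize1(phrase))
    senses[intersect(toks, names(senses))]
  }
  best_pair <- function(sa, sb) {
    # max over sense pairs of the two tokens
    max(wup_similarity(tax, rep(sa, each = length(sb)), rep(sb, length(sa))))
  }
  directional <- function(from, to) {
    mean(vapply(from, function(sa) {
      max(vapply(to, function(sb) best_pair(sa, sb), numeric(1)))
    }, numeric(1)))
  }
  out <- numeric(n)
  unresolved <- logical(n)
  for (i in seq_len(n)) {
    ra <- resolve(a[i]); rb <- resolve(b[i])
    if (length(ra) == 0 || length(rb) == 0) {
      out[i] <- 0; unresolved[i] <- TRUE
    } else {
      out[i] <- (directional(ra, rb) + directional(rb, ra)) / 2
    }
  }
  attr(out, "unresolved") <- unresolved
  out
}
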