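#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions or substitutions
#' converting one string into the other, computed by the standard dynamic
#' programme (via [utils::adist()]). Character-level glyph information: high
#' for small spelling variants, blind to meaning.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein_distance("kitten", "sitting") # 3
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(mapply(function(x, y) drop(adist(x, y)), a, b, USE.NAMES = FALSE))
}

#' Length-normalised Levenshtein similarity
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))`, the standard normalisation that
#' maps edit distance into `[0, 1]`. Two empty strings are identical by
#' convention (similarity 1).
#'
#' @inheritParams levenshtein_distance
#' @return Numeric vector in `[0, 1]`.
#' @export
levenshtein_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  len <- pmax(nchar(a), nchar(b))
  d <- levenshtein_distance(a, b)
  out <- ifelse(len == 0, 1, 1 - d / pmax(len, 1L))
  pmin(pmax(out, 0), 1)
}

#' Jaccard similarity of token sets
#'
#' Size of the intersection over size of the union of the two phrases' token
#' sets (see [tokenize()]; duplicates collapse). Word-level overlap: robust to
#' token order, blind to spelling variants and to synonyms with disjoint
#' vocabulary. Two empty token sets are identical by convention (similarity 1).
#'
#' @param a,b Character vectors of phrases (recycled).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' jaccard_similarity("upper lobe of lung", "lobe of lung") # 0.75
#' @export
jaccard_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  ta <- tokenize(rep_len(as.character(a), n))
  tb <- tokenize(rep_len(as.character(b), n))
  mapply(function(x, y) {
    x <- unique(x); y <- unique(y)
    u <- length(union(x, y))
    if (u == 0) return(1)
    length(intersect(x, y)) / u
  }, ta, tb, USE.NAMES = FALSE)
}
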