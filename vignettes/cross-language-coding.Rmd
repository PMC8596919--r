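---
title: "Cross-language terminology coding with a text-similarity ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-language terminology coding with a text-similarity ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical free-text phrases — radiology findings in particular — need to be
mapped to codes of a standard lexicon before reports can be searched, pooled
or mined. When the reports are written in one language (say Chinese) and the
lexicon exists only in another (say English, with RID-style concept codes,
preferred names and synonym lists), the mapping must cross the language
barrier: each source phrase is translated, the translations are compared
with every lexicon term, and the phrase receives the code of the concept
whose term is judged a synonym of one of its translations — or `NO_MATCH`
when no term is.

`radcoder` implements this pipeline end to end: bilingual glossary
management, hybrid translation, four-way text-similarity scoring, a small
neural ensemble that fuses the four scores into a synonym decision, coding,
and evaluation. A synthetic benchmark generator makes the whole pipeline
testable at toy scale without any licensed lexicon, commercial dictionary or
external translation service.

## Hybrid translation

Dictionary translation is precise but limited by coverage; a general-purpose
machine-translation backend has broad coverage but uneven accuracy on
domain terms. The hybrid rule runs both in parallel:

* if both produce the same (normalised) result, or only one produces
  anything, that result is used;
* if they disagree, the **union** of their candidates is kept and every
  candidate is scored downstream.

The phrasing of the single-backend case is ambiguous in ordinary prose
("only the result of the former can be achieved"); taking whichever lone
non-empty result exists is the only behaviour consistent with the union
rule, and that is what `hybrid_translate()` does. An external backend that
throws is logged and treated as empty, so translation degrades gracefully to
dictionary-only. The package ships a deterministic, table-driven
`mock_translator()`; a real service can be plugged in through
`translator_backend()`, but nothing in the package or its tests requires
network access.

Before translation, a domain dictionary is distilled from merged glossaries
by fuzzy matching against the lexicon (`extract_domain_dictionary()`): a
multi-word glossary target is kept when its Levenshtein distance to some
lexicon term (preferred name *or* synonym — synonyms are terms) is at most 3
("less than 4"), while single-word targets must match exactly, because
one-word fuzzy matches routinely cross concept boundaries (*nodule* vs
*nodules* of a different concept). The threshold is a strict integer
reading of "less than 4". Matching operates on a canonical form
(lowercase, collapsed whitespace, stripped surrounding punctuation); the
candidate search is exhaustive apart from an optional length-window
prefilter (|length difference| > `max_dist` can never be within distance
`max_dist`, so the prefilter is lossless). A pluggable `match_filter` hook
can impose an additional linguistic test on within-distance pairs; it is off
by default, so the pure distance threshold decides.

## The four similarity scores

Each candidate (translation, lexicon term) pair is scored four ways, each
score in $[0, 1]$:

* **Levenshtein** (`levenshtein_similarity()`): character-level glyph
  information, $1 - d(a,b) / \max(|a|, |b|)$, where $d$ is the classic
  minimum count of single-character insertions, deletions and substitutions;
  the normalisation is the standard length normalisation (the source method
  uses the distance as a similarity without stating one). Two empty strings
  score 1.
* **Jaccard** (`jaccard_similarity()`): word-level overlap,
  $|A \cap B| / |A \cup B|$ on lowercased token *sets* (duplicates
  collapse; no stemming — inflection is absorbed by the fuzzy dictionary
  step). Blind to spelling variants and single-token synonyms.
* **CBOW embedding cosine** (`train_cbow()`,
  `cbow_phrase_similarity()`): distributional semantics. A continuous
  bag-of-words model maximises
  $\frac{1}{V}\sum_t \log p(w_t \mid m_{t-c} \dots m_{t+c})$
  by negative-sampling SGD; a phrase is the mean of its in-vocabulary token
  vectors and the score is the cosine, clamped below at zero so
  anti-similar pairs sit at the same floor as the other scorers. Defaults:
  dimension 100, window 5, `min_count` 1 (small corpora), 20 epochs, 5
  negatives, initial learning rate 0.05 with linear decay, single-threaded
  and fully seeded, so training is bit-reproducible. A phrase with no
  in-vocabulary token scores 0 and is flagged out-of-vocabulary.
* **Wu–Palmer** (`wup_similarity()`, `wup_phrase_similarity()`): taxonomy
  position, $2\,N_{LCS} / (N_{a,LCS} + N_{b,LCS})$ where the LCS is the
  deepest node having both query nodes as descendants. The node counts are
  interpreted as node-counted depths with root depth 1 — the only reading
  under which $\mathrm{Sim}(a,a) = 1$. The container is a single-parent
  tree, so the LCS is unique and the DAG tie-break question does not arise.
  Phrases aggregate token-level scores by bidirectional greedy alignment
  (best match per token, averaged, both directions averaged); tokens mapping
  to several nodes take the sense pair maximising the score. Unresolvable
  phrases score 0 and are flagged.

`score_pairs()` assembles the four scores plus imputation flags; a missing
resource (no embedding model, no taxonomy) imputes 0 for its component so
the ensemble input is always a complete vector in $[0,1]^4$.

## The ensemble

No single scorer suffices: glyph-similar names can denote different concepts
(left vs right anatomy), single-token synonym pairs have Jaccard 0,
embeddings miss out-of-vocabulary variants, and taxonomy scores are high for
sibling concepts that are not synonyms. The fusion model is a fully
connected multilayer perceptron with layers 4–5–5–1: ReLU hidden units, a
logistic output read as the synonym probability, decision threshold 0.5
(overridable). Two hidden layers of five neurons are enough for a 4-d input
and keep the parameter count (61) small relative to a few hundred training
pairs.

Training choices the source method leaves open, fixed here as: binary
cross-entropy loss; plain per-example stochastic gradient descent with fixed
learning rate 0.01 and seeded per-epoch reshuffling; "stop when the error
meets the requirement" implemented as early stopping with patience 10 on a
stratified 20% validation split, restoring the best-validation weights;
initial weights uniform in $\pm 1/\sqrt{\text{fan-in}}$ with zero biases.
Because candidate generation produces far more negatives than positives,
the training split is rebalanced by downsampling the majority class to 1:1
by default (`balance = FALSE` disables). Non-finite losses abort with
diagnostics rather than silently continuing.

## Coding and evaluation

`code_phrase()` chains translation, candidate generation (cross product
with all lexicon terms, optionally prefiltered by token overlap), scoring
and the MLP. Among synonym-labelled pairs the highest probability wins; ties
break by higher Wu–Palmer score, then lexicographically smaller code, making
the result fully deterministic. One phrase receives at most one code (the
argmax), which matches the evaluation bookkeeping. Runner-up codes (default
3) are reported as alternatives.

`evaluate_coding()` implements the coding-specific count definitions
literally: TP = phrase with the correct code, FN = gold-coded phrase with a
wrong code *or* missed, FP = gold-`NO_MATCH` phrase that was assigned a
code. A wrong code therefore hurts recall but not precision, unlike the
conventional scheme; `standard_metrics = TRUE` provides the conventional
variant (wrong or spurious assignments count as FP) for comparison.
Ratios with empty denominators are reported as 0 and flagged. Phrases
missing from the gold table are an error by default; `allow_missing = TRUE`
excludes them with a logged count, for gold files that omit `NO_MATCH`
rows.

## The synthetic benchmark

The generator (`simulate_benchmark()`) emulates, at toy scale, every input
the real task needs: a complete taxonomy with pseudo-word labels, a lexicon
built from its leaves (RID-style codes, path-based preferred names, glyph
and token-subset synonyms), a template corpus, two overlapping glossaries
with controlled typo corruption, a labelled pair set spanning four synonym
regimes, a phrase list, a mock translation table and a gold standard.
Source phrases are synthetic identifiers rather than real Chinese: the
coding arithmetic operates on the translated side, so tests only need a
consistent source-to-target mapping (a small hand-written Chinese–English
glossary ships separately for Unicode smoke tests).

Default conditions, chosen once as a realistic desk-scale configuration:
branching 3, depth 4 (27 leaves), 24 concepts, 2000 corpus sentences,
glossary coverage 1.0, typo rate 0.1, 400 positive pairs in equal regime
mix, negatives 1:1. The four positive regimes are built to give each scorer
a blind spot:

* *glyph* — edit-distance 0–3 variants, mixing exact duplicates (the
  dominant true-positive case in real candidate pairs), light typos, and
  heavy per-token corruption on which only the character-level score fires;
* *token subset* — one token dropped;
* *distributional* — a leaf label vs its corpus alias, two tokens sampled
  interchangeably in identical sentence templates, so only the embedding
  scorer fires;
* *taxonomic* — preferred names of same-parent sibling concepts with
  dissimilar leaf labels.

Negatives are cross-parent term pairs plus an adversarial 15% share of
"mirror twin" siblings whose names differ by a single character yet denote
different concepts — the left/right-anatomy failure case. The twins overlap
the glyph-positive signature on purpose; they are what keeps any single
thresholded score, and indeed the ensemble itself, below perfection, and
they are why the ensemble-beats-singles comparison is a real test rather
than a tautology.

An early design lesson is recorded here because it shapes the defaults: when
the glyph regime contained only heavily corrupted variants, the trained
ensemble placed the exact-match vector $(1,1,1,1)$ in the *negative* region
(it lay beyond the adversarial twins' signature), and end-to-end coding
failed in the most embarrassing way possible — on perfect translations. The
glyph mixture over distances 0–3 exists so that the training distribution
covers the near-exact region the coder actually visits.

What the generator does **not** emulate: real report narratives, entity
extraction from free text, genuine morphological variation (plurals,
prepositions), multi-sense clinical vocabulary, or realistic corpus word
frequencies. Passing the synthetic suite therefore shows the pipeline's
machinery is correct and the ensemble genuinely fuses complementary
signals; it does not certify performance on hospital data.

## Problem sizes and runtime

The default benchmark trains a 77-token × 100-dimension embedding on 2000
sentences for 20 epochs (about 10 s single-threaded) and an MLP on 800
scored pairs (a few seconds); a full pipeline run, coding included, takes
well under a minute. These sizes were chosen so the whole test suite and the
reproduction script run comfortably on one CPU; the pure-R CBOW trainer is
entirely adequate at this scale and keeps the package free of compiled
code.

## Known limitations

* The evaluation definitions are the coding-specific ones; numbers are not
  directly comparable to entity-linking literature that uses conventional
  FP accounting (use `standard_metrics = TRUE` for that).
* The taxonomy container is a tree; a DAG-shaped ontology must be reduced
  to one (e.g. a spanning hierarchy) before use.
* Phrase-level Wu–Palmer and mean-vector phrase embeddings are simple
  aggregations; word order and syntax are invisible to them.
* The ensemble is intentionally small; it fuses four scores and cannot
  compensate for information none of them carries (mirror-twin concepts
  are the canonical example).
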