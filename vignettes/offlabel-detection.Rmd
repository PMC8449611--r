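---
title: "Detecting off-label drug use mentions in patient forum posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting off-label drug use mentions in patient forum posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(offlabelr)
```

## The problem

Off-label use — taking a drug for an indication that is not on its
FDA-approved label — is common, clinically consequential, and hard to
observe. Patients discuss it freely in online health communities (OHCs):
"I take gabapentin for my insomnia" is an off-label report, because
gabapentin's label covers epilepsy, postherpetic neuralgia and seizures, not
insomnia. `offlabelr` implements a rule-based NLP pipeline that detects such
reports in keyword-scraped forum posts and buckets each detection by
confidence.

The pipeline runs six fixed stages:

1. **Relevance classification** — a text classifier keeps only posts that
   relay firsthand patient (or family/friend) experience with the drug.
2. **Spelling normalization** — consumer-language misspellings are corrected
   against a medical lexicon plus a general vocabulary.
3. **Entity recognition** — drug and indication mentions are found by
   greedy longest-match against the lexicon.
4. **Non-medical filter** — candidate indications whose word-embedding
   cosine similarity with the target drug is negative are discarded.
5. **Dependency pairing** — each drug mention is paired with indication
   mentions through the sentence's dependency graph; a pair survives only if
   the shortest path between the two words is at most 9 edges ("jumps",
   inclusive). When drug and indication sit in adjacent sentences, an
   anaphor ("it", "drug", "medication") in the indication's sentence is
   substituted by the drug name and the distance is measured inside that
   rewritten sentence. Negation cues on (or hanging directly off) the
   drug–indication path mark the pair negated.
6. **Off-label flagging** — a retained, non-negated pair whose normalized
   indication concept is absent from the drug's approved set is flagged
   off-label; negated pairs are never off-label. Each record carries a
   confidence bucket: *high* (same sentence, distance ≤ 4), *medium* (same
   sentence, distance 5–9), *low* (cross-sentence substitution).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_jumps` | 9 | inclusive shortest-path threshold, in dependency edges |
| `substitution_words` | it, drug, medication | anaphora that may stand in for the drug in an adjacent sentence |
| `adjacent_window` | 1 | sentences checked on each side for cross-sentence pairs |
| `negation_cues` | not, never, no, without, n't | cues that negate a pair when on/off the path |
| `max_edit` | 2 | Levenshtein budget of the spelling corrector |
| vectorizer caps | 900 / 450+450 / 300 | feature caps for single schemes, the count+TF-IDF concatenation, and the document embedding |
| `test_fraction`, `k_folds` | 0.2, 10 | 80/20 held-out split; 10-fold cross-validation |
| embedding `d`, `window`, `min_count`, `epochs`, `negative` | 100, 5, 2, 5, 5 | skip-gram hyperparameters |
| similarity threshold | 0 | the sign test: negative cosine ⇒ non-medical, removed |

The 9-jump threshold, the three substitution words, the adjacent-sentence
check, the 70/30 relevance split, the feature caps and the 80/20 + 10-fold
protocol are fixed study conditions; the remaining defaults are standard
values for their methods.

## Components and the choices behind them

**Relevance classifier.** Texts are lowercased and split on
non-alphanumerics (no tokenizer was prescribed; this is the simplest
deterministic choice, shared by every stage). Under the feature cap we keep
the highest-corpus-frequency terms, ties lexicographic. The count and
TF-IDF vector blocks are *concatenated* for the ensemble scheme — how the
two vectorizations were combined is otherwise unspecified, and concatenation
is the conventional reading. TF-IDF uses the smoothed inverse document
frequency `log((1 + n)/(1 + df)) + 1`. The gradient-boosted tree ensemble
(selected by F1) runs single-threaded with a fixed seed so training is
reproducible; SVM, Bernoulli naive Bayes, a ridge-penalised logistic model
and a random forest fill out the classic grid. The 80/20 split is
stratified by class (stratification was not specified; it guarantees both
classes in both splits at small n). The decision threshold on predicted
probability is 0.5.

**Spelling corrector.** Levenshtein distance (via `utils::adist`) against a
length-bucketed candidate set; the unique closest in-vocabulary candidate
within 2 edits wins, with ties preferring medical-lexicon surfaces over
general vocabulary and then lexicographic order, so correction is
deterministic. Tokens shorter than 4 characters are never corrected ("it",
"rx", doses). Correction is idempotent, preserves token count and leaves
punctuation untouched. Real-word errors and token splitting/merging are out
of scope.

**Entity recognizer.** Dictionary longest-match over the bundled lexicon
(drug and indication categories only). A longer surface ("nerve pain")
always beats a contained shorter one ("pain"), and retained spans never
overlap. Sentences are split at `.`/`!`/`?` followed by whitespace and an
uppercase letter, or end of text.

**Embeddings and the non-medical filter.** The filter needs word vectors;
the package trains skip-gram embeddings with negative sampling (mini-batch
SGD, unigram^0.75 negative distribution, linearly decayed learning rate),
single-threaded and seeded, so training is bit-reproducible. A mention is
dropped exactly when its concept has a vector and its cosine with the
target drug is negative; out-of-vocabulary mentions are retained, since
removal is only ever justified by a computed negative score.

**Pairing.** A "jump" is one undirected dependency edge; distance is the
shortest-path edge count (the standard reading of word-to-word distance in
a dependency tree), and the threshold comparison is inclusive (≤ 9).
Multi-token mentions are anchored at their syntactic head — the span token
whose head lies outside the span — so modifying a mention's other tokens
never changes its distance. In the cross-sentence rule the preceding
sentence is checked before the succeeding one, the first substitute token
in reading order is rewritten when several exist, and the distance is
measured within the rewritten sentence only (not across a merged
multi-sentence graph — the alternative reading; measuring within one
sentence keeps the threshold's scale comparable to same-sentence pairs).
The substitution list is treated as exhaustive but configurable. Only
mentions of the post's scrape keyword participate in pairing; other drugs
in the same post are ignored, matching the keyword-scraped corpus design.
Dependency parses come from a pluggable backend; the bundled deterministic
rule-based parser (last verb as root, prepositional attachment, compound
runs) is adequate for short consumer sentences and for fixtures, and any
parser producing a valid single-rooted tree can be swapped in.

**Negation.** A pair is negated iff a cue token lies on the shortest
dependency path between drug and indication or is a direct dependent of a
path token. The cue list and scope rule are the package's own (the original
design delegates to an external negation pipeline without stating its
configuration) and both are configurable. Negated pairs are always flagged
not off-label.

**Label map.** The 12-drug approved-indication map is bundled as
openFDA-compatible JSON and versioned with the package; `fetch_label()` can
refresh it from the openFDA API but is never used by tests, which must run
offline. Indication matching is concept-level after synonym normalization
("Insomnia", "sleep disorder" → `sleep_disorder_insomnia`), not substring
matching. A symptom of an approved indication still counts as off-label if
its concept is not in the approved set — a known limitation of
label-list comparison.

**Confidence buckets.** No bucket definition exists in the source design;
the high/medium/low scheme above is a placeholder keyed to the two
quantities the pipeline actually measures (distance and cross-sentence
provenance), and its thresholds are configurable.

## The synthetic corpus

No OHC corpus is deposited (and scraping forums violates their terms of
service), so evaluation uses a generator that plants ground truth. Defaults
encode the study conditions: 70% relevant posts (the 7000/3000 annotation
split), ~20% of relevant posts describing off-label use (matching the
~18.6% off-label share observed downstream), 10% misspelling, 10% negation
and 15% cross-sentence rates as realistic mid-range settings. Posts are
drawn from templates spanning the post taxonomy — personal experience,
family/friend experience, general knowledge, consumption-free questions —
so the relevance signal is real but learnable. Misspellings are one
substitution or deletion, never in the first character, only in
in-vocabulary non-stopword tokens of length ≥ 4, so every injected error is
recoverable within the corrector's 2-edit budget by construction. An
`ambiguous_rate` knob appends a hedging sentence and marks the post
ambiguous; "ambiguous" was never defined operationally in the source
design, so this realization is the package's invention.

What passing tests on this corpus show — and do not show: template
sentences are short, grammatical and exactly covered by the lexicon, so
end-to-end recall near 1 demonstrates that the machinery (correction,
recognition, pairing, flagging) composes correctly, not that the pipeline
would achieve that recall on real forum text with creative spelling,
ungrammatical syntax, lexicon gaps and genuine parser errors. The
confusion-matrix arithmetic, by contrast, is checked exactly against the
published validation cells.

## Problem sizes and numerical notes

The test suite and the acceptance script use corpora of 1000 posts for
end-to-end recovery, 600 for classifier sanity, 200 for spell-correction
properties, and 1000 random trees (≤ 50 nodes) for the distance oracle —
sizes chosen so the whole suite runs in about a minute on one CPU while
binomial sampling error stays small. All randomness flows from one root
seed; stochastic stages derive child seeds so one stage's draws cannot
perturb another's. Degenerate inputs are contracts, not crashes: empty
corpora give empty outputs, single-class training labels and all-zero
confusion matrices are errors, zero metric denominators yield `NA` (never
silent zeros), and an invalid dependency tree (cycles, multiple roots) is
rejected at construction.

## Known limitations

- The rule-based parser is not a learned parser; long or unusual sentences
  will get flatter, less accurate trees than ScispaCy-class parsers would
  produce. The module boundary accepts any conforming parser.
- Coreference handling is limited to the three-word substitution rule in
  adjacent sentences.
- The published corpus-level counts (76 912 posts → 64 000 relevant →
  11 927 off-label) are not reproducible without the undeposited corpus and
  are not targets of this package.
- Dose-, route- or age-based off-label determination is out of scope.
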