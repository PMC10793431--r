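---
title: "Methods: corpora, perturbations, retrieval and evaluation in phenonorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corpora, perturbations, retrieval and evaluation in phenonorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

Concept normalization maps a free-text phenotype mention ("hearing loss",
"Kidney - Abnormal", "Aneyrysms") to the identifier of a standardized concept
in the Human Phenotype Ontology — `HP:` followed by seven digits. Clinical
text rarely uses the preferred name: mentions arrive as synonyms, terms
borrowed from other vocabularies such as SNOMED-CT, colloquial paraphrases,
and misspellings. phenonorm provides the machinery to (i) turn an HPO-style
vocabulary into fine-tuning corpora for autoregressive completion models,
(ii) generate controlled perturbations of query terms, (iii) run a BM25
dictionary-lookup baseline, and (iv) score any normalizer — completion-backed
or retrieval-backed — through one evaluation harness.

## Sentence template and training records

Every training sentence follows one template:

```
The Human Phenotype Ontology term <term> is identified by the HPO ID <HP:NNNNNNN>
```

Sentences are rendered **without** a trailing period, so the identifier is
the final token span; the evaluation prompt is the sentence truncated
immediately after `"HPO ID "`, and the model's continuation is the
completion target. This makes `make_records()` lossless: `prompt +
completion` reconstructs each sentence byte-for-byte, and `parse_sentence()`
inverts any rendered sentence to its `(term, id)` pair. A single template is
the default because multi-template training mainly multiplies corpus size;
`render_sentence()` is exposed so callers who want additional templates can
build them explicitly.

## Corpus variants and the half-synonym split

* **NAME** — one sentence per concept, preferred name only. All synonyms are
  recorded as held out.
* **NAME+SYN** — per concept, the NAME sentence plus sentences for a seeded
  uniform random sample of `floor(n_syn / 2)` synonyms; the remaining
  `ceiling(n_syn / 2)` go to the held-out list. A concept with six distinct
  surfaces (name plus five synonyms) therefore trains on three surfaces and
  holds out three.
* **Typo-augmented** — one sentence per input sentence with the term replaced
  by a single-character keyboard typo, for additional fine-tuning epochs.
  The typo corpus is emitted separately so a training schedule can either
  concatenate it with or substitute it for the clean corpus.

Design choices that were genuinely open, and how they were fixed:

* *Floor-to-train, ceiling-to-hold-out* for odd synonym counts. This is the
  conservative direction: the evaluation share is never smaller than the
  training share. With an even count (the six-surface example above) the
  choice is indifferent.
* *Seeded random selection* of the training half rather than "first half of
  the file", to avoid inheriting ordering bias from the source OBO file.
  The split is a pure function of `(vocabulary, seed)` and the
  training/held-out sets are disjoint and exhaustive per concept — both are
  property-tested.
* Synonyms are ingested regardless of scope tag (EXACT/BROAD/NARROW/RELATED),
  deduplicated case-sensitively, and a synonym equal to the preferred name is
  dropped; obsolete and non-HP stanzas are skipped with logged counts.

## Typo model

`qwerty_layout()` builds the adjacency table from key coordinates on a
staggered QWERTY keyboard (row offsets 0, 0.25, 0.75 key widths): two keys
are neighbors when they are in the same row at distance one, or in adjacent
rows at horizontal distance below one. That rule includes diagonal
neighbors, giving `i -> {u, o, j, k}` and `m -> {n, j, k}`, and it is
symmetric by construction.

* `simple_typo()` replaces exactly one letter with a uniformly drawn
  neighbor, preserving case; Hamming distance is exactly 1.
* `complex_typo()` alters `k = min(3, max(1, round(0.2 * L)))` **distinct**
  letter positions, where `L` counts letters only. Rounding is half-up, so
  `k` is 1 for a five-letter term and saturates at 3 from thirteen letters
  on. Counting letters rather than all characters keeps the perturbation
  rate meaningful for multi-word terms; sampling positions without
  replacement makes the Hamming distance equal `k` exactly.
* Non-letter characters (spaces, digits, commas, hyphens) are never altered:
  keyboard proximity is defined for letters, and substitution-only typos
  keep term length fixed. Insertions, deletions and transpositions are out
  of scope by design.

`strip_hyphens()` replaces hyphens with spaces and collapses whitespace —
idempotent, and commuting with the BM25 tokenizer (see below), so hyphen
handling only matters for completion models, whose training surfaces are
almost entirely hyphen-free.

## BM25 baseline

`build_index()` indexes **every (name, concept) and (synonym, concept) pair
as its own entry**, so synonyms compete as separate candidates rather than
being concatenated into one document per concept. The tokenizer lowercases,
splits on runs of non-alphanumeric characters, and applies no stemming or
stopword removal — a plain keyword index.

Scoring is standard Okapi BM25,

$$\mathrm{score}(q, e) = \sum_{t \in q} \ln\!\Big(1 + \tfrac{N - df_t + 0.5}{df_t + 0.5}\Big)\cdot \frac{tf_{t,e}\,(k_1 + 1)}{tf_{t,e} + k_1\,(1 - b + b\,\mathrm{len}_e/\overline{\mathrm{len}})}$$

with `k1 = 1.2`, `b = 0.75` (the common defaults of Lucene-style engines;
both are arguments of `build_index()`), and the non-negative IDF variant so
ubiquitous tokens never push a score below zero.

Retrieval modes: `AND` admits only entries containing **all** query tokens,
`OR` entries containing at least one; candidates are then ranked by score
and the top-1 concept ID returned. Ties are broken by the lexicographically
smallest concept ID, and an empty candidate set (or an empty token list)
returns `NA` — determinism is required for testing, and a miss is scored as
incorrect downstream. The AND candidate set is a subset of the OR set for
every query, which is the mechanism behind the characteristic failure mode:
a single mistyped token removes the gold entry from every AND candidate set,
while OR can still rank it first via the intact tokens. `normalize_term()`
is cross-checked against a brute-force enumeration scorer on small indexes.

## Completion-model adapter

Any object implementing `complete(model, prompt)` can be evaluated:
`completion_normalizer()` renders a prompt template (default: the training
prompt; `"HPO ID of {term} is "` ships as the rewording probe), requests a
greedy continuation capped at 16 characters — an HP identifier plus slack —
and extracts the first `HP:` + 7-digit substring. Greedy decoding keeps
evaluation deterministic; hallucinated identifiers are well-formed by
construction of the extractor and simply score as wrong.

`finetune_config()` carries the fine-tuning recipe: 100 epochs, 30
additional typo epochs, batch size 128, low-rank adapter rank 32. For large
transformer backends the LoRA fields configure adapter-based training; the
built-in model below has so few weights that it trains all of them and
records the LoRA fields untouched.

### The built-in character-level model

`char_lm()` is a fixed-context MLP over a character embedding: a 64-character
window, embedding dimension 12, one tanh hidden layer of width 256, and a
softmax over a ~75-symbol character set — about 216k parameters. The window
length is the one load-bearing choice: in the training template, roughly 37
characters separate the end of the term from the first identifier digit, so
a shorter window would predict digits from context that is identical across
concepts. Training is minibatch Adam (default step size 0.005) on the
cross-entropy of next-character prediction over every position of every
sentence, seeded and therefore bit-reproducible; the per-epoch mean negative
log-likelihood is returned as the loss trace.

The model exists to exercise the train–memorize–evaluate loop of the
completion contract at desk scale: trained for 100 epochs on a 20-concept
NAME corpus it memorizes the training sentences (loss falls from ~2.8 to
~0.05 and greedy decoding recovers every training identifier) while scoring
zero under the reworded prompt — the prompt-brittleness signature of a model
fine-tuned on a single sentence structure. It makes **no** claim of
generalizing to unseen synonyms the way a billion-parameter pretrained model
can, and nothing in the package's conclusions rests on it doing so.

## Evaluation protocol

`build_query_sets()` assembles up to six categories: every preferred name
(`TRAIN_NAME`), the held-out synonyms (`HELD_OUT_SYNONYM`), seeded simple
and complex typos of preferred names (`SIMPLE_TYPO`, `COMPLEX_TYPO`),
cross-referenced surface terms (`XREF`), and colloquial paraphrases supplied
as a TSV (`LAYMEN`). Typos are generated from preferred names only.
`evaluate_normalizer()` scores any `term -> ID or NA` function: correctness
is exact string equality on the normalized-case ID; `NA` and normalizer
errors are recorded as no-prediction and count as incorrect. For every wrong
well-formed prediction the digit-level suffix mismatch length against the
gold ID is recorded — concepts whose IDs differ only in trailing digits are
often hierarchically close, so this is a useful error diagnostic, but it
never awards partial credit. Reports render as TSV or an aligned text table
with one-decimal percentages.

## What the synthetic fixtures do and do not emulate

`generate_fixture()` emulates the structural features the pipeline depends
on: HP-shaped sequential IDs, one multi-word name plus 0–8 synonyms per
concept, optional hyphenated SNOMED-style cross-references, and
deterministic generation (byte-identical output per seed). Names and
synonyms are 2–5-token phrases with globally unique token sets, which makes
exact-name self-retrieval exactly solvable and is what the 100%
self-retrieval check relies on.

Real vocabularies differ in ways that matter for absolute numbers:

* Real synonyms share tokens with their concept's name ("Hearing loss" /
  "Hearing impairment"); fixture synonyms are unrelated phrases. BM25
  accuracy on fixture `HELD_OUT_SYNONYM` queries is pure surface
  self-retrieval (synonyms are indexed), and fixture `XREF` accuracy is near
  zero by construction — neither number transfers to a real vocabulary.
  Relatedly, retrieval rows for `TRAIN_NAME` and `HELD_OUT_SYNONYM` measure
  exact-surface lookup, not generalization, and are not comparable to
  accuracies of a fine-tuned model on those categories.
* Real names have skewed token frequencies ("abnormality", "of the") that
  compress IDF contrast; fixture tokens are near-uniform. Typo accuracies on
  fixtures are therefore optimistic for OR retrieval, though the
  **ordering** — OR far above AND, AND near zero on multi-token typo
  queries — is structural and does reproduce.
* Fixture phrases contain no punctuation inside names, no abbreviations and
  no ambiguous surfaces mapping to multiple concepts.

Passing tests on fixtures therefore validate mechanism (splits, conservation
laws, retrieval semantics, determinism), not clinical-grade accuracy.

## Numerical and degenerate-input choices

* Problem sizes: property suites run on fixtures of 20–500 concepts;
  retrieval/oracle equivalence on indexes of at most 30 entries (where
  brute-force enumeration is exact); the trainable model on a 20-concept
  corpus for 100 epochs.
* All randomized operations take explicit seeds and restore the caller's RNG
  state; sub-seeds for pipeline stages are small offsets of the user seed.
* Degenerate inputs: empty vocabularies are fatal for corpus and index
  builders; terms without letters are fatal for typo generators; an empty
  query tokenization returns no prediction; a concept with zero synonyms
  contributes one sentence and holds out nothing; `epochs = 0` returns the
  model unchanged with an empty loss trace.
* Index persistence stores entries and parameters as versioned JSON and
  rebuilds postings on load, keeping the artifact plain-text.

## Known limitations

* No ontology graph reasoning: the concept hierarchy is neither parsed nor
  used, although the near-miss diagnostic exists precisely because
  ID-adjacent concepts are often semantically adjacent.
* No fuzzy or character-n-gram retrieval; that would change the baseline
  being characterized.
* Laymen's terms are consumed from a file; generating them is out of scope.
* Full-scale fine-tuning of a large pretrained model is configuration only:
  the package defines the records, the hyperparameters and the evaluation
  contract, and `finetune()` implements them for the built-in model.
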