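---
title: "Tracking and explaining violence-related injuries in ER narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and explaining violence-related injuries in ER narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergency-room narrative reports are short, hurried free-text notes:
abbreviations, acronyms, typos and domain jargon are so dense that most
records contain at least one out-of-dictionary token, and the distribution
of those noisy forms is steeply Zipfian — a small curated dictionary of the
most frequent forms repairs a disproportionate share of the noise. Violence
-related injuries (against women, children, the elderly) are systematically
under-reported in such data, which motivates an automatic surveillance
pipeline with two outputs per record:

1. a binary categorization — violence-related (**V**) vs not (**NV**) —
   produced by a neural classifier, and
2. for records deemed V, an *explanation*: a six-slot **violence frame**
   (AGENT, MODE-INSTRUMENT, TIME, LOCATION, BODY-PART, LESION-TYPE) filled
   with the tokens of the record that instantiate each semantic role.

Because the narratives are too ill-formed for dependency parsing, the frame
filler is deliberately parser-free: it combines corpus-trained word
embeddings with two shallow symbolic filters (part-of-speech tags and
WordNet supersense tags).

## The cleaning stage

`normalize_punctuation()` lowercases, collapses whitespace and restores the
missing space after sentence punctuation; it is a projection (applying it
twice equals once). `apply_rewrites()` then expands abbreviations,
acronyms and recurring typos through a rewrite dictionary
(`surface → expansion`, whole-token matches only). The shipped fixture
dictionary has 50 entries; real deployments supply their own TSV. The
dictionary validator enforces a property the rewriting contract depends on:
no whole token of any expansion may equal any surface form. This is
slightly stronger than forbidding self-maps — it also rules out chains such
as `a → b`, `b → c` — and is exactly the condition under which single-pass
rewriting is idempotent.

Tokens not in the dictionary are left untouched: an unlisted abbreviation
survives verbatim, fails embedding lookup later, and simply cannot become a
frame filler — the designed failure mode for unknown noise.

## Word embeddings and role prototypes

`train_embeddings()` trains skip-gram vectors with negative sampling on the
cleaned, tokenized corpus itself (after multiword locutions like
`known_person` are merged, so locutions receive vectors too). The trainer
is vectorized base R: all (center, context) pairs from a fixed symmetric
window are shuffled per epoch and processed in large mini-batches whose
per-token gradients are aggregated as group means — the aggregation keeps
the step size of very frequent tokens bounded, which is what makes the
batched scheme stable where naive gradient summing diverges. Negative
contexts follow the unigram distribution to the 3/4 power; the learning
rate decays linearly. Defaults (window 5, min-count 2, 5 negatives, 10
epochs, dimension 300) are conventional skip-gram settings for small
corpora; every one is exposed.

Two deliberate choices deviate from the word2vec reference implementation
and are worth recording:

* **No dynamic window shrinking.** word2vec resamples the window width per
  token; we keep it fixed for determinism and vectorization. On desk-scale
  corpora the effect is negligible.
* **Exposed vectors are the average of the input and output matrices**
  (option `vectors = "input"` restores the classic convention). On small
  corpora the average also captures first-order co-occurrence — two tokens
  that always appear side by side but never share further context have
  nearly orthogonal *input* vectors, while their input–output products are
  trained directly. Frame ranking benefits measurably.
* **No subword n-grams.** The module contract is a token→vector lookup;
  the subword machinery adds nothing testable at this corpus scale.

Each frame field carries a list of *seed terms* — typical fillers such as
"husband"/"known_person" for AGENT or "fracture"/"contusion"/"trauma" for
LESION-TYPE. `build_prototype()` averages their vectors into the field's
prototype; candidates are later ranked by cosine similarity to it.
Duplicate seeds are kept, so repetition acts as frequency weighting;
out-of-vocabulary seeds are skipped and reported, and a field whose seeds
are all out of vocabulary is a configuration error, not a silent empty
slot.

## The categorizer

`build_model()` assembles the published layer stack exactly: trainable
embedding layer (initialized from the corpus skip-gram vectors; random
uniform rows for tokens without one; a zero row for padding) → 20% dropout
→ 1-D convolution with 64 filters of kernel size 5 and ReLU → max pooling
of window 4 → LSTM with 100 memory units → one sigmoid unit. Training uses
Adam and binary cross-entropy with an 80:20 class-stratified
train/validation split. Forward and backward passes are hand-written
vectorized R (im2col convolution, argmax-routed pooling gradients, full
backpropagation through time); there is no framework underneath, which
keeps the whole run reproducible from a single integer seed.

Choices the architecture description leaves open, fixed here as defaults:
sequence length 100 tokens (pad/truncate at the end; the synthetic
narratives use 30), batch 32, up to 10 epochs with early stopping on
validation loss (patience 2, best weights restored), Adam step 0.001,
decision threshold 0.5, no class reweighting (an optional `class_weight`
switch exists but is off). The embedding layer stays trainable:
"initialized from" pretrained vectors, then fine-tuned.

## Filling the frame

For a record labeled V, every distinct token is a candidate for every
field (types, not positions). Then, per field *f*:

1. **Prune** (unless running the baseline): keep token *t* iff its PoS tag
   is in the field's allowed set *and* at least one supersense of its most
   frequent sense is in the field's allowed set. The compatibility sets
   are: AGENT noun/noun.person; MODE-INSTRUMENT noun/object, artifact,
   state, substance, feeling, act; TIME noun/noun.time; LOCATION
   noun/noun.location; BODY-PART noun/noun.body; LESION-TYPE noun or
   adjective/noun.state, adj.all, noun.phenomenon. Extended tokens bypass
   both filters. Out-of-lexicon tokens have an empty supersense set and
   are pruned — an unknown word should not fill a slot by accident; the
   locution list is the intended escape hatch.
2. **Rank** the survivors by cosine to the field prototype (tokens without
   vectors are dropped; ties break lexicographically).
3. **Threshold**: entries scoring below 0.5 are discarded.
4. **Resolve**: a token surviving for several fields is kept only where
   its score is highest; cross-field ties break by schema order (AGENT
   first). All survivors of a field are its fillers — a slot may
   legitimately end up with zero or several.

The tagger is a pluggable backend; the shipped one is a deterministic TSV
lexicon with most-frequent-sense lookup (rank-1 sense group; ties within
the group return the union of supersenses, which only widens the candidate
pool). The PoS fallback for out-of-lexicon tokens is NOUN — clinical
out-of-vocabulary terms are overwhelmingly nominal — and extended tokens
are always NOUN. Step ordering for resolution is: threshold first, then
reassignment, then per-field reporting; the baseline (no PoS/supersense
filtering) keeps the same threshold so the two runs differ in exactly one
ingredient.

## The synthetic study conditions

The original surveillance data is restricted, so the package carries a
generator that emulates its published statistics rather than its language:

* violence prevalence **3.36%**, allocated by exact quota so class counts
  are reproducible;
* per-field gold fill probabilities AGENT 60%, MODE-INSTRUMENT 97%, TIME
  23.5%, LOCATION 8%, BODY-PART 89.5%, LESION-TYPE 86.5%;
* English-like assault/accident sentence templates over filler
  inventories consistent with the fixture lexicon; one filler per
  mentioned slot; gold frames recorded before noise;
* a noise channel that runs the rewrite dictionary *in reverse*
  (expansion → abbreviation) with a steep Zipfian preference for its top
  entries, plus character-level typos and whitespace jitter. Abbreviation
  noise is exactly invertible by the cleaner — the round-trip property the
  tests rely on; typo events are logged so tests can condition on them.

What the generator does **not** emulate: real clinical vocabulary breadth,
Italian morphology, multi-filler slots, inter-annotator disagreement, and
discourse phenomena (several persons per report, negation). Passing tests
therefore demonstrate that the machinery is correct and that the filters
help under controlled conditions — not that the published accuracy figures
transfer to any particular hospital's data.

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise every component
meaningfully at desk scale: 5,000-record corpora with 100-d embeddings (8
epochs) for the frame benchmark, a 2,000-record corpus with the full 300-d
architecture for the classifier benchmark, and 200-record corpora with
16-d embeddings for determinism checks. Cosine similarity refuses zero
vectors and mismatched dimensions rather than returning NaN. Ranking ties
break lexicographically and cross-field assignment ties break by schema
order, so every ordering in the system is total and reproducible.

## Known limitations

* The most-frequent-sense heuristic ignores context; polysemous tokens
  with an atypical dominant sense are mis-filtered (the documented failure
  mode of the supersense filter).
* Several persons in one narrative cannot be disambiguated without syntax;
  the agent slot then depends on embedding proximity alone.
* The classifier's reported benchmark is deliberately separable; real
  V/NV boundaries are far noisier, and the published per-class figures
  (F1 ≈ .99 NV / .86 V on ~77k real records) are not reproducible without
  the restricted corpus.
* Spelling correction beyond the dictionary is out of scope, as is
  multiword-expression *discovery* (the locution list is given, not
  learned).
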