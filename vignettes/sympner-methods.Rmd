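---
title: "Methods: CRF-based symptom NER with BPE-dropout and sub-subword embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRF-based symptom NER with BPE-dropout and sub-subword embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the representation

`sympner` recognizes symptom mentions in clinical text as labelled character
intervals.  A mention is an `EntitySpan` — `(doc_id, label, start, end,
text)` with 0-based, end-exclusive offsets (the BRAT/standoff convention) —
and the package moves between three representations:

1. **Standoff**: one TSV row per entity over plain-text documents.  This is
   the interchange format; readers verify that every span's surface text
   equals the document substring and refuse to repair mismatches, because an
   offset bug silently "fixed" at read time would poison every downstream
   measurement.
2. **Sentences**: documents are segmented by a rule-based boundary proposer
   (sentence punctuation + whitespace + an uppercase or inverted-punctuation
   character).  Any candidate boundary that falls strictly inside an entity
   is discarded, so no entity ever crosses a sentence boundary; sentences
   tile the document exactly, which makes character- and entity-count
   conservation a testable invariant.  The proposer is a plain function
   argument, so a statistical splitter can be swapped in without touching
   anything else.
3. **BIO tag sequences**: over word tokens (maximal alphanumeric runs plus
   single punctuation marks), the first token of a span gets `B-<label>`,
   later tokens `I-<label>`, everything else `O`.  S-/E-tags are not used.
   Overlapping gold spans are rejected at encode time — BIO cannot represent
   them.  The decoder, by contrast, must tolerate *invalid* sequences
   (per-position argmax heads emit them): an `I` with no compatible
   predecessor is promoted to `B`.  This orphan repair maximizes recall and
   keeps the decoder total.

## Subwords and BPE-dropout

A byte-pair-encoding model is an ordered list of symbol-pair merges over a
base alphabet; rank 0 merges first.  Deterministic encoding repeatedly
applies the best-ranked applicable merge (leftmost occurrence first).
Training-time regularization uses **BPE-dropout**: every attempt to apply a
candidate merge is vetoed independently with probability `p`, so the same
sentence is segmented differently on every epoch — an augmentation effect
for which the conventional setting, used as the default here, is `p = 0.1`.
Two limit laws pin the implementation down exactly: `p = 0` must reproduce
deterministic encoding and `p = 1` must yield pure base symbols; both are
asserted in the tests, as is text reconstruction (concatenating a word's
subwords restores the word) for every `p` and seed.

Dropout is applied to training sentences only.  Prediction always uses the
deterministic segmentation, so predicted offsets are reproducible.

Words are pre-tokenized before BPE and encoded word-by-word, keeping every
subword's exact character interval.  Word-level tags are propagated to
subwords (`B-x` word → `B-x, I-x, I-x, …`), but only word-start subwords are
supervised; continuation subwords are masked out of the loss and ignored at
decode time.  Whether continuation subwords should instead be supervised is
genuinely open; both modes are implemented
(`align_labels(..., supervise_continuations = TRUE)`), masking is the
default because it keeps the tag chain in one-to-one correspondence with
words and hence with recoverable character offsets.

## The sequence model

Emission scores come from a small trainable encoder: token embeddings plus
learned positions, feeding a pre-norm transformer (default 2 layers, width
64, 2 heads, ReLU feed-forward of twice the width) written with explicit
backpropagation and verified against finite differences in the test suite.
The default geometry is deliberately tiny so that the complete stack trains
on a laptop CPU in minutes; a pretrained encoder could replace it behind the
same interfaces, but nothing in the package requires one.

Two output layers are available:

- **Softmax**: independent per-position classification, masked
  cross-entropy.  This head can and does produce invalid BIO transitions.
- **Linear-chain CRF**: path score = start + emissions + transitions + end;
  trained by exact negative log-likelihood via the forward algorithm,
  decoded by Viterbi.  All dynamic programming is in log space with a
  stable log-sum-exp.  Both the log-partition and the decoder are checked
  against exhaustive path enumeration (all `L^T` paths for small `T`, `L`).

**Transition bias.**  The CRF transition matrix is initialized so that
invalid BIO transitions carry a large negative score, `-10000` by default —
effectively `-Inf` at single precision yet safe inside log-sum-exp (a true
`-Inf` would risk `NaN`).  The default `"all_invalid"` mode penalizes
`O → I-x`, `start → I-x` and `B/I-y → I-x` (`y ≠ x`); these are exactly the
transitions that produce an `I` without a compatible predecessor.  A
strictly literal `"o_to_i"` mode penalizing only `O → I` is provided, since
reasonable implementations differ on this point.  Biased entries remain
trainable by default ("initialized" is not "frozen");
`ner_config(crf_freeze_bias = TRUE)` re-imposes them after every optimizer
step.  With the bias in place, decoded output contains no invalid
transitions on any input we have been able to construct, and the acceptance
suite asserts zero invalid transitions across full synthetic test sets while
the softmax head on the same data produces several.

Viterbi ties break toward the lowest label index at every backtracking step
— deterministic, and irrelevant for continuous random scores.

**Training.**  AdamW with decoupled weight decay (applied to weight
matrices, not biases or gains).  The canonical fine-tuning recipe for this
task family — 25 epochs, batches of 15 sentences, learning rate 2e-5,
keeping the best checkpoint by validation score — is the `train_config()`
default.  Two deviations matter in practice and are deliberately exposed
rather than hidden: (a) a from-scratch tiny encoder needs a much larger
learning rate than a fine-tuned pretrained model, so the examples and tests
use 2e-3–4e-3; (b) the model-selection metric is unspecified in common
descriptions of the recipe, and we fix it to strict entity-level F1, the
metric the task optimizes.  A fixed-budget mode (`selection = "last"`) and
an optional single extra epoch on train+validation are provided, matching
common submission practice.

## Sub-subword feature embeddings

Instead of a free lookup table, each subword's embedding can be produced by
a feed-forward network from the character n-grams of the boundary-marked
subword string (`^subword$`).  The **FTE** (feature-to-embedding) network
has a fixed architecture of three hidden layers — width 3072 by default,
configurable down for small-scale work — with tanh activations (the
activation is not dictated by anything; a smooth, bounded nonlinearity keeps
the MSE pre-fit well behaved).  The feature inventory is selected before
training: n-grams (default orders 1–4, default `K` 4096) are ranked by
frequency over the vocabulary, with all order-1 n-grams always included as a
coverage floor so every subword has at least one active feature.  This
frequency heuristic is a documented, reproducible stand-in for more
elaborate selection algorithms and is deliberately replaceable.

When a target embedding matrix exists, the FTE network is **pre-fitted by
mean squared error** to it before joint training, so that swapping the
lookup table for the FTE output starts the NER model near the embeddings it
would otherwise have used.  Two properties make this step testable without
reference to any external model: the loss must strictly decrease from
initialization, and two subwords with identical feature vectors (e.g. `ab`
vs `ba` under unigram features) must map to identical embeddings, so
distinct targets for them leave an irreducible positive loss with an
analytically known floor.  After pre-fitting, the FTE parameters continue
training with the rest of the model.

## Ensembling

Majority voting over span predictions: a span is emitted iff at least
`threshold` member models predicted the *identical* span (document, start,
end, label).  The default threshold is the strict majority
`floor(n/2) + 1`; for even pools (6 or 12 models, as arise when pooling two
or four three-seed configurations) that is 4-of-6 and 7-of-12 — the tie
rule for even pools is not standardized anywhere, so the package makes its
choice explicit and configurable.  If voted spans overlap, the higher-vote
span wins; vote ties go to the longer span, then the earlier start.
Voting is idempotent, monotone in added voters at fixed threshold, and
degenerates to intersection (`threshold = n`) and union (`threshold = 1`).
Because identity is exact-span, ensembling works at the file level on any
systems' standoff outputs (`ensemble_files()`).

## Evaluation

Strict scores count exact `(doc, start, end, label)` matches.  Overlapping
scores (`o_P`, `o_R`, `o_F1`) let a prediction match a gold span of the
same document and label whose interval intersects it, under a **one-to-one
maximal matching**: a greedy assignment by overlap length (ties: earlier
prediction start, then earlier gold start) is completed to a maximum
bipartite matching with augmenting paths.  Greedy alone is provably
suboptimal on some disjoint-interval instances — e.g. gold
`[0,10), [12,20)` with predictions `[3,13), [0,2)`, where taking the
largest overlap first strands both remaining spans — and an evaluator that
under-counts on such instances would make `o_` scores depend on span order.
The implementation is fuzz-tested against an exhaustive matcher on all
instances with up to 8 spans per side.  Every strict match is an overlap
match, so `o_F1 ≥ F1` holds universally.

Conventions, all of which show up in degenerate test cases: empty gold and
empty predictions score 1.0; no predictions against non-empty gold gives
precision 0; `F1 = 2PR/(P+R)` with `F1 = 0` when `P + R = 0`.  Multi-run
aggregation reports mean, sample SD (n−1 denominator; 0 for a single run),
min and max, and `format_run_table()` prints the conventional
`Mean (SD) / Min / Max` percent table.

## The synthetic corpus

`generate_corpus()` emulates the *shape* of a symptom-NER corpus: documents
of sentences assembled from a distractor vocabulary, with multi-word,
accent-bearing gazetteer phrases inserted as labelled spans.  Defaults —
50 documents of 10 sentences, 6–12 word slots per sentence, entity
probability 0.5 per sentence, a 12-phrase Spanish-flavoured gazetteer — give
a corpus whose scale (hundreds of sentences, one entity class `SINTOMA`,
spans of 2–4 words) mirrors a desk-scale slice of a real shared-task corpus
while remaining trivially regenerable from a seed.

The one scientifically load-bearing knob is `ambiguity_rate`: the
probability that a distractor slot is filled with a single gazetteer
*token* emitted as non-entity text.  At 0, membership in the gazetteer
fully determines the label and a model can memorize its way to near-perfect
F1 — that configuration is the end-to-end correctness check.  At moderate
rates (the ablation study uses 0.15), token identity alone is insufficient,
label transitions and context carry real information, and the relative
ordering of the ablation configurations (softmax < CRF < CRF+bias) has room
to express itself.

What the generator does **not** emulate: grammar, discourse structure,
spelling variation, nested or discontinuous mentions, annotation
disagreement, or the long-tail lexical distribution of real clinical text.
Passing tests on this corpus demonstrate that the machinery is correct and
that the methods behave directionally as expected; they are not evidence
about absolute performance on real clinical corpora, which additionally
requires a pretrained domain encoder and gold data.

`corrupt_predictions()` complements the generator for evaluation tests: it
degrades gold annotations with known drop, shift and spurious-span rates,
so expected precision/recall are known by construction (a pure sub-length
offset shift keeps `o_F1 = 1` while pushing strict F1 below 1).

## Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise every code path
with comfortable statistical margins on one CPU core: CRF-vs-enumeration on
1000 random instances (`T ≤ 4`, `L ≤ 4`, tolerance 1e-6); 10 000 BPE
round-trip fuzz cases; 1000 evaluation instances against the exhaustive
matcher; an end-to-end run on a 300-sentence unambiguous corpus (width-32,
2-layer encoder, 12 epochs) that is required to reach strict F1 ≥ 0.9; and
a 3-seed × 3-configuration ablation on a 400-sentence corpus with
ambiguity 0.15 (14 epochs), where mean strict F1 must be non-decreasing
from softmax to CRF+BPE-dropout to CRF+BPE-dropout+bias within a 0.02
tolerance, and each configuration's 3-seed majority-vote ensemble must not
fall below its weakest member.  The tolerance acknowledges that three seeds
estimate a mean coarsely; the orderings observed in practice clear it by a
wide margin.

Other fixed numerical choices: log-sum-exp everywhere in CRF dynamic
programming; transition bias −10000; LayerNorm ε 1e-5; Adam ε 1e-8,
β = (0.9, 0.999); softmax-head log-probabilities floored at 1e-12; FTE
weights initialized uniform ±sqrt(6/(fan_in+fan_out)), encoder weights
normal σ = 0.02.  All randomness flows through explicit seeds: corpus
generation, parameter initialization, batch shuffling and BPE-dropout
sampling are each reproducible, and training is bit-deterministic given its
seed.

## Known limitations

- The tiny encoder is a correctness vehicle, not a competitive clinical
  model; no pretrained-weight loading is bundled.
- BIO cannot represent overlapping or discontinuous mentions; such gold
  input is rejected rather than approximated.
- The feature-selection heuristic for sub-subword features is a stand-in;
  plugging in a different selection algorithm only requires producing an
  `ssw_inventory`.
- Exact-span identity in voting means boundary-variant predictions of the
  same mention split their votes; an overlap-merging vote is possible but
  deliberately not the default, as it changes what "majority" means.
- Checkpoints use R serialization (RDS): self-describing and bit-stable
  within R, but not a cross-language format.
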