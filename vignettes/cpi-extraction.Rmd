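---
title: "Extracting chemical-protein interactions with a narrow shortest-dependency-path representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-protein interactions with a narrow shortest-dependency-path representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdprel)
```

## The task and the model

Biomedical abstracts describe interactions between chemical compounds and
proteins — activation, inhibition, agonism, antagonism, substrate
relations. Given gold-standard entity mentions and pre-computed dependency
parses, `sdprel` classifies every chemical–protein mention pair that
co-occurs in a sentence into one of the five evaluated CHEMPROT relation
groups (CPR:3, CPR:4, CPR:5, CPR:6, CPR:9) or a negative class. The design
premise is a deliberately *narrow* instance representation: the words that
decide whether "meloxicam" inhibits "COX" almost always sit on the
shortest dependency path (SDP) between the two mentions, so a small model
over at most 10 SDP tokens can compete with far larger sentence encoders.

Each candidate pair is represented by five sequences of
(token, PoS tag, dependency label) triples:

1. the SDP from the chemical head token to the protein head token
   (undirected search over the dependency graph, at most 10 tokens / 9
   hops, dependency features taken from the traversed arcs, final slot
   `#none`);
2. the chemical-left and 3. chemical-right contexts;
4. the protein-left and 5. protein-right contexts (at most 20 tokens
   each, every token carrying its *incoming* arc label, `#none` when the
   token has no governor — collapsed dependency graphs leave absorbed
   prepositions without incoming arcs).

The two focal mentions are blinded to `#chemical` / `#gene` so the
classifier learns relational patterns rather than entity names; a pair
whose mentions share a single token (a chemical nested inside a protein
name) collapses to the joint placeholder `#chemical#gene`.

Two choices here deserve a note because the representation is sensitive to
them:

* **Context bounds.** The inner context sequences stop at the *other*
  focal entity: chemical-right and protein-left both cover exactly the
  tokens strictly between the two mentions (and are therefore identical
  when the chemical precedes the protein), while chemical-left and
  protein-right run to the sentence edges. This is what the reference
  sentence reproduced in `inst/extdata` requires; cutting at the partner
  entity also keeps the linear input centred on the span that actually
  expresses the relation.
* **Head tokens and ties.** For a multi-word mention the anchor is the
  token whose governor lies outside the mention; when no token or several
  tokens qualify, the last mention token is used. Shortest paths are found
  by breadth-first search expanding neighbours in ascending token index,
  which fixes tie-breaking deterministically (on dependency *trees* the
  shortest path is unique anyway; ties can only arise on degenerate
  graphs).
* **Truncation sides.** When a path exceeds 10 tokens the chemical-side
  prefix is kept (the traversal starts at the chemical) and the final
  surviving triple's dependency slot is forced to `#none`; context
  sequences keep their entity-proximal 20 tokens, since relation cues
  cluster near the mentions.
* **No-path pairs.** Candidate pairs whose head tokens are disconnected in
  the dependency graph cannot be represented on an SDP at all; they are
  skipped and counted, not padded into empty instances.

## Encoding

Tokens are encoded by three fixed embedding tables. Word vectors come from
any pre-trained word2vec/fastText text-format model; because the parser's
tokenization never matches the embedding vocabulary exactly, each corpus
word is mapped by greedy longest-match segmentation (case-folded) over the
embedding vocabulary and represented by the L2-normalized sum of its
constituent vectors. An exact vocabulary hit keeps its stored vector
unchanged (whether single-constituent compositions should also be
re-normalized is genuinely ambiguous; it is a flag, off by default).
Words with no matchable constituent are *dropped* together with their PoS
and dependency entries — in practice this removes uninformative stopwords
and shrinks the vocabulary considerably.

PoS-tag and dependency-label embeddings are small fixed tables built from
the corpus itself (window-3 co-occurrence + PPMI + truncated SVD, or
seeded uniform vectors in [-0.05, 0.05]; randomly initialized fixed tag
embeddings perform on par with trained ones for this task, so the random
mode is the pipeline default). All tables stay fixed during training.

Every instance becomes two index arrays: the SDP input (10 positions) and
the linear input (80 positions: chem-left ‖ chem-right ‖ prot-left ‖
prot-right, each post-padded to 20). Index 0 is reserved for padding and
embeds to the zero vector.

## The classifier

Both inputs pass through the same two-branch architecture: per-position
concatenation of word+PoS+dep vectors → additive Gaussian noise (sd 0.01,
training only) → a branch core → concatenation of the two branch outputs →
dropout 0.4 → dense softmax over the six classes. The branch core is
either

* a bidirectional LSTM (128 units per direction, dropout and recurrent
  dropout 0.4) whose two final states are concatenated — final-state
  pooling matches the narrow-representation intent, the sequences are
  short; or
* parallel 1-D convolutions with window sizes 3/4/5 and 64 filters each,
  ReLU, followed by global max pooling.

Masking: the recurrent core carries its state unchanged through padded
positions. Convolutions see zero vectors at padded positions — each
window size contributes one window per start position, implicitly
zero-padded on the right, and the global max pool only admits windows
starting at a content position. With this scheme a window's value depends
only on the content it covers, so trailing padding provably never changes
a branch output (a property test verifies this in a bias-free
configuration), while short sequences still activate every filter bank:
a 3-token SDP — the most common case — would have no fully-contained
size-4 or size-5 window at all. Gaussian noise is applied to the full concatenated
embedding vector, not to the word part only, since the noise layer sits
after the concatenation.

No deep-learning framework is involved: the forward pass, backpropagation
through time and the RMSprop optimizer (lr 0.001, rho 0.9) are implemented
directly on BLAS matrix operations, and all analytic gradients are checked
against central finite differences in the test suite (relative error
below 1e-5 on both cores).

## Training protocol

Training minimizes class-weighted categorical cross-entropy (weights
inversely proportional to training-set class frequency, normalized so the
per-instance mean weight is 1) in minibatches of 128. 30% of the instances
form a validation subset. After every epoch:

1. the decision threshold θ is tuned **on the training portion** — the
   rule: predict the best positive class c\* if P(c\*) ≥ θ, otherwise
   NEGATIVE; θ maximizes micro-F1 over a 0.00–1.00 grid in steps of 0.01,
   ties resolved to the smallest θ (favouring recall). NEGATIVE is the
   abstention class, so this monotonically trades precision for recall;
2. validation micro-F1 is computed with that θ and monitored for early
   stopping (patience 30, maximum 500 epochs); the weights and θ of the
   best validation epoch are restored at the end. The per-epoch θ thereby
   influences both model selection and final reporting.

With `validation_split = 0` training runs exactly `max_epochs` and keeps
the final weights (useful when every instance is needed for training; the
recurrent core is markedly more resistant to overfitting in this regime
than the convolutional one).

Final predictions average the probabilities of three members trained under
different random states — initialization, train/validation split and batch
shuffling all derive from one master seed per member. The ensemble
threshold is the mean of the member thresholds by default (re-tuning on
training data is available via the `theta` argument of
`ensemble_predict()`).

## Evaluation

`micro_prf()` implements the official micro-averaged scoring: a true
positive is an exact (document, label, chemical, protein) tuple match;
a right pair with the wrong label counts simultaneously as a false
positive and a false negative; duplicate predicted tuples are deduplicated
before scoring; zero denominators yield 0. `stratified_heatmap()`
aggregates the same counts per (entities-per-sentence,
relations-per-sentence) cell, the grid on which precision typically decays
for entity-dense, relation-sparse sentences.

## The synthetic corpus generator

Real CHEMPROT data cannot ship with a package, so `generate_corpus()`
emulates the statistical structure the method relies on, with dependency
trees generated directly rather than parsed from text:

* every sentence holds 1–2 chemical and 1–2 protein mentions under a
  verb; in a positive sentence the verb is the class trigger
  (`activates`, `inhibits`, `agonizes`, `antagonizes`, `metabolizes`) and
  governs both entity heads, so the trigger lies on every chemical→protein
  path; negative sentences use neutral verbs, so no trigger ever appears
  on a negative pair's path. Every pair of a trigger sentence is planted
  positive with the sentence label — mixing positive and negative pairs
  inside one clause would put the trigger on negative paths and break the
  contract the classifier is supposed to learn;
* sentence classes are drawn as 50% negative / 10% per CPR class; 1–3
  sentences per abstract; a 60% chance of a headless-preposition tail
  (exercising `#none`), 25% of protein mentions are two-word (exercising
  head finding); `label_noise` flips gold labels at a stated rate
  (0 by default — the reference experiment is noiseless);
* rare layouts are planted on demand: a single token annotated as both
  chemical and protein (5% of negative sentences), and cross-sentence
  gold relations (2% of multi-sentence documents) that the candidate
  generator must discard;
* `make_fixture_embeddings()` draws unit-norm word vectors (dimension 16
  by default, PoS/dep tables dimension 8) with trigger vectors resampled
  until all pairwise cosines fall below 0.3, keeping classes linearly
  separable.

The generator writes the four standard corpus files and returns the
corpus re-read through the package's own readers, so every generated
corpus passes the offset/surface validators by construction.

What passing the synthetic suite does *not* show: real biomedical language
has no single lexical trigger per class, negation and long-range
discourse effects, nested coordination, parser errors, and heavily skewed
class frequencies. The synthetic results certify the machinery —
representation, optimization, thresholding, evaluation — not corpus-level
accuracy on CHEMPROT.

## Reference experiment and problem sizes

`learnability_experiment()` is the package's end-to-end check: a noiseless
140-document corpus (~660 instances), a 75/25 document split (~500
training instances), fixture embeddings, default hyper-parameters capped
at 50 epochs, 3-seed ensembles for both cores, scored with `micro_prf()`
on the held-out documents. Both cores reach high micro-F1 (the recurrent
core ≥ 0.95, the convolutional ≥ 0.90 in the test suite); these sizes keep
the full experiment at a few minutes of CPU time while leaving enough
held-out relations (~150 instances) for a stable estimate.

Reproducing the published CHEMPROT numbers (test micro-F1 around 0.63 for
the recurrent core) is deliberately out of scope for the test suite: it
requires the CHEMPROT corpus distribution, the external TEES/BLLIP/
Stanford parsing pipeline, and large pre-trained biomedical embeddings.
The recipe with real data is exactly the worked example in the README:
read the corpus directory, read the parses, `encode_corpus()` with the
published vectors, `train_ensemble()` per branch core, and
`micro_prf()` against the gold relations of the development/test sets.

## Numerical and degenerate-input choices

* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* A candidate whose SDP drops *all* tokens at encoding time becomes an
  all-padding input; both cores map it to a constant (zero state / zero
  pool) rather than failing.
* `f1_from_pr(0, 0) = 0`, empty prediction sets give precision = recall
  = 0, and an empty corpus is an error at encoding, not a silent empty
  model.
* Thresholds always come from the tuning grid, so serialized models carry
  a θ that re-verification can reproduce exactly.
* Duplicate gold pairs listed under several CPR groups keep their
  first-seen label with a warning (multi-label pairs are rare; the task is
  treated as single-label multi-class); non-evaluated CPR groups are
  dropped at read time rather than mapped to negatives, which would
  contaminate the negative class.

## Known limitations

* Cross-sentence relations are out of scope by design; they are counted
  and discarded.
* The greedy longest-match segmentation is a heuristic; subword-ngram
  inference for truly out-of-vocabulary words (fastText-style) is not
  implemented.
* Entity mentions sharing offsets but differing in term id are accepted
  as distinct (the deduplication policy of the source files is unknown).
* The engine is CPU-bound single-precision-free R; it is sized for the
  narrow representation (10 + 80 positions), not for document-length
  inputs.
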