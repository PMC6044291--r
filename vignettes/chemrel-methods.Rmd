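---
title: "chemrel: model, training procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemrel: model, training procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `chemrel` computes and why it is built the
way it is: the candidate-pair model, the two-phase training procedure,
the parameters that matter, the synthetic corpus the tests rely on, and
the numerical decisions taken where the design was genuinely open.

## The task and its representation

The input is a corpus of abstracts with character-offset annotations of
chemical and gene/protein mentions, and gold relations in five groups
(CPR:3 upregulator, CPR:4 downregulator, CPR:5 agonist, CPR:6
antagonist, CPR:9 substrate/product). The unit of classification is a
*candidate*: one chemical mention paired with one gene mention from the
same document. The model assumes that the evidence for a relation is
local — candidates are restricted to pairs whose token distance (last
token of the later entity minus first token of the earlier one) is at
most 60, and the classified token window extends only 5 tokens beyond
the pair. Gold relations whose arguments are farther apart are
unreachable false negatives by construction.

Offsets index the document text formed as title + one tab + body,
0-based half-open. Because corpus releases differ in this convention,
the entity reader has a strict mode that verifies every annotated
surface against the document slice and fails loudly on a mismatch;
that verification, rather than an assumption, is the guard.

Tokenization is chemistry-aware: whitespace splitting followed by
iterative stripping of clause punctuation and *unbalanced* brackets at
token edges, keeping internal hyphens, digits and balanced brackets, so
`COX-2` and `(S)-ibuprofen` survive as single tokens. The exact rule
set of the original chemistry tokenizer this approximates is not
published; the tokenizer here is a stated, testable rule set behind a
small interface (`tokenize_with_spans()`), and no fidelity claim is
made for Greek letters, unicode dashes or nested brackets. A token
counts as part of an entity on *any* overlap with its span — this is
what makes a token annotated as both chemical and protein maskable as
`$BOTH`, and it determines both the masking and the overlap features.

Each candidate carries three aligned sequences: the masked token ids
(candidate chemical tokens to `$CHEMICAL`, gene tokens to `$PROTEIN`,
shared tokens to `$BOTH`, one mask token per original token); i4, ten
bits per token (the five overlap flags — in, at start, at end,
overlapping start, overlapping end — against any chemical entity and
against any gene entity of the document); and i5, two bits per token
(membership in the candidate chemical / candidate gene). i4 tells the
network where *all* entities are; i5 singles out the pair in question.

## Vocabulary and embeddings

The vocabulary is built from the training corpus only; tokens occurring
once are out-of-vocabulary and map to `<UNK>` at lookup (min_count = 2,
configurable). Five indices are reserved: padding (0), unknown (1) and
the three mask tokens. Embedding rows for tokens found in a GloVe
text-format file copy that vector; rows for all other tokens — and all
five reserved rows — start at zero. Everything stays trainable. The
zero initialization for the reserved rows mirrors the rule for unseen
tokens; the pre-training text shares the task vocabulary, which is what
lets the shared embedding transfer between phases.

## The two networks

Both networks share the embedding `e1`, a forward LSTM `l1` and a
reversed LSTM `l2` (300 units each at full scale) — literally the same
parameter tensors, so an update in one phase is immediately visible in
the other, and nothing is frozen.

The **pre-training network** performs negative-sample discrimination.
For each unlabelled line, a substituted copy replaces every token
independently with probability 0.5 by a token drawn
occurrence-weighted from the current sub-epoch's pool. Inputs are the
original sequence (i1), the substituted sequence shifted one right
(i2, pad first) and one left (i3, pad last); `c1 = [l1, e2]` and
`c2 = [l2, e3]` (600 wide at full scale) feed 300-unit rectified
layers and per-position sigmoid outputs that judge whether each
substituted token is original, from the left and from the right
context. The loss is binary cross-entropy, masked and averaged over
the two outputs.

The **recognition network** runs `e1/l1/l2` over the masked candidate
sequence, adds width-3 rectified convolutions over i4 (48 filters) and
i5 (6 filters), concatenates (`c3`, width 654 = 300+300+48+6 at full
scale), passes a bidirectional LSTM `l3` (128 units per direction),
takes a per-feature maximum over positions (width 256) and ends in a
6-way softmax trained with mean squared error against the one-hot
label. A width-3 convolution can replace `l3` (`l3_type = "conv"`).

All recurrent layers return per-position sequences and use dropout and
recurrent dropout of 0.5 during training (disabled for prediction).
Both networks train with RMSProp (learning rate 0.001 at full scale,
decay 0.9, epsilon 1e-7).

Because no deep-learning framework is available to R here, the layers,
backpropagation through time and the optimizer are implemented in the
package. Correctness is established by finite-difference gradient
checks over every parameter tensor of both networks (tolerance 1e-4 on
the relative error at step 1e-5), plus single-batch overfitting and
determinism tests.

## Training schedule and epoch selection

Training runs `n_epochs` epochs (default 50). The first five include
phase 1: `subepochs_per_epoch` (default 25, settable 0–25) sub-epochs,
each reading `lines_per_subepoch` (default 12 000) unlabelled lines
through a moving cursor that cycles at end of file. Every epoch then
makes one phase-2 pass over the training candidates. Batches group 32
sequences of adjacent lengths (sorted, chunked, padded per group) and
are visited in random order. After each epoch the development
candidates are scored with dropout off, tuple-level micro-P/R/F is
logged, and test predictions can be written; the epoch with the best
development F wins, ties to the earliest. All randomness flows from
one seed, so runs are exactly reproducible — a deliberate departure
from unseeded original practice, made configurable rather than hidden.

## Decision rules and evaluation

The default decision is the argmax of the six outputs (ties to the
lowest index, so exact ties conservatively favour NONE). The
thresholded rule computes `a = o_x`, `b = o_x − o_0` or
`c = o_x / o_0` (`+Inf` when `o_0 = 0`) and accepts the best positive
class when the statistic is *strictly* above the threshold. Fitting
searches all three formulas over the midpoints between consecutive
distinct statistic values observed on the development set (plus
sentinels beyond both extremes); since the objective only changes at
observed values, this grid is exact for the development set. Ties
break by formula order A, B, C, then lower threshold. With `b` and
threshold 0 the rule coincides with the argmax wherever the maximum is
unique, so the fitted rule can never fall below the argmax baseline on
the data it was fitted to.

Scoring deduplicates predictions to unique
`(doc, group, chemical, gene)` tuples — several mention pairs
expressing the same relation count once — while the confusion matrix
is per candidate. Percentages are reported to two decimals with
half-up rounding, matching how such tables are conventionally printed;
F is defined as 0 when precision + recall is 0.

## The synthetic corpus: what it emulates and what it does not

The generator emits abstracts built from template sentences: relation
sentences (`<CHEM> <trigger> <PROT>` with adverb/preamble variants),
non-relation co-occurrence sentences, and entity-free distractors.
Per-group trigger lexicons are pairwise disjoint and the configuration
enforces this, so the label is a deterministic function of the trigger
and an oracle reading only the trigger scores F = 100 — the point of
the design: end-to-end runs have a known ceiling, separating pipeline
bugs from modelling noise. Entity offsets are computed exactly and
pass strict verification; sentence-final periods are attached to the
preceding word so the tokenizer's stripping path is exercised inside
the pipeline. Every gold pair sits within one sentence, well inside
the 60-token window. Lexicons include multi-word proteins ("MAP
kinase") and bracketed chemicals ("(S)-ibuprofen") to exercise
multi-token masking and chemistry tokenization. Defaults: 25 chemicals,
25 proteins, 3–6 sentences per abstract, 25% non-relation
co-occurrence sentences, 20% distractors — roughly the entity density
of abstracts, chosen once.

Pre-training text comes from a first-order Markov grammar over the
same token inventory (~170 words), each token having three preferred
successors carrying 95% of the transition mass (60/25/10). The
concentration is deliberately strong so that a randomly substituted
token is statistically detectable from one neighbour — the phase-1
task is learnable at desk scale within few updates.

What passing these runs shows: candidate generation, masking,
features, batching, the shared-layer transfer, both losses, decision
rules and scoring are wired correctly, and the architecture can learn
a cleanly separable relation signal. What it does not show: performance
on real biomedical language — no anaphora, negation, coordination,
cross-sentence relations, annotation noise, or class imbalance of real
corpora; real-corpus scores require the external CHEMPROT data and
full-scale training.

## Desk-scale configuration

Synthetic runs use embedding 24, shared LSTMs 24 units, `l3` 16 units
per direction, 10 epochs with phase 1 in the first five (3 sub-epochs
of 500 lines each), 300 training and 60 development abstracts — sizes
at which a full run takes a few minutes on one CPU. A desk-scale
schedule takes two orders of magnitude fewer gradient updates than a
full-scale run, so `scaled_config()` raises the RMSProp learning rate
to 0.01; with the full-scale 0.001 the shortened schedule stops far
short of convergence. The topology is unchanged.

## Numerical choices and degenerate inputs

* Shift-introduced padding positions are excluded from the phase-1
  loss by a mask (one shared mask zeroing the first and last position
  of each example); including them would teach the network the pad
  symbol and nothing else. A length-1 line is fully masked.
* Padded batch positions are excluded from global max pooling; within
  length-grouped batches padding is minimal, and the reversed LSTM
  simply processes pads like tokens.
* The reversed LSTM re-reverses its outputs so position t aligns with
  position t of the input; this pairing is what lets `c2` compare the
  rightward context with the left-shifted sequence.
* Replacement flags record the substitution *event*: a position is a
  negative sample even if the sampled token equals the original.
* LSTM initialization: Glorot-uniform input kernels, block-orthogonal
  recurrent kernels, forget-gate bias 1. Dropout masks are drawn once
  per sequence and shared across timesteps (variational form).
* Division by zero in the `c` statistic yields `+Inf` (always
  accepted); empty prediction or gold sets score 0, not NaN.
* Multi-label candidate pairs resolve to the lowest-numbered group
  with a warning; the softmax is single-label and conflicts are rare
  corpus artifacts.
* The phase-1 loss averages (rather than sums) the two output losses;
  the choice is config-visible in the loss weights and only scales
  gradients by a constant.

## Known limitations

The tokenizer is an approximation to the original chemistry tokenizer,
not a port. One candidate instance is emitted per mention pair without
deduplication of repeated entity pairs. Per-class thresholds are not
supported (the rebalancing rule is global). The pure-R layers are fast
at desk scale but not suited to full-scale corpora; the architecture
ablations beyond the convolutional second stage are out of scope.
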