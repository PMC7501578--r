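---
title: "Lattice LSTM-CRF tagging with contextualized character embeddings: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice LSTM-CRF tagging: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeNER)
```

## The problem

Chinese clinical text has no word boundaries, and clinical entities (diseases,
drugs, anatomy, operations, imaging and laboratory items) are dense,
long, and full of domain terms that general-purpose segmenters break. A
character-level tagger sidesteps segmentation errors but discards word-level
evidence. The lattice architecture keeps the character sequence as the
labeling backbone while injecting the memory of every dictionary-matched
multi-character term at the position where that term ends, so the model can
exploit a clinical terminology lexicon without committing to a single
segmentation.

`latticeNER` implements that architecture end to end: BIO-tagged corpus I/O,
trie lexicon matching, a lattice LSTM encoder, a variant contextualized
character language model, an exact linear-chain CRF, per-sentence SGD
training, and strict entity-level evaluation, with a seeded synthetic-data
generator standing in for access-restricted clinical corpora.

## Model components and their assumptions

### Lattice encoder

The character path is a standard LSTM. A lexicon match `(b, e)` (0-based,
half-open; terms are at least two characters) spawns an *output-gate-free
word cell* from the hidden and cell state at the term's first character, and
delivers it to the character cell at the term's last character. At a merge
position the new cell value is a convex combination of the incoming word
cells and the character candidate `tanh` term; the combination weights are
an elementwise softmax over each word cell's combine-gate logit
`W^l [x_t ; c^w] + b^l` and the character input-gate logit. Three numerical
readings fixed here:

* **Biases sit inside the nonlinearity.** Writing the gate as
  `σ(Wz) + b` would produce unbounded "gates"; the implementation uses
  `σ(Wz + b)` throughout.
* **The combine gate carries a weight matrix.** A gate over the
  concatenation `[x_t ; c^w]` must project to the hidden dimension;
  `σ(W^l [x_t ; c^w] + b^l)` is the only dimensionally consistent form.
* **Normalization acts on the logits.** The merge weights are a softmax over
  the pre-sigmoid gate values, elementwise per hidden dimension. This
  satisfies the sum-to-one requirement, is monotone in the gate activations,
  and has clean gradients. At merge positions the forget path from
  `c_{t-1}` is not used — the cell is rebuilt entirely from word cells and
  the candidate — which is the defining recurrence of this model family.
  Positions with no incoming word cell use the plain LSTM update, so an
  empty lexicon reduces the encoder *exactly* to a character LSTM (this
  degeneracy is asserted to 1e-6 in the test suite).

The encoder runs bidirectionally by default with separate parameter sets,
mirroring the convention that every baseline of this model family is a
BiLSTM; the published architecture diagram draws a single direction and
never states the choice, so a unidirectional switch exists
(`ner_config(bidirectional = FALSE)`).

### Contextualized character embeddings

The language model is a two-layer bidirectional LSTM over characters. The
convolutional character encoder of the original contextual-embedding
architecture is removed: a 100-dim character embedding feeds the recurrent
layers directly, and each direction's layer output is projected to 50 dims,
so the token layer and both recurrent layers are all 100-dim per position.
The forward stream predicts each character from its left context and the
backward stream from its right context (sentinel BOS/EOS tokens are added
internally and stripped from representations); the vocabulary softmax is
shared between directions, halving output parameters. A full softmax is
used — the vocabulary is characters, so exactness costs little.

During tagger training the language model is frozen; only the scalar mixer
(`γ`, softmax-normalized layer weights `s`) trains jointly with the tagger.
Per-sentence layer stacks are precomputed once, which makes the frozen-body
choice essentially free at training time.

Unstated in the source architecture and therefore fixed here as defaults:
the pre-projection hidden size (100; any value works, the projection fixes
the interface), the pretraining optimizer (Adam, lr 5e-3, minibatch 32 —
chosen because batch-1 SGD is needlessly slow for a language model and the
pretraining stage is not part of the tagger's optimizer contract), and the
epoch count (caller-specified).

### CRF

Emissions are unnormalized logits from a linear projection of the encoder
hidden states — calling them "probabilities" would make global normalization
incoherent — plus a `(k+2) x (k+2)` transition matrix with explicit START
and STOP states (initialized at zero; transitions into START and out of
STOP are masked with a large negative constant, kept finite so log-sum-exp
never produces NaN). The partition function is computed by the forward
recursion in log space; gradients come from forward-backward marginals.
Viterbi decoding breaks ties toward the lowest label index, and by default
adds a hard mask of BIO-invalid transitions (`O -> I-X`, `B-X -> I-Y`, ...)
at decode time only — training stays unmasked, and the mask can never make a
schema-consistent gold path infeasible.

## Tunable parameters

Defaults are the study configuration; all are plain numbers in
`ner_config()`.

| Parameter | Default | Notes |
|---|---|---|
| `char_emb_size` | 100 | static character embedding dim |
| `elmo_emb_size` | 100 | contextual embedding dim (2 x 50 projections) |
| `word_emb_size` | 100 | lexicon-term embedding dim |
| `dropout` | 0.5 | inverted dropout on the concatenated input embedding, training only |
| `hidden` | 200 | recurrent size per direction |
| `lstm_layers` | 1 | encoder depth |
| `lr` | 0.015 | SGD step size |
| `lr_decay` | 0.05 | schedule `lr / (1 + decay * epoch)`, epoch 0-based |
| `epochs` | 10 | passes over the training corpus |
| `batch_size` | 1 | the lattice is computed per sentence, unbatched |
| `clip_norm` | 50 | global gradient-norm bound |

Two of these deserve justification:

* **The decay formula.** Only a rate and a decay constant are named by the
  study; `lr0 / (1 + decay * epoch)` is the schedule used throughout this
  model family's reference implementations and reproduces the stated
  values at epoch 0.
* **`clip_norm = 50`, not 5.** Measured per-sentence gradient norms of the
  full weight tree sit between 15 and 50 at initialization. A bound of 5
  would rescale essentially every update, silently dividing the stated
  learning rate by a factor of 3–10; 50 clips only genuine outliers while
  leaving the optimizer at its nominal step size. Dropout applies to input
  embeddings only, not hidden states — the conservative reading of a single
  stated rate.

Initialization: Glorot-uniform gate matrices, zero biases except forget-gate
biases at 1 (the standard remedy for vanishing memory early in training),
zero transition matrix, zero mixer logits (uniform layer weights) with
`γ = 1`. Out-of-vocabulary tokens resolve to a seeded UNK row drawn
uniformly from `[-0.5/dim, 0.5/dim]`, the word2vec convention, and are
reproducible across runs.

## The synthetic-data generator

`fixture_config()` / `generate_study()` emulate the structural skeleton of
clinical NER corpora: a fixed category set (six by default, mirroring the
disease / image / laboratory / operation / drug / anatomy roles), sentences
bounded at 200 characters, entities inserted at a Poisson rate
(`entity_density`, default 1.5 per sentence) that are *exactly* lexicon
terms — so a lattice word path exists for every gold entity — and an
`ambiguity_rate` controlling both how often lexicon terms share character
bigrams with each other and how often filler characters are drawn from the
characters inside entity terms. Ambiguity is the property the lattice is
designed to exploit: when filler text looks locally like term fragments, a
character-only model has no cheap boundary cue, while the lattice path marks
every true term explicitly. Synthetic characters come from the Unicode
private-use block so no accidental linguistic semantics leak in; embedding
tables are seeded Gaussians with entry scale 0.5, roughly the scale of
trained word2vec vectors. Everything is a pure function of the config seed.

What the generator does **not** model: real Chinese clinical language,
mixed alphanumeric laboratory entities, inter-annotator noise, or realistic
label imbalance. Passing tests on this generator demonstrates that the
machinery — matching, encoding, inference, training dynamics, evaluation —
is correct and that the lexicon signal is exploitable; it says nothing about
F1 on actual clinical corpora, which are access-restricted and out of scope.

`generate_lm_corpus()` is a separate, deliberately low-entropy corpus for
language-model benchmarking: sentences drawn from a handful of fixed
patterns. A corpus of random sentences has an intrinsic per-token
cross-entropy floor (each direction must guess which sentence it is in
before seeing any of it, contributing about
`2 log(n_patterns) / (pattern_len + 1)` nats per token), so memorization
targets are only meaningful against a corpus whose floor is well below the
target. With 3 patterns of 30 characters the floor is about 0.07 nats; the
benchmark target of 0.1 sits just above it.

## Problem sizes used by the shipped benchmarks

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen once: 200 sentences / 3 categories / density 1.5 for the
overfitting benchmark (training-set F1 reaches 100 within 30 epochs at the
default hyperparameters); 50 sentences / 200 epochs for language-model
memorization; 80 training and 40 test sentences at ambiguity 0.5, five
seeded runs per configuration, for the lexicon-benefit comparison (the test
asserts that the mean strict F1 of the lattice configuration exceeds the
character-only configuration; the acceptance script reports the measured
gain on its own split); and 150/50 sentences for the acceptance script's
end-to-end numbers. The
language-model used in these benchmarks runs with a pre-projection hidden
size of 64 — the projection interface, not the hidden size, fixes the
architecture, and the benchmark measures memorization, not capacity limits.

## Known limitations

* Batch size is fixed at 1 for the tagger (the lattice recurrence is
  inherently per-sentence here); the language model batches internally.
* Pure-R execution: fine at the benchmark scales above, not engineered for
  the multi-thousand-sentence corpora of the original studies.
* BIO only (no BIOES), strict matching only (no relaxed/overlap credit),
  first-order CRF only.
* The character repair policy on malformed BIO input (`I-X` after `O`
  becomes `B-X`) preserves entity mass but invents a boundary; evaluator
  and reader share the same policy so scores stay consistent.
* No fuzzy lexicon matching: orthographic variants of the same clinical
  term (e.g. 黏膜 vs 粘膜) are distinct strings and no normalization is
  applied.
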