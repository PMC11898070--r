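---
title: "Retrieval-augmented multi-window convolutional peptide classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-augmented multi-window convolutional peptide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragmcnn)
```

## The problem and the model

Interleukin-6 (IL-6) is a cytokine central to inflammation; peptides that
trigger its production are of direct interest for vaccine safety and
immunotherapy design. `ragmcnn` frames their recognition as binary sequence
classification over per-residue embeddings from a protein language model
(PLM): a peptide of length $L$ becomes an $L \times D$ real matrix
(one $D$-dimensional vector per residue, $D = 1024$ for ProtTrans-scale
models), zero-padded on the C-terminal side to a fixed $L_{pad}$ rows.

Classification happens in three stages.

**Retrieval-augmented enrichment.** A labeled reference collection of
peptides is indexed as a vector store: each entry keeps its padded
embedding matrix and the masked mean over its true-length rows as a
sequence-level "pooled" vector. For a query, the $k = 5$ stored peptides
with the smallest cosine distance between pooled vectors are retrieved,
their padded matrices averaged element-wise, and the average fused with the
query matrix as

$$X_{fused} = \frac{a\,X_{query} + b\,\bar{X}_{retrieved}}{a + b},$$

with equal weights $a = b = 1$ by default, so the unique features of the
query and the contextual signal of its neighborhood contribute equally.
Setting $b = 0$ recovers the plain, retrieval-free pipeline.

**Multi-window convolution.** The fused matrix is scanned by parallel 1-D
convolutions along the sequence axis, one per window size
$w \in \{2, 4, 16, 24, 32, 34\}$, each with 512 filters spanning all $D$
channels. Each filter's rectified response profile is reduced by a global
maximum over positions to a single value — the strongest match of that
filter's pattern anywhere in the peptide — and the per-window outputs are
concatenated into a $6 \times 512 = 3072$-long feature vector feeding a
sigmoid output unit. Small windows capture local motifs, large windows
near-global patterns; global max pooling makes each filter a
position-invariant motif detector.

**Evaluation.** Sensitivity, specificity, accuracy, balanced accuracy
(BACC, the mean of sensitivity and specificity), the Matthews correlation
coefficient (MCC) and the rank-based ROC-AUC, under stratified $k$-fold
cross-validation with predictions pooled across folds.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `dim` ($D$) | 1024 | per-residue embedding width; any PLM obeying the adapter contract works |
| `padded_length` ($L_{pad}$) | 40 residues | must be at least the largest window (34); the padding scheme (C-terminal zeros, truncate-with-warning beyond) is this package's choice, as is the value 40 |
| `window_sizes` | 2, 4, 16, 24, 32, 34 | the selected multi-window combination |
| `n_filters` | 512 | the selected filter count |
| `k` | 5 | neighbors retrieved |
| ratio $a{:}b$ | 1:1 | fusion weights; only the ratio matters (scaling both leaves the result unchanged) |
| distance | cosine | on mean-pooled vectors; Euclidean available. The sequence-level representation used for retrieval (masked mean pooling) is this package's choice and is configurable |
| threshold | 0.5 | score cutoff for confusion matrices |

Training hyperparameters (all in `train_config()`) are package decisions,
stated explicitly because no part of the architecture fixes them: binary
cross-entropy, Adam at learning rate $10^{-3}$, batch 32, up to 30 epochs,
early stopping on a 10% stratified validation split with patience 5, class
weighting off by default and available as `"balanced"` for skewed
collections. The seed fully determines initialization, the validation
split and batch order, so training is bitwise reproducible.

## Design choices where the design was open

* **Self-exclusion during retrieval.** A training query that also sits in
  the store would retrieve itself, making fusion partially a no-op and
  leaking its own label context. Store entries with a sequence identical
  to the query are therefore skipped by default (`exclude_self`), and
  cross-validation rebuilds the store from the training folds only, so a
  held-out peptide never queries a store that contains it.
* **Label-blind retrieval.** Neighbors are retrieved from the whole store
  regardless of class; restricting retrieval by label would presuppose the
  label being predicted.
* **Variable-length averaging.** Neighbor matrices are averaged on the
  common padded grid, zeros included beyond each neighbor's true length —
  the only shape-preserving option that needs no alignment step. The
  average's true length is the maximum neighbor true length; fusion keeps
  the query's.
* **Ties.** Equal retrieval distances resolve by store insertion order;
  equal max-pool responses resolve to the earliest position; tied scores
  contribute one half to the AUC (midranks). All three are deterministic.
* **Undefined metrics.** A zero denominator (e.g. sensitivity of an
  all-negative fold) yields `NA` plus an `undefined` flag, never a silent 0.
* **Report rounding.** Tables are rounded half away from zero at 4
  decimals. In a rounded report, BACC is recomputed as the mean of the
  rounded sensitivity and specificity — the convention of published
  performance tables, which keeps every printed row internally consistent.
* **CV summary.** Predictions are pooled across folds before computing
  the summary metrics; per-fold averaging is available via `pool = FALSE`.

## The synthetic data generator

`generate_synthetic_dataset()` emulates a labeled peptide collection with
a planted-motif class signal: negatives are i.i.d. uniform over the 20
canonical residues, positives additionally carry a fixed motif written
over the residues at a uniform offset with probability `motif_prob`, so
the length distribution is identical across classes and the only class
signal is the motif. The default length range 8–35 reflects typical
epitope lengths and keeps every sequence beneath the default padded
length. The companion synthetic embedder is a deterministic per-residue
lookup (21 seeded standard-normal vectors, one per canonical residue plus
an unknown token): no context mixing, which is exactly enough for
convolution windows to detect planted motifs while keeping every test
reproducible without pretrained weights.

What the generator does *not* emulate: real epitope composition biases,
homology structure between related peptides, PLM context dependence
(real embeddings of the same residue differ across contexts), and real
class overlap. Passing tests on synthetic data therefore demonstrate that
the machinery — retrieval, fusion, convolution, optimization, evaluation —
behaves as specified, not that any particular real-data performance level
will be reached.

## Numerical and testing choices

Problem sizes in the test suite are deliberately desk-scale (embedding
dims 6–16, 8–16 filters, a few hundred peptides), chosen so the whole
suite re-derives its expectations from independent oracles — brute-force
neighbor sorts, exhaustive AUC pair counting, exact motif-containment
probabilities via a KMP-automaton Markov chain — in well under a minute.
The end-to-end learnability check runs 5-fold cross-validation on a
200 + 200 planted-motif set and requires pooled AUC at or above 0.95.

The retrieval-benefit check uses a fixture constructed so that neighbors
carry label-informative signal: positives are residue-composition shifted
(tryptophan upweighted) rather than motif-marked. Mean-pool retrieval
sees composition directly, while a max-pooled convolution is a weak
composition counter (it detects presence, not abundance), so averaging
five retrieved neighbors injects a denoised, class-correlated signal into
every row of the fused matrix — and the 1:1-fused pipeline must score at
least as high an AUC as the retrieval-free one.

## Known limitations

* Training is plain R linear algebra: ideal for desk-scale studies and
  ablations; training at full published scale (1024-dim embeddings, 512
  filters, thousands of peptides) is possible but slow, and a GPU backend
  is out of scope.
* The store uses exact search; collections far beyond $10^4$ entries
  would want approximate indexing, which is deliberately not included.
* Real PLM embedders are attached through the adapter contract
  (`sequence in, L x D matrix out`); none are bundled, and published
  benchmark numbers that depend on them and on external databases are not
  reproduced here — the harness reproduces the protocol, and the
  published confusion-matrix arithmetic is verified exactly from the
  printed rates and class sizes.
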