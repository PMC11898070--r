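# ragmcnn

Retrieval-augmented multi-window convolutional classification of
cytokine-inducing peptides.

## What it is for

Peptides that induce interleukin-6 (IL-6) drive inflammatory responses
relevant to vaccine safety and immunotherapy. `ragmcnn` is an R toolkit for
predicting IL-6-inducing peptides from per-residue protein language model
(PLM) embeddings, aimed at computational immunologists who want the full
pipeline — retrieval database, classifier, evaluation harness, ablations —
reproducible on one CPU.

The method, in the field's standard notation: a peptide of length *L* is
embedded as an *L* × *D* matrix (*D* = 1024 per residue for
ProtTrans-scale models), zero-padded to *L*<sub>pad</sub> rows. The query
is enriched by retrieval-augmented fusion: the *k* = 5 stored peptides
with the smallest cosine distance between masked mean-pooled vectors are
retrieved and their matrices averaged, then

X<sub>fused</sub> = (a·X<sub>query</sub> + b·X̄<sub>retrieved</sub>) / (a + b),  a : b = 1 : 1 by default.

The fused matrix is scanned by parallel 1-D convolutions with window sizes
{2, 4, 16, 24, 32, 34} × 512 filters, each filter globally max-pooled to a
single value, concatenated (6 × 512 = 3072 features) into a sigmoid unit.
Performance is reported as sensitivity, specificity, accuracy, balanced
accuracy BACC = (Sn + Sp)/2, Matthews correlation coefficient

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

and rank-based ROC-AUC, under stratified 5-fold cross-validation.

A deterministic synthetic embedder (seeded per-residue lookup) and a
planted-motif dataset generator make every stage testable without
pretrained weights; real PLMs plug in through the adapter contract of
`embedder_config()` (sequence string in, *L* × *D* matrix out).

## Worked example

Build a reference store from a synthetic planted-motif collection, then
cross-validate the retrieval-augmented classifier:

```r
library(ragmcnn)

db <- generate_synthetic_dataset(n_pos = 150, n_neg = 150,
                                 length_range = c(8, 20),
                                 motif = "WWHGA", motif_prob = 1, seed = 42,
                                 name = "reference")
embedder <- embedder_config(dim = 16, padded_length = 20, seed = 1)
store <- build_store(db, embedder)
store
#> <rag_store: 300 entries, dim 16, padded_length 20, backend 'synthetic'>

cv <- run_cross_validation(
  manifest  = db, embedder = embedder,
  fusion    = fusion_config(k = 5, ratio_query = 1, ratio_retrieved = 1),
  model_cfg = mcnn_config(window_sizes = c(2, 5, 8), n_filters = 16,
                          padded_length = 20, dim = 16, seed = 1),
  tcfg      = train_config(epochs = 12, seed = 1),
  k = 5, seed = 1)
cv$summary
#> <metric_report: BACC 0.9367 | sens 0.9733 | spec 0.9 | ACC 0.9367 | MCC 0.8757 | AUC 0.9822>
```

The pooled 5-fold report says the classifier recovered 97.3% of motif
carriers (sensitivity) at 90% specificity; the AUC of 0.982 means a
randomly chosen positive outscores a randomly chosen negative 98.2% of the
time. Because the only class signal is the planted 5-mer, this confirms the
max-pooled convolution windows act as position-invariant motif detectors.

Metric arithmetic works directly from printed rates too — reconstructing a
confusion matrix from a published sensitivity/specificity pair with the
known class sizes (73 positives, 598 negatives):

```r
counts <- reconstruct_confusion(0.7808, 0.9365, n_pos = 73, n_neg = 598)
unlist(counts)
#>  TP  FP  TN  FN
#>  57  38 560  16
round_report(metrics_from_confusion(counts))
#> <metric_report: BACC 0.8587 | sens 0.7808 | spec 0.9365 | ACC 0.9195 | MCC 0.6407 | AUC NA>
```

## Command line

Every stage is exposed as a subcommand of the installed script
(`system.file("cli", "ragmcnn.R", package = "ragmcnn")`): `simulate`,
`build-db`, `augment`, `train`, `predict`, `evaluate`, `cv`, `ablate` —
all accept `--seed` and a YAML `--config`; identical seeds and configs
give byte-identical outputs. For example, the published-style fusion-ratio
ablation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ragmcnn.R",package="ragmcnn"))')" \
  ablate --input train.csv --axis ratio --values 1:1,1:2,1:5,2:1,5:1 \
  --out ratio_table.csv --seed 7
```

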