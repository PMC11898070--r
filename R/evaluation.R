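# Confusion-matrix metrics, ROC-AUC, confusion reconstruction from printed
# rates, stratified k-fold cross-validation, and ablation sweeps.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integers.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  vals <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop_user("confusion counts must be non-negative integers")
  }
  structure(as.list(vals), class = "confusion_counts")
}

#' Confusion counts from scores and labels
#'
#' @param labels binary vector.
#' @param scores numeric scores.
#' @param threshold call positive when `score >= threshold` (default 0.5).
#' @return a [confusion_counts()] object.
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= threshold)
  confusion_counts(tp = sum(pred == 1 & labels == 1),
                   fp = sum(pred == 1 & labels == 0),
                   tn = sum(pred == 0 & labels == 0),
                   fn = sum(pred == 0 & labels == 1))
}

#' Metrics from a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N`, balanced accuracy `(sensitivity+specificity)/2`, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' all at full precision. A metric whose denominator is zero is reported
#' as `NA` and listed in the report's `undefined` field — never silently
#' coerced to 0.
#'
#' @param counts a [confusion_counts()] object.
#' @param auc optional ROC-AUC to carry alongside (see [roc_auc()]).
#' @return a `metric_report`: list with `sensitivity`, `specificity`,
#'   `accuracy`, `bacc`, `mcc`, `auc`, `counts`, `undefined`.
#' @export
metrics_from_confusion <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  acc <- safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  bacc <- if (anyNA(c(sens, spec))) {
    undefined <- c(undefined, "bacc")
    NA_real_
  } else {
    (sens + spec) / 2
  }
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    undefined <- c(undefined, "mcc")
    NA_real_
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }
  structure(
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         bacc = bacc, mcc = mcc, auc = auc, counts = counts,
         undefined = unique(undefined)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  r <- round_report(x, digits)
  cat(sprintf(
    "<metric_report: BACC %s | sens %s | spec %s | ACC %s | MCC %s | AUC %s>\n",
    format(r$bacc), format(r$sensitivity), format(r$specificity),
    format(r$accuracy), format(r$mcc), format(r$auc)))
  if (length(x$undefined) > 0) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Round a metric report to table precision
#'
#' Rounds half away from zero to `digits` decimals. Balanced accuracy in
#' the rounded report is recomputed as the mean of the *rounded*
#' sensitivity and specificity — the convention of published performance
#' tables, which keeps the rounded report self-consistent (the mean of
#' the two printed rates is exactly the printed BACC).
#'
#' @param report a `metric_report`.
#' @param digits decimal places (default 4, typical table precision).
#' @return the report with rounded metric fields.
#' @export
round_report <- function(report, digits = 4) {
  out <- report
  for (f in c("sensitivity", "specificity", "accuracy", "mcc", "auc")) {
    if (!is.na(out[[f]])) out[[f]] <- round_half_up(out[[f]], digits)
  }
  if (!anyNA(c(out$sensitivity, out$specificity))) {
    out$bacc <- round_half_up((out$sensitivity + out$specificity) / 2, digits)
  }
  out
}

#' Reconstruct confusion counts from printed rates
#'
#' Validation utility binding printed sensitivity/specificity to known
#' class sizes: `TP = round(sensitivity * n_pos)`,
#' `TN = round(specificity * n_neg)`, complements for FN/FP. Fails
#' loudly when the rounded counts cannot reproduce the stated rates to
#' within `tol` — i.e. the inputs are mutually inconsistent.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg class sizes.
#' @param tol maximum allowed `|TP/n_pos - sensitivity|` (and the
#'   specificity analogue) after rounding; default 1e-4.
#' @return a [confusion_counts()] object.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg,
                                  tol = 1e-4) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
            n_pos >= 1, n_neg >= 1)
  tp <- round_half_up(sensitivity * n_pos, 0)
  tn <- round_half_up(specificity * n_neg, 0)
  if (abs(tp / n_pos - sensitivity) > tol) {
    stop_user(sprintf(
      "inconsistent inputs: sensitivity %.6f with %d positives implies TP %.4f, not an integer within %g",
      sensitivity, n_pos, sensitivity * n_pos, tol))
  }
  if (abs(tn / n_neg - specificity) > tol) {
    stop_user(sprintf(
      "inconsistent inputs: specificity %.6f with %d negatives implies TN %.4f, not an integer within %g",
      specificity, n_neg, specificity * n_neg, tol))
  }
  confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' ROC-AUC by the midrank statistic
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, ties counted half — computed from midranks
#' (Mann-Whitney), so it equals exhaustive pair counting exactly.
#'
#' @param labels binary vector (both classes required).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop_user("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class with the seeded generator and splits it into k
#' near-equal contiguous chunks, so every fold's positive count is within
#' one example of perfect stratification. Deterministic in `seed`.
#'
#' @param labels binary vector.
#' @param k number of folds (>= 2); each class must have at least k
#'   members.
#' @param seed integer seed.
#' @return list of k integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  labels <- as.integer(labels)
  for (cls in unique(labels)) {
    if (sum(labels == cls) < k) {
      stop_user("class ", cls, " has fewer than k = ", k, " members")
    }
  }
  with_seed(seed, {
    folds <- rep(list(integer(0)), k)
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      bounds <- floor(seq(0, length(idx), length.out = k + 1))
      for (j in seq_len(k)) {
        if (bounds[j + 1] > bounds[j]) {
          folds[[j]] <- c(folds[[j]], idx[(bounds[j] + 1):bounds[j + 1]])
        }
      }
    }
    lapply(folds, sort)
  })
}

#' End-to-end stratified cross-validation of the retrieval-augmented model
#'
#' For each fold: the retrieval store is rebuilt from the training folds
#' only (held-out peptides never sit in the store they query), training
#' inputs are retrieval-augmented with self-exclusion, a fresh model is
#' trained, and the held-out fold is scored. Predictions are pooled
#' across folds for the summary report by default; per-fold averaging of
#' metrics is available via `pool = FALSE`.
#'
#' @param manifest a labeled [peptide_manifest()].
#' @param embedder an [embedder_config()].
#' @param fusion a [fusion_config()].
#' @param model_cfg an [mcnn_config()].
#' @param tcfg a [train_config()].
#' @param k number of folds.
#' @param seed seed for fold assignment and per-fold training (fold i
#'   trains with `seed + i`).
#' @param pool pool predictions before computing the summary (default)
#'   or average per-fold metrics.
#' @return list with `summary` (a `metric_report`), `folds` (per-fold
#'   reports), and `predictions` (data.frame `id`, `label`, `score`,
#'   `fold`, in manifest order).
#' @export
run_cross_validation <- function(manifest, embedder, fusion = fusion_config(),
                                 model_cfg, tcfg = train_config(),
                                 k = 5L, seed = 0L, pool = TRUE) {
  stopifnot(inherits(manifest, "peptide_manifest"))
  labels <- manifest$peptides$label
  if (anyNA(labels)) stop_user("cross-validation requires fully labeled data")
  embeddings <- embed_dataset(manifest, embedder)
  folds <- stratified_kfold(labels, k = k, seed = seed)
  n <- length(labels)
  scores <- rep(NA_real_, n)
  fold_of <- integer(n)
  fold_reports <- vector("list", k)

  for (j in seq_len(k)) {
    test_idx <- folds[[j]]
    train_idx <- setdiff(seq_len(n), test_idx)
    train_manifest <- peptide_manifest(manifest$peptides[train_idx, ],
                                       name = paste0(manifest$name, "-fold", j))
    store <- build_store(train_manifest, embedder)
    train_inputs <- augment_dataset(train_manifest, store, embedder, fusion,
                                    embeddings = embeddings[train_idx])
    test_manifest <- peptide_manifest(manifest$peptides[test_idx, ],
                                      name = paste0(manifest$name, "-test", j))
    test_inputs <- augment_dataset(test_manifest, store, embedder, fusion,
                                   embeddings = embeddings[test_idx])
    model_j <- model_cfg
    model_j$seed <- model_cfg$seed + j
    tcfg_j <- tcfg
    tcfg_j$seed <- tcfg$seed + j
    model <- train_mcnn(build_mcnn(model_j), train_inputs, labels[train_idx], tcfg_j)
    scores[test_idx] <- predict_scores(model, test_inputs)
    fold_of[test_idx] <- j
    fold_reports[[j]] <- metrics_from_confusion(
      confusion_from_scores(labels[test_idx], scores[test_idx], model_cfg$threshold),
      auc = roc_auc(labels[test_idx], scores[test_idx])
    )
  }

  summary <- if (pool) {
    metrics_from_confusion(
      confusion_from_scores(labels, scores, model_cfg$threshold),
      auc = roc_auc(labels, scores)
    )
  } else {
    avg <- function(f) mean(vapply(fold_reports, function(r) r[[f]], numeric(1)))
    structure(
      list(sensitivity = avg("sensitivity"), specificity = avg("specificity"),
           accuracy = avg("accuracy"), bacc = avg("bacc"), mcc = avg("mcc"),
           auc = avg("auc"), counts = NULL, undefined = character(0)),
      class = "metric_report"
    )
  }
  list(summary = summary, folds = fold_reports,
       predictions = data.frame(id = manifest$peptides$id, label = labels,
                                score = scores, fold = fold_of))
}

#' Ablation sweeps over window sizes, filter counts, and fusion ratios
#'
#' Re-runs cross-validation once per value of the chosen axis and emits
#' one metric row per value, mirroring published ablation-table layout:
#'
#' * `window_single` — a single convolution window per run.
#' * `window_combo` — a list of window-size vectors, one combination per
#'   run.
#' * `filters` — filter counts.
#' * `ratio` — fusion ratio strings such as `"1:1"`, `"1:5"`, `"2:1"`.
#'
#' @param axis one of `"window_single"`, `"window_combo"`, `"filters"`,
#'   `"ratio"`.
#' @param values vector (or list, for `window_combo`) of axis values.
#' @param manifest labeled [peptide_manifest()].
#' @param embedder,fusion,model_cfg,tcfg base configurations; the swept
#'   axis overrides the corresponding field per run.
#' @param k,seed,pool passed to [run_cross_validation()].
#' @return data.frame: `value` plus rounded `bacc`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `auc` (4 d.p., half-up).
#' @export
ablation_sweep <- function(axis = c("window_single", "window_combo", "filters", "ratio"),
                           values, manifest, embedder,
                           fusion = fusion_config(), model_cfg,
                           tcfg = train_config(), k = 5L, seed = 0L,
                           pool = TRUE) {
  axis <- match.arg(axis)
  if (length(values) == 0) stop_user("no values supplied for the sweep")
  rows <- lapply(seq_along(values), function(i) {
    v <- if (is.list(values)) values[[i]] else values[i]
    fus <- fusion
    mdl <- model_cfg
    label <- as.character(v)[1]
    if (axis == "window_single") {
      if (!is.numeric(v) || length(v) != 1 || v < 1) stop_user("invalid single window: ", label)
      mdl <- mcnn_config(window_sizes = as.integer(v), n_filters = model_cfg$n_filters,
                         padded_length = model_cfg$padded_length, dim = model_cfg$dim,
                         threshold = model_cfg$threshold, seed = model_cfg$seed)
    } else if (axis == "window_combo") {
      mdl <- mcnn_config(window_sizes = as.integer(v), n_filters = model_cfg$n_filters,
                         padded_length = model_cfg$padded_length, dim = model_cfg$dim,
                         threshold = model_cfg$threshold, seed = model_cfg$seed)
      label <- paste0("[", paste(v, collapse = ", "), "]")
    } else if (axis == "filters") {
      if (!is.numeric(v) || length(v) != 1 || v < 1) stop_user("invalid filter count: ", label)
      mdl <- mcnn_config(window_sizes = model_cfg$window_sizes, n_filters = as.integer(v),
                         padded_length = model_cfg$padded_length, dim = model_cfg$dim,
                         threshold = model_cfg$threshold, seed = model_cfg$seed)
    } else {
      w <- parse_ratio(v)
      fus <- fusion_config(k = fusion$k, ratio_query = w[["ratio_query"]],
                           ratio_retrieved = w[["ratio_retrieved"]],
                           metric = fusion$metric, exclude_self = fusion$exclude_self)
    }
    cv <- run_cross_validation(manifest, embedder, fus, mdl, tcfg,
                               k = k, seed = seed, pool = pool)
    r <- round_report(cv$summary, 4)
    data.frame(value = label, bacc = r$bacc, sensitivity = r$sensitivity,
               specificity = r$specificity, accuracy = r$accuracy,
               mcc = r$mcc, auc = r$auc)
  })
  do.call(rbind, rows)
}
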