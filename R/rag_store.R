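# Retrieval database: build, persist, query top-k neighbors, average
# their embeddings, and fuse with the query at a configurable ratio.

#' Fusion / retrieval configuration
#'
#' Controls neighbor retrieval and embedding fusion. The default is the
#' method's standard setting: the five most similar stored peptides are
#' retrieved by cosine distance between mean-pooled vectors, their padded
#' embedding matrices averaged, and the average fused with the query
#' embedding at a 1:1 weighting ratio.
#'
#' @param k neighbor count (>= 1).
#' @param ratio_query,ratio_retrieved non-negative fusion weights `a` and
#'   `b`; the fused matrix is `(a * query + b * retrieved) / (a + b)`.
#'   `a = b = 1` is the equal-weight default; `b = 0` disables retrieval.
#' @param metric `"cosine"` (default; standard for language-model
#'   embeddings) or `"euclidean"`, on mean-pooled vectors.
#' @param exclude_self skip store entries whose sequence is identical to
#'   the query's. On by default: a training-set query that sits in the
#'   store would otherwise retrieve itself and leak its own context.
#' @return a `fusion_config` object.
#' @export
fusion_config <- function(k = 5L, ratio_query = 1, ratio_retrieved = 1,
                          metric = c("cosine", "euclidean"),
                          exclude_self = TRUE) {
  metric <- match.arg(metric)
  stopifnot(k >= 1, ratio_query >= 0, ratio_retrieved >= 0)
  if (ratio_query + ratio_retrieved <= 0) stop_user("ratio weights must not both be zero")
  structure(
    list(k = as.integer(k), ratio_query = ratio_query,
         ratio_retrieved = ratio_retrieved, metric = metric,
         exclude_self = isTRUE(exclude_self)),
    class = "fusion_config"
  )
}

#' Parse a fusion ratio string
#'
#' Converts `"a:b"` (e.g. `"1:1"`, `"1:5"`, `"2:1"`) into the two
#' numeric fusion weights.
#'
#' @param ratio string `"a:b"` with non-negative numbers.
#' @return numeric vector `c(ratio_query, ratio_retrieved)`.
#' @export
parse_ratio <- function(ratio) {
  parts <- strsplit(ratio, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_user("invalid ratio '", ratio, "' (expected 'a:b')")
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || any(vals < 0) || sum(vals) <= 0) {
    stop_user("invalid ratio '", ratio, "'")
  }
  stats::setNames(vals, c("ratio_query", "ratio_retrieved"))
}

#' Build a retrieval store from a labeled manifest
#'
#' Embeds every peptide, mean-pools each matrix, and indexes the results
#' for exact top-k similarity search. Insertion order is manifest order
#' and is preserved (it is the documented tie-break for equal distances).
#'
#' @param manifest a [peptide_manifest()].
#' @param config an [embedder_config()].
#' @return a `rag_store`: ids, sequences, labels, an n x dim matrix of
#'   pooled vectors, the per-peptide embedding matrices, and the embedder
#'   geometry (`dim`, `padded_length`).
#' @export
build_store <- function(manifest, config) {
  stopifnot(inherits(manifest, "peptide_manifest"))
  if (nrow(manifest$peptides) == 0) stop_user("cannot build a store from an empty manifest")
  emb <- embed_dataset(manifest, config)
  pooled <- t(vapply(emb, function(e) mean_pool(e)$values, numeric(config$dim)))
  structure(
    list(
      ids = manifest$peptides$id,
      sequences = manifest$peptides$sequence,
      labels = manifest$peptides$label,
      pooled = pooled,
      matrices = lapply(emb, function(e) e$values),
      true_lengths = vapply(emb, function(e) e$true_length, integer(1)),
      dim = config$dim,
      padded_length = config$padded_length,
      embedder = list(backend = config$backend, seed = config$seed)
    ),
    class = "rag_store"
  )
}

#' @export
print.rag_store <- function(x, ...) {
  cat(sprintf("<rag_store: %d entries, dim %d, padded_length %d, backend '%s'>\n",
              length(x$ids), x$dim, x$padded_length, x$embedder$backend))
  invisible(x)
}

#' Persist a retrieval store
#'
#' Writes a JSON manifest (ids, sequences, labels, true lengths,
#' geometry, embedder provenance) plus a dense little-endian double
#' array holding the pooled vectors followed by the embedding matrices,
#' in insertion order, column-major. The round trip is lossless.
#'
#' @param store a `rag_store`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_store <- function(store, dir) {
  stopifnot(inherits(store, "rag_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "ragmcnn-store-v1",
    ids = store$ids, sequences = store$sequences,
    labels = store$labels, true_lengths = unname(store$true_lengths),
    dim = store$dim, padded_length = store$padded_length,
    embedder = store$embedder
  )
  jsonlite::write_json(meta, file.path(dir, "store.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  con <- file(file.path(dir, "store.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(store$pooled), con, size = 8, endian = "little")
  for (m in store$matrices) writeBin(as.numeric(m), con, size = 8, endian = "little")
  invisible(dir)
}

#' Load a persisted retrieval store
#'
#' @param dir directory written by [save_store()].
#' @return a `rag_store`.
#' @export
load_store <- function(dir) {
  meta_path <- file.path(dir, "store.json")
  if (!file.exists(meta_path)) stop_user("no store found in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "ragmcnn-store-v1")) stop_user("unrecognized store format")
  n <- length(meta$ids)
  d <- as.integer(meta$dim)
  lp <- as.integer(meta$padded_length)
  con <- file(file.path(dir, "store.bin"), "rb")
  on.exit(close(con))
  pooled <- matrix(readBin(con, "numeric", n * d, size = 8, endian = "little"),
                   nrow = n, ncol = d)
  rownames(pooled) <- meta$ids
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    mats[[i]] <- matrix(readBin(con, "numeric", lp * d, size = 8, endian = "little"),
                        nrow = lp, ncol = d)
  }
  names(mats) <- meta$ids
  labels <- meta$labels
  labels <- if (is.null(labels)) rep(NA_integer_, n) else as.integer(labels)
  structure(
    list(ids = meta$ids, sequences = meta$sequences, labels = labels,
         pooled = pooled, matrices = mats,
         true_lengths = stats::setNames(as.integer(meta$true_lengths), meta$ids),
         dim = d, padded_length = lp,
         embedder = list(backend = meta$embedder$backend,
                         seed = as.integer(meta$embedder$seed))),
    class = "rag_store"
  )
}

cosine_distance <- function(pooled, q) {
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(pooled^2))
  sim <- as.numeric(pooled %*% q)
  denom <- rn * qn
  sim <- ifelse(denom > 0, sim / denom, 0) # zero vectors: similarity 0 by convention
  1 - sim
}

#' Retrieve the top-k most similar stored peptides
#'
#' Exact search: distances from the query's pooled vector to every
#' eligible store entry, sorted ascending; ties broken by store insertion
#' order. Returns fewer than `k` neighbors (with a warning) only when the
#' eligible store is smaller than `k`.
#'
#' @param store a `rag_store`.
#' @param query a `pooled_vector` (from [mean_pool()]) or a plain numeric
#'   vector of length `store$dim`.
#' @param config a [fusion_config()].
#' @param query_sequence the query's residue string; needed for
#'   self-exclusion (entries with an identical sequence are skipped when
#'   `config$exclude_self`).
#' @return a `neighbor_set` data.frame: `peptide_id`, `index` (store
#'   position), `distance`, non-decreasing.
#' @export
retrieve_top_k <- function(store, query, config = fusion_config(),
                           query_sequence = NULL) {
  stopifnot(inherits(store, "rag_store"))
  q <- if (inherits(query, "pooled_vector")) query$values else as.numeric(query)
  if (length(q) != store$dim) stop_user("query dim ", length(q), " != store dim ", store$dim)
  eligible <- seq_along(store$ids)
  if (config$exclude_self && !is.null(query_sequence)) {
    eligible <- eligible[store$sequences != query_sequence]
  }
  if (length(eligible) == 0) stop_user("no eligible store entries for retrieval")
  d <- switch(config$metric,
    cosine = cosine_distance(store$pooled[eligible, , drop = FALSE], q),
    euclidean = sqrt(rowSums(sweep(store$pooled[eligible, , drop = FALSE], 2, q)^2))
  )
  if (length(eligible) < config$k) {
    warning(sprintf("only %d eligible entries for k = %d", length(eligible), config$k))
  }
  take <- order(d)[seq_len(min(config$k, length(eligible)))] # order() is stable: insertion-order ties
  structure(
    data.frame(peptide_id = store$ids[eligible[take]],
               index = eligible[take],
               distance = pmax(d[take], 0),
               row.names = NULL),
    class = c("neighbor_set", "data.frame")
  )
}

#' Average the embedding matrices of a neighbor set
#'
#' Element-wise mean on the common padded grid: rows beyond each
#' neighbor's true length are zero and are included, which is the only
#' shape-preserving way to average variable-length peptides without an
#' alignment step. The result's true length is the maximum neighbor true
#' length.
#'
#' @param store a `rag_store`.
#' @param neighbors a `neighbor_set` from [retrieve_top_k()].
#' @return an `embedding_matrix`.
#' @export
average_neighbors <- function(store, neighbors) {
  stopifnot(inherits(store, "rag_store"), nrow(neighbors) >= 1)
  acc <- Reduce(`+`, store$matrices[neighbors$index])
  new_embedding_matrix(acc / nrow(neighbors),
                       max(store$true_lengths[neighbors$index]),
                       paste0("avg(", paste(neighbors$peptide_id, collapse = ","), ")"))
}

#' Fuse a query embedding with averaged retrieved context
#'
#' Element-wise convex combination `(a * query + b * retrieved) / (a + b)`
#' with the configured weights; at the default 1:1 this is the plain
#' average of the two matrices. The fused matrix keeps the query's true
#' length.
#'
#' @param query,neighbor_mean `embedding_matrix` objects of equal shape.
#' @param config a [fusion_config()] supplying the weights.
#' @return an `embedding_matrix`.
#' @export
fuse_embeddings <- function(query, neighbor_mean, config = fusion_config()) {
  stopifnot(inherits(query, "embedding_matrix"))
  a <- config$ratio_query
  b <- config$ratio_retrieved
  if (b == 0) {
    return(new_embedding_matrix(query$values, query$true_length, query$peptide_id))
  }
  stopifnot(inherits(neighbor_mean, "embedding_matrix"))
  if (!all(dim(query$values) == dim(neighbor_mean$values))) {
    stop_user("shape mismatch between query and retrieved embeddings")
  }
  new_embedding_matrix((a * query$values + b * neighbor_mean$values) / (a + b),
                       query$true_length, query$peptide_id)
}

#' Retrieval-augment every peptide of a manifest
#'
#' The end-to-end enrichment step: embed each peptide, retrieve its
#' nearest stored neighbors, average their matrices, and fuse with the
#' query embedding. With `ratio_retrieved = 0` retrieval is skipped and
#' the query embeddings are returned unchanged.
#'
#' @param manifest a [peptide_manifest()].
#' @param store a `rag_store` to retrieve from.
#' @param embedder an [embedder_config()] (must match the store geometry).
#' @param fusion a [fusion_config()].
#' @param embeddings optional precomputed [embed_dataset()] result.
#' @return named list of fused `embedding_matrix` objects, manifest order.
#' @export
augment_dataset <- function(manifest, store, embedder,
                            fusion = fusion_config(), embeddings = NULL) {
  stopifnot(inherits(store, "rag_store"))
  if (store$dim != embedder$dim || store$padded_length != embedder$padded_length) {
    stop_user("embedder geometry (dim/padded_length) does not match the store")
  }
  emb <- embeddings %||% embed_dataset(manifest, embedder)
  if (fusion$ratio_retrieved == 0) return(emb)
  peptides <- if (inherits(manifest, "peptide_manifest")) manifest$peptides else manifest
  out <- vector("list", length(emb))
  for (i in seq_along(emb)) {
    nb <- retrieve_top_k(store, mean_pool(emb[[i]]), fusion,
                         query_sequence = peptides$sequence[i])
    out[[i]] <- fuse_embeddings(emb[[i]], average_neighbors(store, nb), fusion)
  }
  names(out) <- names(emb)
  out
}
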