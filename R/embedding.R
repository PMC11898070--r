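# Per-residue embedding: embedder contract, synthetic lookup backend,
# padding, masked mean pooling, and the adapter interface for real PLMs.

#' Embedder configuration
#'
#' Declares how peptides are turned into padded per-residue embedding
#' matrices. Two backends exist:
#'
#' * `"synthetic"` — a deterministic per-residue lookup: each of the 20
#'   canonical residues (plus the unknown token `"X"`) maps to a fixed
#'   vector drawn once from a seeded standard normal. No context mixing;
#'   the simplest stand-in for a protein language model that still lets
#'   convolution windows detect planted motifs.
#' * `"adapter"` — any callable obeying the protein-language-model
#'   contract: sequence string in, L x dim numeric matrix out. The
#'   pipeline pads/truncates and behaves identically downstream.
#'
#' @param dim embedding dimension per residue (1024 for ProtTrans-scale
#'   models; tests use much smaller values).
#' @param padded_length fixed number of rows after C-terminal zero
#'   padding; must be at least the largest convolution window used
#'   downstream.
#' @param backend `"synthetic"` or `"adapter"`.
#' @param seed seed for the synthetic residue table.
#' @param adapter function `(sequence) -> L x dim matrix`; required when
#'   `backend = "adapter"`.
#' @return an `embedder_config` object.
#' @export
embedder_config <- function(dim = 1024L, padded_length = 40L,
                            backend = c("synthetic", "adapter"),
                            seed = 0L, adapter = NULL) {
  backend <- match.arg(backend)
  stopifnot(dim >= 1, padded_length >= 1)
  if (backend == "adapter" && !is.function(adapter)) {
    stop_user("backend 'adapter' requires an adapter function")
  }
  structure(
    list(dim = as.integer(dim), padded_length = as.integer(padded_length),
         backend = backend, seed = as.integer(seed), adapter = adapter),
    class = "embedder_config"
  )
}

#' Synthetic residue embedding table
#'
#' 21 vectors (20 canonical residues plus the unknown token) of length
#' `dim`, each component i.i.d. standard normal from the seeded
#' generator, fixed thereafter. The synthetic backend sets row i of a
#' peptide's matrix to the table entry of residue i.
#'
#' @param seed integer seed.
#' @param dim vector length.
#' @return 21 x dim numeric matrix with residue letters as rownames.
#' @export
synthetic_residue_table <- function(seed = 0L, dim = 1024L) {
  letters21 <- c(AA_ALPHABET, AA_UNKNOWN)
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(letters21) * dim), nrow = length(letters21),
                dimnames = list(letters21, NULL))
    m
  })
}

new_embedding_matrix <- function(values, true_length, peptide_id) {
  structure(
    list(values = values, true_length = as.integer(true_length),
         peptide_id = peptide_id),
    class = "embedding_matrix"
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix '%s': %d x %d, true_length %d>\n",
              x$peptide_id, nrow(x$values), ncol(x$values), x$true_length))
  invisible(x)
}

#' Embed one peptide as a padded per-residue matrix
#'
#' Produces a `padded_length x dim` matrix: one row per residue from the
#' configured backend, zero rows beyond the true length (C-terminal zero
#' padding). Sequences longer than `padded_length` are truncated at the
#' C-terminus with a warning.
#'
#' @param peptide a one-row data.frame (`id`, `sequence`) or a list with
#'   `$id` and `$sequence`.
#' @param config an [embedder_config()].
#' @param table optional precomputed [synthetic_residue_table()] (avoids
#'   rebuilding it per peptide when embedding many).
#' @return an `embedding_matrix`: list with `values`, `true_length`,
#'   `peptide_id`.
#' @export
embed_peptide <- function(peptide, config, table = NULL) {
  stopifnot(inherits(config, "embedder_config"))
  sequence <- toupper(as.character(peptide$sequence))
  id <- as.character(peptide$id)
  if (is.na(sequence) || !nzchar(sequence)) stop_user("empty sequence for '", id, "'")
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L > config$padded_length) {
    warning(sprintf("sequence '%s' (%d residues) truncated to padded_length %d",
                    id, L, config$padded_length))
    chars <- chars[seq_len(config$padded_length)]
    L <- config$padded_length
  }
  values <- matrix(0, nrow = config$padded_length, ncol = config$dim)
  if (config$backend == "synthetic") {
    if (is.null(table)) table <- synthetic_residue_table(config$seed, config$dim)
    if (ncol(table) != config$dim) stop_user("residue table dim mismatch")
    unknown <- !chars %in% rownames(table)
    chars[unknown] <- AA_UNKNOWN
    values[seq_len(L), ] <- table[chars, , drop = FALSE]
  } else {
    raw <- config$adapter(paste(chars, collapse = ""))
    if (!is.matrix(raw) || ncol(raw) != config$dim) {
      stop_user("adapter must return an L x ", config$dim, " matrix")
    }
    keep <- min(nrow(raw), L)
    values[seq_len(keep), ] <- raw[seq_len(keep), , drop = FALSE]
    L <- keep
  }
  new_embedding_matrix(values, L, id)
}

#' Embed every peptide of a manifest
#'
#' @param manifest a [peptide_manifest()] or peptide data.frame.
#' @param config an [embedder_config()].
#' @return named list of `embedding_matrix` objects, in manifest order.
#' @export
embed_dataset <- function(manifest, config) {
  peptides <- if (inherits(manifest, "peptide_manifest")) manifest$peptides else manifest
  table <- if (config$backend == "synthetic") {
    synthetic_residue_table(config$seed, config$dim)
  }
  out <- lapply(seq_len(nrow(peptides)), function(i) {
    embed_peptide(peptides[i, ], config, table = table)
  })
  names(out) <- peptides$id
  out
}

#' Masked mean pooling of an embedding matrix
#'
#' Component-wise mean over the first `true_length` rows; padding rows
#' never contribute. This sequence-level vector is what similarity
#' retrieval compares.
#'
#' @param matrix an `embedding_matrix`.
#' @return a `pooled_vector`: list with `values` (length-dim numeric) and
#'   `peptide_id`.
#' @export
mean_pool <- function(matrix) {
  stopifnot(inherits(matrix, "embedding_matrix"))
  if (matrix$true_length < 1) stop_user("cannot pool an empty embedding")
  structure(
    list(values = colMeans(matrix$values[seq_len(matrix$true_length), , drop = FALSE]),
         peptide_id = matrix$peptide_id),
    class = "pooled_vector"
  )
}
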