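# Peptide dataset I/O, manifests, and the synthetic planted-motif generator.

#' Validate peptide records
#'
#' Checks ids are unique and non-empty, sequences are non-empty and drawn
#' from the 20 canonical residue letters. Non-canonical letters
#' (B, J, O, U, X, Z) are rejected by default; with `allow_nonstandard`
#' they are mapped to the dedicated unknown token `"X"` understood by the
#' synthetic embedder. Silent coercion is never performed: anything outside
#' the 26 letters is always an error.
#'
#' @param peptides data.frame with columns `id`, `sequence` (and optionally
#'   `label`).
#' @param allow_nonstandard map non-canonical residue letters to `"X"`
#'   instead of rejecting them.
#' @return the validated (possibly remapped) data.frame.
#' @export
validate_peptides <- function(peptides, allow_nonstandard = FALSE) {
  stopifnot(is.data.frame(peptides), all(c("id", "sequence") %in% names(peptides)))
  peptides$id <- as.character(peptides$id)
  peptides$sequence <- toupper(as.character(peptides$sequence))
  if (anyNA(peptides$id) || any(!nzchar(peptides$id))) {
    stop_user("peptide ids must be non-empty")
  }
  dup <- peptides$id[duplicated(peptides$id)]
  if (length(dup) > 0) {
    stop_user("duplicate peptide id(s): ", paste(unique(dup), collapse = ", "))
  }
  empty <- which(!nzchar(peptides$sequence) | is.na(peptides$sequence))
  if (length(empty) > 0) {
    stop_user("empty sequence for record(s): ",
              paste(peptides$id[empty], collapse = ", "))
  }
  letters_used <- strsplit(peptides$sequence, "")
  for (i in seq_along(letters_used)) {
    bad <- setdiff(letters_used[[i]], AA_ALPHABET)
    if (length(bad) == 0) next
    nonstd <- intersect(bad, NONSTANDARD_AA)
    other <- setdiff(bad, NONSTANDARD_AA)
    if (length(other) > 0) {
      stop_user("record '", peptides$id[i], "' contains non-residue character(s): ",
                paste(other, collapse = ", "))
    }
    if (!allow_nonstandard) {
      stop_user("record '", peptides$id[i], "' contains non-canonical residue(s) ",
                paste(nonstd, collapse = ", "),
                " (use allow_nonstandard = TRUE to map them to the unknown token)")
    }
    s <- letters_used[[i]]
    s[s %in% NONSTANDARD_AA] <- AA_UNKNOWN
    peptides$sequence[i] <- paste(s, collapse = "")
  }
  peptides
}

#' Assemble a peptide dataset manifest
#'
#' A manifest bundles an ordered peptide table with its name and class
#' counts. Counts are always re-derived from the labels, never trusted
#' from the caller.
#'
#' @param peptides data.frame with columns `id`, `sequence` and optionally
#'   `label` (binary: 1 = IL-6 inducing, 0 = non-inducing, NA = unlabeled).
#' @param name dataset name.
#' @param allow_nonstandard passed to [validate_peptides()].
#' @return an object of class `peptide_manifest`: list with `name`,
#'   `peptides`, and `class_counts` (`n_positive`, `n_negative`).
#' @export
peptide_manifest <- function(peptides, name = "dataset", allow_nonstandard = FALSE) {
  peptides <- validate_peptides(peptides, allow_nonstandard = allow_nonstandard)
  if (!"label" %in% names(peptides)) peptides$label <- NA_integer_
  lab <- peptides$label
  if (!all(is.na(lab) | lab %in% c(0L, 1L))) {
    bad <- which(!(is.na(lab) | lab %in% c(0L, 1L)))
    stop_user("non-binary label in row(s): ", paste(bad, collapse = ", "))
  }
  peptides$label <- as.integer(lab)
  structure(
    list(
      name = name,
      peptides = peptides,
      class_counts = c(
        n_positive = sum(peptides$label == 1L, na.rm = TRUE),
        n_negative = sum(peptides$label == 0L, na.rm = TRUE)
      )
    ),
    class = "peptide_manifest"
  )
}

#' @export
print.peptide_manifest <- function(x, ...) {
  cat(sprintf(
    "<peptide_manifest '%s': %d peptides (%d positive, %d negative, %d unlabeled)>\n",
    x$name, nrow(x$peptides),
    x$class_counts[["n_positive"]], x$class_counts[["n_negative"]],
    sum(is.na(x$peptides$label))
  ))
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' The header token before the first whitespace becomes the id; sequences
#' are uppercased; record order is preserved. Multi-line sequences are
#' accepted.
#'
#' @param path FASTA file path.
#' @param allow_nonstandard passed to [validate_peptides()].
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, allow_nonstandard = FALSE) {
  if (!file.exists(path)) stop_user("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  validate_peptides(
    data.frame(id = ids, sequence = as.character(set), row.names = NULL),
    allow_nonstandard = allow_nonstandard
  )
}

#' Write peptides to a FASTA file
#'
#' Sequences are written on a single line each.
#'
#' @param peptides data.frame with columns `id`, `sequence`, or a
#'   `peptide_manifest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  if (inherits(peptides, "peptide_manifest")) peptides <- peptides$peptides
  set <- Biostrings::BStringSet(peptides$sequence)
  names(set) <- peptides$id
  Biostrings::writeXStringSet(set, path, width = 100000L)
  invisible(path)
}

#' Load a labeled peptide table
#'
#' Reads a comma-separated UTF-8 table with a header row and columns
#' `id`, `sequence`, and (optionally, for prediction inputs) `label`.
#' Labels must be 0 or 1; anything else is an error naming the row.
#'
#' @param path CSV file path.
#' @param name manifest name (defaults to the file stem).
#' @param allow_nonstandard passed to [validate_peptides()].
#' @return a [peptide_manifest()].
#' @export
load_labeled_table <- function(path, name = NULL,
                               allow_nonstandard = FALSE) {
  if (!file.exists(path)) stop_user("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(c("id", "sequence"), names(tab))
  if (length(missing_cols) > 0) {
    stop_user("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if ("label" %in% names(tab) && nrow(tab) > 0) {
    raw <- tab$label
    ok <- raw %in% c("0", "1") | raw == "" | is.na(raw)
    if (!all(ok)) {
      stop_user("non-binary label in row(s): ",
                paste(which(!ok), collapse = ", "),
                " (values: ", paste(unique(raw[!ok]), collapse = ", "), ")")
    }
    tab$label <- ifelse(raw %in% c("0", "1"), as.integer(raw), NA_integer_)
  }
  peptide_manifest(tab, name = name %||% tools::file_path_sans_ext(basename(path)),
                   allow_nonstandard = allow_nonstandard)
}

#' Write a manifest as a labeled CSV table
#'
#' @param manifest a [peptide_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(manifest, path) {
  stopifnot(inherits(manifest, "peptide_manifest"))
  utils::write.csv(manifest$peptides[c("id", "sequence", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic labeled peptide dataset with a planted motif
#'
#' Stand-in for a curated cytokine-peptide collection. Negative sequences
#' are i.i.d. uniform over the 20 canonical residues with lengths drawn
#' uniformly from `length_range`. Positives are generated the same way,
#' then with probability `motif_prob` the motif is written over the
#' residues at a uniformly chosen offset, so the length distribution is
#' identical across classes. Fully reproducible from `seed`.
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range integer `(min, max)` sequence length in residues.
#' @param motif residue string planted in positives; must be no longer
#'   than `length_range[1]`.
#' @param motif_prob probability a positive carries the motif (0 < p <= 1).
#' @param seed integer seed.
#' @param name manifest name.
#' @return a [peptide_manifest()]; positives first, then negatives.
#' @export
generate_synthetic_dataset <- function(n_pos, n_neg, length_range = c(8L, 35L),
                                       motif = "WWWWW", motif_prob = 1,
                                       seed = 0L, name = "synthetic") {
  stopifnot(n_pos >= 0, n_neg >= 0, length(length_range) == 2)
  length_range <- as.integer(length_range)
  if (length_range[1] < 1 || length_range[2] < length_range[1]) {
    stop_user("invalid length_range")
  }
  if (nchar(motif) > length_range[1]) {
    stop_user("motif (length ", nchar(motif),
              ") longer than minimum sequence length ", length_range[1])
  }
  if (!(motif_prob > 0 && motif_prob <= 1)) {
    stop_user("motif_prob must be in (0, 1]")
  }
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% AA_ALPHABET)) stop_user("motif contains non-canonical residues")
  m <- length(motif_chars)

  with_seed(seed, {
    n <- n_pos + n_neg
    candidates <- seq.int(length_range[1], length_range[2])
    lens <- if (length(candidates) == 1L) rep(candidates, n) else {
      sample(candidates, n, replace = TRUE)
    }
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- sample(AA_ALPHABET, lens[i], replace = TRUE)
      if (i <= n_pos && stats::runif(1) <= motif_prob) {
        off <- sample.int(lens[i] - m + 1L, 1L)
        s[off:(off + m - 1L)] <- motif_chars
      }
      seqs[i] <- paste(s, collapse = "")
    }
    peptide_manifest(
      data.frame(
        id = c(sprintf("pos%04d", seq_len(n_pos)), sprintf("neg%04d", seq_len(n_neg)))[seq_len(n)],
        sequence = seqs,
        label = rep(c(1L, 0L), c(n_pos, n_neg))
      ),
      name = name
    )
  })
}
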