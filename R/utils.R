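# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_UNKNOWN <- "X"
NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Round half away from zero
#'
#' Report-precision rounding: exact halves move away from zero (so 0.85865
#' at 4 digits gives 0.8587), unlike [base::round()]'s round-half-even.
#' A 1e-9 relative guard absorbs binary representation error just below a
#' half (e.g. `(0.7808 + 0.9365) / 2` stored fractionally under 0.85865).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_user <- function(...) {
  stop(structure(
    class = c("ragmcnn_user_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
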