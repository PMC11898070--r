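# Nested run configuration shared by the CLI and scripted pipelines.

#' Default run configuration
#'
#' One nested configuration covering every pipeline stage, with defaults
#' equal to the method's selected settings: windows 2, 4, 16, 24, 32, 34
#' with 512 filters, top-5 cosine retrieval fused at 1:1, 5-fold
#' cross-validation. Serializes to and from YAML unchanged.
#'
#' @return a `run_config`: nested list with sections `embedder`,
#'   `fusion`, `model`, `training`, `evaluation`.
#' @export
default_run_config <- function() {
  structure(
    list(
      embedder = list(dim = 1024L, padded_length = 40L, backend = "synthetic",
                      seed = 0L),
      fusion = list(k = 5L, ratio_query = 1, ratio_retrieved = 1,
                    metric = "cosine", exclude_self = TRUE),
      model = list(window_sizes = c(2L, 4L, 16L, 24L, 32L, 34L),
                   n_filters = 512L, threshold = 0.5),
      training = list(epochs = 30L, batch_size = 32L, learning_rate = 1e-3,
                      val_fraction = 0.1, patience = 5L,
                      class_weighting = "none"),
      evaluation = list(k_folds = 5L, pool = TRUE)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Sections or fields absent from the file keep their defaults; unknown
#' sections or fields are an error (they are almost always typos).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_user("no such config file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (section in names(user)) {
    if (!section %in% names(cfg)) stop_user("unknown config section: ", section)
    for (field in names(user[[section]])) {
      if (!field %in% names(cfg[[section]])) {
        stop_user("unknown config field: ", section, ".", field)
      }
      template <- cfg[[section]][[field]]
      value <- user[[section]][[field]]
      cfg[[section]][[field]] <- if (is.integer(template)) {
        as.integer(value)
      } else if (is.numeric(template)) {
        as.numeric(value)
      } else if (is.logical(template)) {
        as.logical(value)
      } else {
        as.character(value)
      }
    }
  }
  cfg
}

#' Write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialize the module-level configs from a run_config.
resolve_configs <- function(cfg, seed = NULL) {
  embedder <- embedder_config(dim = cfg$embedder$dim,
                              padded_length = cfg$embedder$padded_length,
                              backend = cfg$embedder$backend,
                              seed = seed %||% cfg$embedder$seed)
  fusion <- fusion_config(k = cfg$fusion$k,
                          ratio_query = cfg$fusion$ratio_query,
                          ratio_retrieved = cfg$fusion$ratio_retrieved,
                          metric = cfg$fusion$metric,
                          exclude_self = cfg$fusion$exclude_self)
  model <- mcnn_config(window_sizes = cfg$model$window_sizes,
                       n_filters = cfg$model$n_filters,
                       padded_length = cfg$embedder$padded_length,
                       dim = cfg$embedder$dim,
                       threshold = cfg$model$threshold,
                       seed = seed %||% cfg$embedder$seed)
  training <- train_config(epochs = cfg$training$epochs,
                           batch_size = cfg$training$batch_size,
                           learning_rate = cfg$training$learning_rate,
                           val_fraction = cfg$training$val_fraction,
                           patience = cfg$training$patience,
                           class_weighting = cfg$training$class_weighting,
                           seed = seed %||% cfg$embedder$seed)
  list(embedder = embedder, fusion = fusion, model = model, training = training,
       k_folds = cfg$evaluation$k_folds, pool = cfg$evaluation$pool)
}
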