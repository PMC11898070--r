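# Multi-window convolutional classifier over (fused) embedding matrices.
#
# Architecture: for each configured window size w, a 1-D convolution of
# extent w over the padded length axis spanning all embedding channels
# (n_filters output channels), rectified, then globally max-pooled so each
# filter contributes a single value; per-window outputs are concatenated
# and fed to a sigmoid unit. Implemented directly in vectorized base R
# (im2col + matrix multiply forward, analytic backprop, Adam), so training
# is deterministic given the seed and runs on one CPU.

#' Model configuration for the multi-window CNN
#'
#' Defaults follow the method's selected architecture: six parallel
#' windows of sizes 2, 4, 16, 24, 32, 34 with 512 filters each, giving a
#' concatenated feature vector of length `6 * 512 = 3072`.
#'
#' @param window_sizes positive integer kernel extents; each must be at
#'   most `padded_length`.
#' @param n_filters filters per window.
#' @param padded_length,dim input geometry; must match the embedder.
#' @param threshold score cutoff for hard class calls (confusion
#'   matrices); 0.5 by default.
#' @param seed seed for weight initialization.
#' @return an `mcnn_config` object.
#' @export
mcnn_config <- function(window_sizes = c(2L, 4L, 16L, 24L, 32L, 34L),
                        n_filters = 512L, padded_length = 40L, dim = 1024L,
                        threshold = 0.5, seed = 0L) {
  window_sizes <- as.integer(window_sizes)
  stopifnot(length(window_sizes) >= 1, all(window_sizes >= 1), n_filters >= 1)
  if (max(window_sizes) > padded_length) {
    stop_user("largest window (", max(window_sizes),
              ") exceeds padded_length (", padded_length, ")")
  }
  structure(
    list(window_sizes = window_sizes, n_filters = as.integer(n_filters),
         padded_length = as.integer(padded_length), dim = as.integer(dim),
         threshold = threshold, seed = as.integer(seed)),
    class = "mcnn_config"
  )
}

#' Training configuration
#'
#' Every optimization choice is explicit and seedable: binary
#' cross-entropy loss, Adam, learning rate 1e-3, batch size 32, 30
#' epochs, early stopping on a 10% stratified validation split with
#' patience 5, class weighting off by default.
#'
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction held out for early stopping (0 disables
#'   early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param class_weighting `"none"` or `"balanced"` (per-example loss
#'   weights inversely proportional to class frequency).
#' @param seed seed governing the validation split and batch order.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, learning_rate = 1e-3,
                         val_fraction = 0.1, patience = 5L,
                         class_weighting = c("none", "balanced"), seed = 0L) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            val_fraction >= 0, val_fraction < 1, patience >= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, val_fraction = val_fraction,
         patience = as.integer(patience), class_weighting = class_weighting,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# P x (w*dim) linear-index matrix: row p holds the column-major flatten of
# input rows p..p+w-1 across all dim channels.
im2col_index <- function(w, padded_length, dim) {
  base <- rep((seq_len(dim) - 1L) * padded_length, each = w) + seq_len(w)
  P <- padded_length - w + 1L
  matrix(rep(base, each = P), nrow = P) + (seq_len(P) - 1L)
}

#' Build an untrained multi-window CNN
#'
#' Convolution weights are He-initialized from the seeded generator;
#' biases and the output layer start at zero, so an untrained model
#' scores every input at exactly 0.5.
#'
#' @param config an [mcnn_config()].
#' @return an `mcnn_model` (untrained).
#' @export
build_mcnn <- function(config) {
  stopifnot(inherits(config, "mcnn_config"))
  F <- config$n_filters
  params <- with_seed(config$seed, {
    W <- lapply(config$window_sizes, function(w) {
      fan_in <- w * config$dim
      matrix(stats::rnorm(fan_in * F, sd = sqrt(2 / fan_in)), nrow = fan_in, ncol = F)
    })
    b <- lapply(config$window_sizes, function(w) numeric(F))
    list(W = W, b = b,
         v = numeric(length(config$window_sizes) * F), c = 0)
  })
  structure(
    list(config = config, params = params, trained = FALSE, history = NULL,
         idx = lapply(config$window_sizes, im2col_index,
                      padded_length = config$padded_length, dim = config$dim)),
    class = "mcnn_model"
  )
}

#' @export
print.mcnn_model <- function(x, ...) {
  cat(sprintf("<mcnn_model: windows [%s], %d filters, input %d x %d, %s>\n",
              paste(x$config$window_sizes, collapse = ", "),
              x$config$n_filters, x$config$padded_length, x$config$dim,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

as_input_matrix <- function(x, config) {
  v <- if (inherits(x, "embedding_matrix")) x$values else x
  if (!is.matrix(v) || nrow(v) != config$padded_length || ncol(v) != config$dim) {
    stop_user("input shape ", paste(dim(v), collapse = " x "),
              " does not match model geometry ",
              config$padded_length, " x ", config$dim)
  }
  v
}

# Forward pass over a list of inputs. Returns logits plus, when
# want_cache, everything backprop needs (im2col blocks, pre-activations,
# argmax positions).
mcnn_forward <- function(model, inputs, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- length(inputs)
  nw <- length(cfg$window_sizes)
  F <- cfg$n_filters
  H <- matrix(0, nrow = B, ncol = nw * F)
  cache <- if (want_cache) {
    list(Xc = vector("list", nw), argmax = vector("list", nw),
         active = vector("list", nw))
  }
  mats <- lapply(inputs, as_input_matrix, config = cfg)
  for (j in seq_len(nw)) {
    idx <- model$idx[[j]]
    P <- nrow(idx)
    Xc <- do.call(rbind, lapply(mats, function(X) matrix(X[idx], nrow = P)))
    A <- pmax(Xc %*% p$W[[j]] + rep(p$b[[j]], each = B * P), 0)
    am <- matrix(0L, nrow = B, ncol = F)
    hv <- matrix(0, nrow = B, ncol = F)
    for (i in seq_len(B)) {
      Ai <- A[((i - 1L) * P + 1L):(i * P), , drop = FALSE]
      mc <- max.col(t(Ai), ties.method = "first") # earliest position on ties
      am[i, ] <- mc
      hv[i, ] <- Ai[cbind(mc, seq_len(F))]
    }
    H[, ((j - 1L) * F + 1L):(j * F)] <- hv
    if (want_cache) {
      cache$Xc[[j]] <- Xc
      cache$argmax[[j]] <- am
      cache$active[[j]] <- hv > 0
    }
  }
  logits <- as.numeric(H %*% p$v + p$c)
  out <- list(logits = logits, scores = 1 / (1 + exp(-logits)), features = H)
  if (want_cache) out$cache <- cache
  out
}

#' Post-pooling feature vectors
#'
#' Runs the convolutional front end only: one concatenated feature vector
#' of length `length(window_sizes) * n_filters` per input.
#'
#' @param model an `mcnn_model`.
#' @param inputs list of `embedding_matrix` objects (or plain matrices of
#'   the model's geometry).
#' @return numeric matrix, one row per input.
#' @export
mcnn_features <- function(model, inputs) {
  mcnn_forward(model, inputs)$features
}

bce_loss <- function(scores, labels, weights) {
  eps <- 1e-12
  sum(weights * -(labels * log(scores + eps) + (1 - labels) * log(1 - scores + eps))) /
    sum(weights)
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' Train the multi-window CNN
#'
#' Minimizes binary cross-entropy with Adam. Identical
#' `(model, inputs, labels, tcfg)` always yield identical histories and
#' parameters: the only randomness is the seeded validation split, batch
#' order and (already fixed) initialization.
#'
#' @param model an untrained (or previously trained) `mcnn_model`.
#' @param inputs list of `embedding_matrix` objects aligned with `labels`.
#' @param labels binary vector (both classes must be present).
#' @param tcfg a [train_config()].
#' @return the trained `mcnn_model`, with `$history` (per-epoch train and
#'   validation loss) and the parameters of the best validation epoch.
#' @export
train_mcnn <- function(model, inputs, labels, tcfg = train_config()) {
  stopifnot(inherits(model, "mcnn_model"), inherits(tcfg, "train_config"))
  labels <- as.numeric(labels)
  if (length(inputs) != length(labels)) stop_user("inputs and labels differ in length")
  if (length(unique(labels)) < 2) {
    stop_user("training set contains a single class; need both positives and negatives")
  }
  n <- length(labels)
  weights <- if (tcfg$class_weighting == "balanced") {
    n / (2 * ifelse(labels == 1, sum(labels == 1), sum(labels == 0)))
  } else {
    rep(1, n)
  }

  with_seed(tcfg$seed, {
    val_idx <- integer(0)
    if (tcfg$val_fraction > 0) {
      for (cls in c(0, 1)) { # stratified split keeps both classes in both parts
        cls_idx <- which(labels == cls)
        n_val <- floor(length(cls_idx) * tcfg$val_fraction)
        if (n_val > 0) val_idx <- c(val_idx, sample(cls_idx, n_val))
      }
      val_idx <- sort(val_idx)
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(labels[train_idx])) < 2) {
      stop_user("validation split left a single-class training set; lower val_fraction")
    }
    use_val <- length(val_idx) > 0 && length(unique(labels[val_idx])) == 2

    p <- model$params
    opt <- adam_init(p)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    nw <- length(model$config$window_sizes)
    F <- model$config$n_filters
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, params = p, epoch = 0L)
    stale <- 0L

    for (epoch in seq_len(tcfg$epochs)) {
      order_idx <- sample(train_idx)
      batch_losses <- numeric(0)
      for (start in seq(1, length(order_idx), by = tcfg$batch_size)) {
        bi <- order_idx[start:min(start + tcfg$batch_size - 1, length(order_idx))]
        B <- length(bi)
        model$params <- p
        fw <- mcnn_forward(model, inputs[bi], want_cache = TRUE)
        wts <- weights[bi]
        loss <- bce_loss(fw$scores, labels[bi], wts)
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (lower the learning rate)")
        }
        batch_losses <- c(batch_losses, loss)

        dlogit <- wts * (fw$scores - labels[bi]) / sum(wts)
        grads <- list(W = vector("list", nw), b = vector("list", nw),
                      v = as.numeric(crossprod(fw$features, dlogit)),
                      c = sum(dlogit))
        dH <- outer(dlogit, p$v)
        for (j in seq_len(nw)) {
          cols <- ((j - 1L) * F + 1L):(j * F)
          dHj <- dH[, cols, drop = FALSE] * fw$cache$active[[j]]
          P <- nrow(model$idx[[j]])
          dW <- matrix(0, nrow = nrow(p$W[[j]]), ncol = F)
          db <- numeric(F)
          for (i in seq_len(B)) {
            g <- dHj[i, ]
            nz <- g != 0
            if (!any(nz)) next
            rows <- fw$cache$Xc[[j]][(i - 1L) * P + fw$cache$argmax[[j]][i, nz], ,
                                     drop = FALSE]
            dW[, nz] <- dW[, nz] + t(rows * g[nz])
            db[nz] <- db[nz] + g[nz]
          }
          grads$W[[j]] <- dW
          grads$b[[j]] <- db
        }

        opt$t <- opt$t + 1L
        corr1 <- 1 - beta1^opt$t
        corr2 <- 1 - beta2^opt$t
        step <- function(par, g, m, v) {
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g^2
          list(par = par - tcfg$learning_rate * (m / corr1) / (sqrt(v / corr2) + eps),
               m = m, v = v)
        }
        for (j in seq_len(nw)) {
          s <- step(p$W[[j]], grads$W[[j]], opt$m$W[[j]], opt$v$W[[j]])
          p$W[[j]] <- s$par; opt$m$W[[j]] <- s$m; opt$v$W[[j]] <- s$v
          s <- step(p$b[[j]], grads$b[[j]], opt$m$b[[j]], opt$v$b[[j]])
          p$b[[j]] <- s$par; opt$m$b[[j]] <- s$m; opt$v$b[[j]] <- s$v
        }
        s <- step(p$v, grads$v, opt$m$v, opt$v$v)
        p$v <- s$par; opt$m$v <- s$m; opt$v$v <- s$v
        s <- step(p$c, grads$c, opt$m$c, opt$v$c)
        p$c <- s$par; opt$m$c <- s$m; opt$v$c <- s$v
      }

      model$params <- p
      val_loss <- NA_real_
      monitor <- mean(batch_losses)
      if (use_val) {
        fw <- mcnn_forward(model, inputs[val_idx])
        val_loss <- bce_loss(fw$scores, labels[val_idx], weights[val_idx])
        monitor <- val_loss
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(batch_losses),
                                           val_loss = val_loss))
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, params = p, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (use_val && stale >= tcfg$patience) break
      }
    }

    model$params <- best$params
    model$trained <- TRUE
    model$history <- history
    model$best_epoch <- best$epoch
    model
  })
}

#' Score peptides with a trained model
#'
#' @param model a trained `mcnn_model`.
#' @param inputs list of `embedding_matrix` objects (or plain matrices).
#' @return numeric scores in `[0, 1]`, one per input, order preserved.
#' @export
predict_scores <- function(model, inputs) {
  stopifnot(inherits(model, "mcnn_model"))
  if (length(inputs) == 0) return(numeric(0))
  scores <- numeric(length(inputs))
  for (start in seq(1, length(inputs), by = 64L)) { # bounded batch memory
    sel <- start:min(start + 63L, length(inputs))
    scores[sel] <- mcnn_forward(model, inputs[sel])$scores
  }
  scores
}

#' Save a model checkpoint
#'
#' Config as JSON plus all parameter arrays as a dense little-endian
#' double stream; [load_mcnn()] restores the model losslessly.
#'
#' @param model an `mcnn_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_mcnn <- function(model, dir) {
  stopifnot(inherits(model, "mcnn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "ragmcnn-model-v1",
               config = unclass(model$config), trained = model$trained,
               best_epoch = model$best_epoch %||% NA)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  }
  con <- file(file.path(dir, "model.bin"), "wb")
  on.exit(close(con))
  for (j in seq_along(model$params$W)) {
    writeBin(as.numeric(model$params$W[[j]]), con, size = 8, endian = "little")
    writeBin(as.numeric(model$params$b[[j]]), con, size = 8, endian = "little")
  }
  writeBin(as.numeric(model$params$v), con, size = 8, endian = "little")
  writeBin(as.numeric(model$params$c), con, size = 8, endian = "little")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [save_mcnn()].
#' @return an `mcnn_model`.
#' @export
load_mcnn <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop_user("no model found in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "ragmcnn-model-v1")) stop_user("unrecognized model format")
  cfg <- mcnn_config(window_sizes = meta$config$window_sizes,
                     n_filters = meta$config$n_filters,
                     padded_length = meta$config$padded_length,
                     dim = meta$config$dim,
                     threshold = meta$config$threshold,
                     seed = meta$config$seed)
  model <- build_mcnn(cfg)
  F <- cfg$n_filters
  con <- file(file.path(dir, "model.bin"), "rb")
  on.exit(close(con))
  for (j in seq_along(cfg$window_sizes)) {
    fan_in <- cfg$window_sizes[j] * cfg$dim
    model$params$W[[j]] <- matrix(
      readBin(con, "numeric", fan_in * F, size = 8, endian = "little"),
      nrow = fan_in, ncol = F)
    model$params$b[[j]] <- readBin(con, "numeric", F, size = 8, endian = "little")
  }
  model$params$v <- readBin(con, "numeric", length(cfg$window_sizes) * F,
                            size = 8, endian = "little")
  model$params$c <- readBin(con, "numeric", 1, size = 8, endian = "little")
  model$trained <- isTRUE(meta$trained)
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) model$history <- utils::read.csv(hist_path)
  model
}
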