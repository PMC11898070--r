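make_inputs <- function(manifest, cfg) {
  embed_dataset(manifest, cfg)
}

test_that("concatenated feature width is windows x filters for every geometry", {
  # the selected architecture: 6 windows x 512 filters = 3072 features
  default_cfg <- mcnn_config()
  expect_equal(length(default_cfg$window_sizes) * default_cfg$n_filters, 3072)
  expect_equal(default_cfg$window_sizes, c(2L, 4L, 16L, 24L, 32L, 34L))

  cases <- list(c(1, 1), c(3, 4), c(2, 16))
  for (cs in cases) {
    nw <- cs[1]; nf <- cs[2]
    cfg <- mcnn_config(window_sizes = seq(2, length.out = nw), n_filters = nf,
                       padded_length = 12, dim = 5, seed = 1)
    model <- build_mcnn(cfg)
    H <- mcnn_features(model, list(matrix(rnorm(60), 12, 5)))
    expect_equal(ncol(H), nw * nf)
  }

  expect_error(mcnn_config(window_sizes = c(2, 40), padded_length = 12),
               "exceeds padded_length")
})

test_that("an all-zero input yields the rectified bias of each filter", {
  cfg <- mcnn_config(window_sizes = c(2, 3), n_filters = 4, padded_length = 10,
                     dim = 6, seed = 5)
  model <- build_mcnn(cfg)
  model$params$b <- list(c(-1, 0.5, 0, 2), c(0.25, -3, 1, 0))
  H <- mcnn_features(model, list(matrix(0, 10, 6)))
  expect_equal(as.numeric(H), pmax(c(-1, 0.5, 0, 2, 0.25, -3, 1, 0), 0))
})

test_that("an untrained model scores everything at exactly 0.5", {
  cfg <- mcnn_config(window_sizes = c(2, 4), n_filters = 8, padded_length = 16,
                     dim = 8, seed = 2)
  model <- build_mcnn(cfg)
  inputs <- lapply(1:4, function(i) matrix(rnorm(128), 16, 8))
  expect_equal(predict_scores(model, inputs), rep(0.5, 4))
})

test_that("a hand-set motif filter is invariant to interior motif position", {
  dim <- 10
  cfg <- mcnn_config(window_sizes = 3, n_filters = 1, padded_length = 15,
                     dim = dim, seed = 0)
  model <- build_mcnn(cfg)
  tab <- synthetic_residue_table(0, dim)
  # filter weights = the embedding of the motif "WAC" itself, bias 0
  motif_rows <- tab[c("W", "A", "C"), ]
  model$params$W[[1]] <- matrix(as.vector(motif_rows), ncol = 1)
  model$params$b[[1]] <- 0

  emb_cfg <- embedder_config(dim = dim, padded_length = 15, seed = 0)
  base <- strsplit("GHIKLMNPQRST", "")[[1]] # 12 residues, no W/A/C
  responses <- vapply(c(1, 4, 8, 10), function(off) {
    s <- base
    s[off:(off + 2)] <- c("W", "A", "C")
    em <- embed_peptide(list(id = "m", sequence = paste(s, collapse = "")), emb_cfg)
    mcnn_features(model, list(em))[1, 1]
  }, numeric(1))
  # the max-pooled response of the matched filter is the motif self-similarity,
  # wherever the motif sits inside the unpadded region
  expect_true(all(abs(responses - responses[1]) < 1e-9))
  expect_equal(responses[1], sum(motif_rows^2))
})

test_that("training is bitwise deterministic in its seed", {
  man <- generate_synthetic_dataset(20, 20, length_range = c(6, 12),
                                    motif = "WWWWW", seed = 9)
  emb_cfg <- small_embedder(dim = 8, padded_length = 12)
  inputs <- make_inputs(man, emb_cfg)
  cfg <- mcnn_config(window_sizes = c(2, 4), n_filters = 6, padded_length = 12,
                     dim = 8, seed = 3)
  tcfg <- train_config(epochs = 4, seed = 11)
  m1 <- train_mcnn(build_mcnn(cfg), inputs, man$peptides$label, tcfg)
  m2 <- train_mcnn(build_mcnn(cfg), inputs, man$peptides$label, tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  m3 <- train_mcnn(build_mcnn(cfg), inputs, man$peptides$label,
                   train_config(epochs = 4, seed = 12))
  expect_false(identical(m1$params, m3$params))
})

test_that("loss decreases on a linearly separable planted-motif fixture", {
  man <- generate_synthetic_dataset(40, 40, length_range = c(8, 14),
                                    motif = "WWWWW", motif_prob = 1, seed = 13)
  emb_cfg <- small_embedder(dim = 10, padded_length = 14)
  inputs <- make_inputs(man, emb_cfg)
  cfg <- mcnn_config(window_sizes = c(3, 5), n_filters = 8, padded_length = 14,
                     dim = 10, seed = 1)
  model <- train_mcnn(build_mcnn(cfg), inputs, man$peptides$label,
                      train_config(epochs = 6, val_fraction = 0, seed = 1))
  expect_true(all(diff(model$history$train_loss[1:5]) < 0))

  # held-out discrimination on fresh data from the same generator
  test_man <- generate_synthetic_dataset(30, 30, length_range = c(8, 14),
                                         motif = "WWWWW", motif_prob = 1, seed = 14)
  scores <- predict_scores(model, make_inputs(test_man, emb_cfg))
  expect_gte(roc_auc(test_man$peptides$label, scores), 0.95)
})

test_that("degenerate training inputs are rejected", {
  emb_cfg <- small_embedder(dim = 6, padded_length = 10)
  man <- generate_synthetic_dataset(4, 4, length_range = c(6, 9), motif = "ACD",
                                    seed = 2)
  inputs <- make_inputs(man, emb_cfg)
  cfg <- mcnn_config(window_sizes = 2, n_filters = 2, padded_length = 10,
                     dim = 6, seed = 0)
  expect_error(train_mcnn(build_mcnn(cfg), inputs, rep(1, 8), train_config()),
               "single class")
  expect_error(train_mcnn(build_mcnn(cfg), inputs[1:3], rep(0:1, 4), train_config()),
               "differ in length")
  expect_error(predict_scores(build_mcnn(cfg), list(matrix(0, 5, 6))),
               "does not match model geometry")
})

test_that("checkpoints restore the exact trained model", {
  man <- generate_synthetic_dataset(15, 15, length_range = c(6, 10),
                                    motif = "ACD", seed = 4)
  emb_cfg <- small_embedder(dim = 6, padded_length = 10)
  inputs <- make_inputs(man, emb_cfg)
  cfg <- mcnn_config(window_sizes = c(2, 3), n_filters = 4, padded_length = 10,
                     dim = 6, seed = 7)
  model <- train_mcnn(build_mcnn(cfg), inputs, man$peptides$label,
                      train_config(epochs = 3, seed = 7))
  dir <- withr::local_tempdir()
  save_mcnn(model, dir)
  back <- load_mcnn(dir)
  expect_identical(back$params, model$params)
  expect_identical(predict_scores(back, inputs), predict_scores(model, inputs))
})
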